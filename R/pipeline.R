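# End-to-end driver: annotation QC -> variant discovery -> polarization
# -> constitutive-PTC calls, on in-memory study components.

#' Run the PTC discovery pipeline
#'
#' Chains [qc_filter_genes()], [discover_variants()] and
#' [polarize_variants()] on a study (real or from
#' [simulate_ptc_study()]), and extracts the accepted constitutive PTC
#' set and its gene-level frequency groups.
#'
#' @param study List with `genome`, `genes`, `panel`, `outgroups` (the
#'   shape returned by [simulate_ptc_study()]).
#' @param min_informative Informative-base filter threshold (default 60).
#' @param min_truncation Minimum truncation fraction for a PTC call
#'   (default 0.05).
#' @return List with `qc` (QC result), `variants` (polarized variant
#'   table), `ptc` (accepted PTC subset), `gene_groups` (gene-level
#'   frequency groups of the PTC genes).
#' @export
run_ptc_pipeline <- function(study, min_informative = 60L,
                             min_truncation = 0.05) {
  qc <- qc_filter_genes(study$genes, study$genome)
  variants <- discover_variants(study$genome, qc$retained, study$panel,
                                min_informative = min_informative,
                                min_truncation = min_truncation)
  variants <- polarize_variants(variants, study$panel, study$genome,
                                study$outgroups)
  ptc <- variants[variants$ptc_call &
                    variants$freq_group %in% c("low", "moderate", "high"), ,
                  drop = FALSE]
  list(qc = qc, variants = variants, ptc = ptc,
       gene_groups = gene_frequency_groups(variants))
}
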