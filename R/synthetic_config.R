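# Configuration for the synthetic study generator.  The defaults mirror the
# study design being emulated: 162 inbred strains, 30 adult tissue types of
# which six are sex-related, four replicate arrays per tissue.

#' Default tissue labels for the synthetic expression atlas
#'
#' Thirty adult tissue labels; the final six are sex-related
#' (reproductive-tract) tissues.
#' @keywords internal
DEFAULT_TISSUES <- c(
  "brain", "head", "eye", "thoracic_ganglion", "salivary_gland", "crop",
  "midgut", "malpighian_tubule", "hindgut", "heart", "fat_body", "carcass",
  "rectal_pad", "antenna", "maxillary_palp", "proboscis", "wing", "leg",
  "haltere", "trachea", "larval_fat_body", "larval_midgut", "larval_tubule",
  "larval_trachea",
  "testis", "ovary", "male_accessory_gland", "ejaculatory_duct",
  "mated_spermatheca", "virgin_spermatheca"
)

#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic data: panel size, gene/isoform
#' architecture, planted variants, outgroup divergence, masking rates and
#' the expression-atlas layout.
#'
#' @param n_strains Number of strains in the panel (default 162).
#' @param n_genes Number of genes to generate.
#' @param chrom_names Chromosome labels; must be unique and include
#'   `x_chrom`.
#' @param x_chrom Label of the chromosome flagged as X.
#' @param isoforms_per_gene Integer range `c(min, max)` of isoforms drawn
#'   per gene (capped by the number of skippable internal exons).
#' @param codons_per_gene Integer range of CDS length in codons (the final
#'   stop codon included).
#' @param exons_per_gene Integer range of CDS segment counts per gene.
#' @param intron_length Integer range of intron lengths (nt).
#' @param intergenic_gap Integer range of gaps between gene loci (nt).
#' @param chrom_length Optional fixed chromosome length; an error is raised
#'   if the generated loci do not fit.
#' @param planted_variants `data.frame` of planted variants (see
#'   [planted_variant()]); `NULL` plants nothing.
#' @param outgroup_divergence Per-site, per-outgroup substitution
#'   probability at focal sites (makes a fraction of sites unpolarizable).
#' @param het_rate Probability that a strain/site cell is emitted as an
#'   IUPAC heterozygote code (never applied at planted sites).
#' @param n_mask_rate Probability that a strain/site cell is emitted as `N`
#'   (never applied at planted sites).
#' @param n_tissues Number of tissue types in the expression atlas
#'   (default 30).
#' @param tissue_names Tissue labels (length `n_tissues`).
#' @param sex_tissues Subset of `tissue_names` flagged sex-related.
#' @param replicates_per_tissue Replicate arrays per tissue (default 4).
#' @param archetype_probs Named probabilities for the per-gene expression
#'   archetypes `broad`, `tissue_specific`, `sex_specific`, `silent`.
#' @param young_fraction Fraction of genes labelled evolutionarily young in
#'   random age tables (default 0.09, the genome-wide share of young
#'   genes in the emulated study system).
#' @param seed Integer seed; every generator call is deterministic given
#'   the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 162L,
                             n_genes = 30L,
                             chrom_names = c("2L", "2R", "3R", "X"),
                             x_chrom = "X",
                             isoforms_per_gene = c(1L, 3L),
                             codons_per_gene = c(80L, 250L),
                             exons_per_gene = c(2L, 4L),
                             intron_length = c(60L, 150L),
                             intergenic_gap = c(200L, 600L),
                             chrom_length = NULL,
                             planted_variants = NULL,
                             outgroup_divergence = 0,
                             het_rate = 0,
                             n_mask_rate = 0,
                             n_tissues = 30L,
                             tissue_names = DEFAULT_TISSUES,
                             sex_tissues = DEFAULT_TISSUES[25:30],
                             replicates_per_tissue = 4L,
                             archetype_probs = c(broad = 0.55,
                                                 tissue_specific = 0.20,
                                                 sex_specific = 0.10,
                                                 silent = 0.15),
                             young_fraction = 0.09,
                             seed = 1L) {
  probs <- c(outgroup_divergence, het_rate, n_mask_rate, young_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (n_strains < 60L) {
    stop("configuration error: n_strains must be >= 60 so the ",
         "informative-base filter can pass")
  }
  if (anyDuplicated(chrom_names)) {
    stop("configuration error: chrom_names must be unique")
  }
  if (!x_chrom %in% chrom_names) {
    stop("configuration error: x_chrom must be one of chrom_names")
  }
  tissue_names <- tissue_names[seq_len(n_tissues)]
  if (anyNA(tissue_names)) {
    stop("configuration error: need ", n_tissues, " tissue names")
  }
  if (!all(sex_tissues %in% tissue_names)) {
    stop("configuration error: sex_tissues must be a subset of tissue_names")
  }
  if (!is.null(planted_variants)) {
    planted_variants <- as.data.frame(planted_variants)
    bad <- setdiff(c("site_class", "target_daf", "constitutive",
                     "truncation_fraction", "ancestral_is_ref"),
                   colnames(planted_variants))
    if (length(bad)) {
      stop("configuration error: planted_variants lacks column(s) ",
           paste(bad, collapse = ", "))
    }
    if (any(planted_variants$target_daf < 0 |
            planted_variants$target_daf > 1)) {
      stop("configuration error: target_daf must lie in [0, 1]")
    }
  }
  structure(
    list(n_strains = as.integer(n_strains),
         n_genes = as.integer(n_genes),
         chrom_names = chrom_names, x_chrom = x_chrom,
         isoforms_per_gene = as.integer(isoforms_per_gene),
         codons_per_gene = as.integer(codons_per_gene),
         exons_per_gene = as.integer(exons_per_gene),
         intron_length = as.integer(intron_length),
         intergenic_gap = as.integer(intergenic_gap),
         chrom_length = chrom_length,
         planted_variants = planted_variants,
         outgroup_divergence = outgroup_divergence,
         het_rate = het_rate, n_mask_rate = n_mask_rate,
         n_tissues = as.integer(n_tissues),
         tissue_names = tissue_names, sex_tissues = sex_tissues,
         replicates_per_tissue = as.integer(replicates_per_tissue),
         archetype_probs = archetype_probs,
         young_fraction = young_fraction,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d strains, %d genes on %s; %d planted variants; seed %d\n",
    x$n_strains, x$n_genes, paste(x$chrom_names, collapse = "/"),
    if (is.null(x$planted_variants)) 0L else nrow(x$planted_variants),
    x$seed))
  invisible(x)
}

#' Describe one planted variant
#'
#' @param site_class One of `"nonsense"`, `"missense"`, `"synonymous"`,
#'   `"splice"`, `"start_loss"`.
#' @param target_daf Target derived allele frequency in `[0, 1]`; realized
#'   as `round(target_daf * n_strains)` carrier strains.
#' @param constitutive Should the variant hit every isoform?  `FALSE` (only
#'   meaningful for nonsense) plants the variant in an alternatively
#'   spliced exon and requires a multi-isoform gene.
#' @param truncation_fraction For nonsense variants, the approximate
#'   fraction of the coding region removed by the new stop.
#' @param ancestral_is_ref If `TRUE` the outgroups carry the reference
#'   base and the alternate allele is derived; if `FALSE` the outgroups
#'   carry the alternate base, which makes the site unpolarizable under
#'   the conservative reference-anchored rule.
#' @param gene_id Optional gene to plant into; `NA` lets the generator
#'   pick a suitable gene.
#' @return One-row `data.frame`.
#' @export
planted_variant <- function(site_class,
                            target_daf,
                            constitutive = TRUE,
                            truncation_fraction = 0.5,
                            ancestral_is_ref = TRUE,
                            gene_id = NA_character_) {
  site_class <- match.arg(site_class, c("nonsense", "missense", "synonymous",
                                        "splice", "start_loss"))
  data.frame(gene_id = gene_id, site_class = site_class,
             target_daf = target_daf, constitutive = constitutive,
             truncation_fraction = truncation_fraction,
             ancestral_is_ref = ancestral_is_ref,
             stringsAsFactors = FALSE)
}

#' A default mixed set of planted variants
#'
#' Cycles through the five variant classes with derived allele frequencies
#' spanning the low/moderate/high bins, including values adjacent to the
#' 1.5% and 10% group boundaries.
#'
#' @param n Number of variants.
#' @param n_strains Panel size (used to pick achievable frequencies).
#' @return `data.frame` of planted variants.
#' @export
default_planted_variants <- function(n, n_strains = 162L) {
  classes <- rep(c("nonsense", "missense", "synonymous", "nonsense",
                   "splice", "start_loss", "nonsense", "missense",
                   "synonymous", "nonsense"), length.out = n)
  dafs <- rep(c(1 / n_strains, 0.02, 0.30, 0.10, 0.05, 0.02, 0.01, 0.15,
                0.08, 0.11), length.out = n)
  truncs <- rep(c(0.9, 0.5, 0.2, 0.95, 0.5, 0.5, 0.07, 0.5, 0.5, 0.6),
                length.out = n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    planted_variant(classes[i], dafs[i],
                    truncation_fraction = truncs[i])
  }))
}
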