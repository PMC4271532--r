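# Annotation quality control: remove genes whose annotation is internally
# inconsistent before any variant calling.  A gene is rejected if ANY
# isoform (1) has a CDS length not divisible by three, (2) contains an
# internal stop codon in the reference translation, or (3) does not start
# with ATG or end with a canonical stop codon.  The annotated stop codon is
# taken to be the final three nucleotides of the CDS.

#' Filter gene models by annotation quality
#'
#' @param genes List of `gene_model` objects.
#' @param genome Named character vector of chromosome sequences.
#' @return List with `retained` (list of `gene_model`) and `rejected`
#'   (`data.frame` with `gene_id` and a `;`-separated `reason` string
#'   drawn from `length`, `internal_stop`, `start_stop`).
#' @export
qc_filter_genes <- function(genes, genome) {
  reasons <- lapply(genes, gene_qc_reasons, genome = genome)
  bad <- vapply(reasons, function(r) length(r) > 0L, logical(1L))
  rejected <- data.frame(
    gene_id = vapply(genes[bad], `[[`, character(1L), "gene_id"),
    reason = vapply(reasons[bad], paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE
  )
  rownames(rejected) <- NULL
  list(retained = genes[!bad], rejected = rejected)
}

gene_qc_reasons <- function(gene, genome) {
  chromseq <- genome[[gene$chrom]]
  if (is.null(chromseq) || is.na(chromseq)) {
    stop("input error: gene ", gene$gene_id, ": chromosome '", gene$chrom,
         "' absent from reference")
  }
  sp <- gene_span(gene)
  if (sp[1L] < 1L || sp[2L] > nchar(chromseq)) {
    stop("input error: gene ", gene$gene_id,
         ": coordinates outside chromosome ", gene$chrom)
  }
  reasons <- character(0)
  for (tx in names(gene$isoforms)) {
    segs <- gene$isoforms[[tx]]
    len <- sum(segs$end - segs$start + 1L)
    if (len %% 3L != 0L) {
      reasons <- c(reasons, "length")
      next  # translation undefined for out-of-frame CDS
    }
    cds <- extract_cds(gene, genome, tx)
    aa <- translate_cds(cds)
    n_aa <- nchar(aa)
    if (n_aa > 1L && grepl("*", substr(aa, 1L, n_aa - 1L), fixed = TRUE)) {
      reasons <- c(reasons, "internal_stop")
    }
    first <- substr(cds, 1L, 3L)
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (first != "ATG" || !last %in% STOP_CODONS) {
      reasons <- c(reasons, "start_stop")
    }
  }
  unique(reasons)
}
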