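# Tiny constructed fixtures: a single-gene locus with explicit codons,
# exon layout and introns, on either strand, with coordinate accessors.

# codons: transcript-order codons (final one the annotated stop)
# exon_nt: CDS segment lengths in nt (transcript order; sum = CDS length)
# introns: intron sequences between consecutive exons (GT..AG)
# isoform_exons: named list of exon-index vectors (default: one isoform
#   using all exons)
build_toy_gene <- function(codons, strand = "+", exon_nt = NULL,
                           introns = NULL, flank = 15L, chrom = "chr1",
                           gene_id = "toy", isoform_exons = NULL) {
  cds <- paste(codons, collapse = "")
  if (is.null(exon_nt)) exon_nt <- nchar(cds)
  exon_nt <- as.integer(exon_nt)
  stopifnot(sum(exon_nt) == nchar(cds))
  k <- length(exon_nt)
  if (is.null(introns) && k > 1L) {
    introns <- rep("GTAAGCATTACAG", k - 1L)
  }
  exon_start <- integer(k); exon_end <- integer(k)
  intr_start <- integer(max(0L, k - 1L)); intr_end <- intr_start
  parts <- character(0)
  at <- 1L
  cds_end <- cumsum(exon_nt)
  cds_start <- c(1L, cds_end[-k] + 1L)
  for (e in seq_len(k)) {
    exon_start[e] <- at
    exon_end[e] <- at + exon_nt[e] - 1L
    parts <- c(parts, substr(cds, cds_start[e], cds_end[e]))
    at <- exon_end[e] + 1L
    if (e < k) {
      intr_start[e] <- at
      intr_end[e] <- at + nchar(introns[e]) - 1L
      parts <- c(parts, introns[e])
      at <- intr_end[e] + 1L
    }
  }
  locus <- paste(parts, collapse = "")
  len <- nchar(locus)
  insert <- if (strand == "-") revcomp(locus) else locus
  genome <- stats::setNames(paste0(strrep("C", flank), insert,
                                   strrep("C", flank)), chrom)
  l2g <- function(t) {
    if (strand == "-") flank + len - t + 1L else flank + t
  }
  if (is.null(isoform_exons)) {
    isoform_exons <- stats::setNames(list(seq_len(k)),
                                     paste0(gene_id, ".t1"))
  }
  isoforms <- lapply(isoform_exons, function(ex) {
    a <- vapply(exon_start[ex], l2g, integer(1L))
    b <- vapply(exon_end[ex], l2g, integer(1L))
    data.frame(start = pmin(a, b), end = pmax(a, b))
  })
  gene <- gene_model(gene_id, chrom, strand, isoforms)
  # genomic position of the p-th CDS base (full isoform)
  cds2g <- function(p) {
    e <- findInterval(p, cds_start)
    l2g(exon_start[e] + (p - cds_start[e]))
  }
  list(gene = gene, genome = genome, strand = strand, l2g = l2g,
       cds2g = cds2g, intr_start = intr_start, intr_end = intr_end,
       locus_len = len)
}

# a site_panel built directly from a ref base and per-strain symbols
make_site <- function(ref_base, alleles, chrom = "chr1", pos = 1L) {
  if (is.null(names(alleles))) {
    names(alleles) <- sprintf("S%03d", seq_along(alleles))
  }
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref_base = ref_base, alleles = alleles),
            class = "site_panel")
}

# sense codons (from the Biostrings genetic code, independent of the
# package's table)
SENSE <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

# a run of n safe filler codons (Gly/Ala only: no stop reachable in 1 step)
filler_codons <- function(n) rep(c("GGC", "GCC"), length.out = n)
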