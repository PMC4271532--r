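# Gene models: a gene with >= 1 isoforms, each an ordered list of CDS
# segments on reference coordinates (1-based, inclusive, as in GFF3).
# Internally segments are stored sorted by genomic start; transcription
# order is derived from the strand when sequences are extracted.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param isoforms Named list (names are transcript ids); each element a
#'   `data.frame` with integer columns `start` and `end` (1-based inclusive
#'   CDS segments in reference coordinates).
#' @param is_X Logical flag marking X-linked genes.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, isoforms, is_X = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            is.list(isoforms), length(isoforms) >= 1L,
            !is.null(names(isoforms)), !anyNA(names(isoforms)))
  isoforms <- lapply(isoforms, function(segs) {
    segs <- as.data.frame(segs)[, c("start", "end")]
    segs <- segs[order(segs$start), , drop = FALSE]
    rownames(segs) <- NULL
    if (any(segs$end < segs$start)) {
      stop("gene ", gene_id, ": segment end < start")
    }
    if (nrow(segs) > 1L && any(segs$start[-1L] <= segs$end[-nrow(segs)])) {
      stop("gene ", gene_id, ": overlapping CDS segments within an isoform")
    }
    segs
  })
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         isoforms = isoforms, is_X = isTRUE(is_X)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)%s  %d isoform(s)\n",
              x$gene_id, x$chrom, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, if (x$is_X) " [X]" else "", length(x$isoforms)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene A `gene_model`.
#' @return Integer vector `c(start, end)` over all isoforms.
#' @export
gene_span <- function(gene) {
  starts <- vapply(gene$isoforms, function(s) min(s$start), numeric(1L))
  ends <- vapply(gene$isoforms, function(s) max(s$end), numeric(1L))
  c(min(starts), max(ends))
}

#' Genomic positions of an isoform's CDS in transcription order
#'
#' For minus-strand genes the positions run 3' to 5' on the reference so
#' that element `k` is the k-th base of the spliced CDS.
#'
#' @param gene A `gene_model`.
#' @param transcript_id Transcript id; defaults to the first isoform.
#' @return Integer vector of reference coordinates.
#' @export
cds_genomic_positions <- function(gene, transcript_id = NULL) {
  segs <- isoform_segments(gene, transcript_id)
  pos <- unlist(Map(seq.int, segs$start, segs$end), use.names = FALSE)
  if (gene$strand == "-") rev(pos) else pos
}

isoform_segments <- function(gene, transcript_id = NULL) {
  if (is.null(transcript_id)) return(gene$isoforms[[1L]])
  segs <- gene$isoforms[[transcript_id]]
  if (is.null(segs)) {
    stop("gene ", gene$gene_id, ": no transcript '", transcript_id, "'")
  }
  segs
}

#' Extract the spliced CDS sequence of an isoform
#'
#' @param gene A `gene_model`.
#' @param genome Named character vector of chromosome sequences.
#' @param transcript_id Transcript id; defaults to the first isoform.
#' @return Single character string (reverse-complemented for minus-strand
#'   genes, i.e. always in reading orientation).
#' @export
extract_cds <- function(gene, genome, transcript_id = NULL) {
  chromseq <- genome[[gene$chrom]]
  if (is.null(chromseq) || is.na(chromseq)) {
    stop("gene ", gene$gene_id, ": chromosome '", gene$chrom,
         "' absent from genome")
  }
  segs <- isoform_segments(gene, transcript_id)
  if (max(segs$end) > nchar(chromseq) || min(segs$start) < 1L) {
    stop("gene ", gene$gene_id, ": coordinates outside chromosome ",
         gene$chrom)
  }
  s <- paste(substring(chromseq, segs$start, segs$end), collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

#' Introns of an isoform
#'
#' @param gene A `gene_model`.
#' @param transcript_id Transcript id; defaults to the first isoform.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive,
#'   genomic order); zero rows for single-segment isoforms.
#' @export
gene_introns <- function(gene, transcript_id = NULL) {
  segs <- isoform_segments(gene, transcript_id)
  n <- nrow(segs)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = segs$end[-n] + 1L, end = segs$start[-1L] - 1L)
}

#' Table of gene spans for a list of gene models
#' @param genes List of `gene_model` objects.
#' @return `data.frame` with `gene_id`, `chrom`, `strand`, `is_X`, `start`,
#'   `end`.
#' @export
gene_table <- function(genes) {
  spans <- vapply(genes, gene_span, numeric(2L))
  data.frame(
    gene_id = vapply(genes, `[[`, character(1L), "gene_id"),
    chrom = vapply(genes, `[[`, character(1L), "chrom"),
    strand = vapply(genes, `[[`, character(1L), "strand"),
    is_X = vapply(genes, `[[`, logical(1L), "is_X"),
    start = spans[1L, ], end = spans[2L, ],
    stringsAsFactors = FALSE
  )
}
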