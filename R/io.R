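# File-format interfaces: FASTA via Biostrings, GFF3 read via rtracklayer,
# GFF3 write as a plain 9-column formatter, tab-separated tables via utils.

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(as.list(genome)))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features with `ID`/`Parent` links, 1-based
#' inclusive coordinates.  X-linked genes carry an `is_x=1` attribute so the
#' flag round-trips.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    sp <- gene_span(g)
    xattr <- if (g$is_X) ";is_x=1" else ""
    writeLines(sprintf("%s\tptcpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       g$chrom, sp[1L], sp[2L], g$strand, g$gene_id, xattr),
               con)
    for (tx in names(g$isoforms)) {
      segs <- g$isoforms[[tx]]
      writeLines(sprintf(
        "%s\tptcpop\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, min(segs$start), max(segs$end), g$strand, tx, g$gene_id),
        con)
      # phase of each CDS segment in transcription order
      ord <- if (g$strand == "-") rev(seq_len(nrow(segs))) else
        seq_len(nrow(segs))
      lens <- segs$end - segs$start + 1L
      phase <- integer(nrow(segs))
      acc <- 0L
      for (i in ord) {
        phase[i] <- (3L - acc %% 3L) %% 3L
        acc <- acc + lens[i]
      }
      writeLines(sprintf(
        "%s\tptcpop\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
        g$chrom, segs$start, segs$end, g$strand, phase, tx, tx), con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses with [rtracklayer::import()] and rebuilds `gene_model` objects
#' from `gene`/`mRNA`/`CDS` features linked by `Parent` attributes.
#'
#' @param path GFF3 file.
#' @return List of `gene_model` objects, named by gene id.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- vapply(as.list(meta$Parent), function(p) {
    if (length(p)) as.character(p[[1L]]) else NA_character_
  }, character(1L))

  gidx <- which(type == "gene")
  tidx <- which(type == "mRNA")
  cidx <- which(type == "CDS")
  tx_gene <- stats::setNames(parents[tidx], ids[tidx])

  is_x_attr <- if ("is_x" %in% colnames(meta)) {
    stats::setNames(as.character(meta$is_x)[gidx], ids[gidx])
  } else {
    stats::setNames(rep(NA_character_, length(gidx)), ids[gidx])
  }

  cds_by_tx <- split(
    data.frame(start = GenomicRanges::start(gr)[cidx],
               end = GenomicRanges::end(gr)[cidx]),
    parents[cidx]
  )

  genes <- vector("list", length(gidx))
  names(genes) <- ids[gidx]
  for (i in seq_along(gidx)) {
    gid <- ids[gidx[i]]
    txs <- names(tx_gene)[tx_gene == gid]
    genes[[gid]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[gidx[i]],
      strand = as.character(GenomicRanges::strand(gr))[gidx[i]],
      isoforms = cds_by_tx[txs],
      is_X = !is.na(is_x_attr[[gid]]) && is_x_attr[[gid]] %in%
        c("1", "true", "TRUE")
    )
  }
  genes
}

#' Write one FASTA file per strain
#'
#' @param panel A `strain_panel`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_strain_fasta <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(panel$strains))
  for (i in seq_along(panel$strains)) {
    s <- panel$strains[i]
    genome <- vapply(panel$chroms, function(m) rawToChar(m[, i]),
                     character(1L))
    paths[i] <- file.path(dir, paste0(s, ".fasta"))
    write_genome_fasta(genome, paths[i])
  }
  invisible(paths)
}

#' Read a strain panel from per-strain FASTA files
#'
#' @param paths Named character vector of FASTA files (names are strain
#'   ids; unnamed paths use the file base name).
#' @return A `strain_panel`.
#' @export
read_strain_panel <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.fa(sta)?$", "", basename(paths))
  }
  seqs <- lapply(paths, read_genome_fasta)
  strain_panel_from_seqs(seqs)
}

#' Assemble a strain panel from in-memory sequences
#'
#' @param seqs Named list (one element per strain) of named character
#'   vectors of chromosome sequences; all strains must share identical
#'   chromosome names and lengths.
#' @return A `strain_panel`: list with `strains` (character) and `chroms`
#'   (per-chromosome raw byte matrix, positions x strains).
#' @export
strain_panel_from_seqs <- function(seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  chroms <- names(seqs[[1L]])
  mats <- lapply(chroms, function(ch) {
    cols <- lapply(seqs, function(g) {
      s <- g[[ch]]
      if (is.null(s)) stop("strain missing chromosome ", ch)
      charToRaw(s)
    })
    len <- unique(vapply(cols, length, integer(1L)))
    if (length(len) != 1L) {
      stop("chromosome ", ch, ": strain sequences differ in length")
    }
    m <- do.call(cbind, cols)
    colnames(m) <- names(seqs)
    m
  })
  names(mats) <- chroms
  structure(list(strains = names(seqs), chroms = mats),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("<strain_panel> %d strains, %d chromosome(s): %s\n",
              length(x$strains), length(x$chroms),
              paste(sprintf("%s (%d bp)", names(x$chroms),
                            vapply(x$chroms, nrow, integer(1L))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a data frame as a tab-separated file
#' @param x A data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#' @param path Input file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
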