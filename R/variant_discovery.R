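# Variant discovery: extract per-site strain genotypes from the
# pseudochromosome panel, apply the site filters (biallelic, no
# heterozygous line, >= 60 informative bases), and classify SNPs into
# synonymous / missense / nonsense (with per-isoform truncation fractions
# and the constitutive rule) / splice-disrupting / start-loss.
#
# Coordinates: all public interfaces use 1-based inclusive reference
# coordinates, as in GFF3.

#' Extract the per-strain alleles at one reference position
#'
#' Returns the raw symbols; no filtering is applied at this stage.
#'
#' @param panel A `strain_panel`.
#' @param reference Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param pos 1-based reference coordinate.
#' @return An object of class `site_panel`: list with `chrom`, `pos`,
#'   `ref_base` and `alleles` (named character vector, one symbol per
#'   strain in `{A,C,G,T,N,het-code}`).
#' @export
extract_site_panel <- function(panel, reference, chrom, pos) {
  m <- panel$chroms[[chrom]]
  if (is.null(m)) stop("input error: chromosome '", chrom, "' not in panel")
  if (pos < 1L || pos > nrow(m)) {
    stop("input error: position ", pos, " outside chromosome ", chrom)
  }
  alleles <- rawToChar(m[pos, ], multiple = TRUE)
  names(alleles) <- panel$strains
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref_base = substr(reference[[chrom]], pos, pos),
                 alleles = alleles),
            class = "site_panel")
}

#' Apply the per-site filters
#'
#' A site passes when no strain carries a heterozygote code, at least
#' `min_informative` strains carry an unambiguous base, and exactly two
#' alleles (one of them the reference base) segregate among the
#' unambiguous calls.
#'
#' @param site A `site_panel`.
#' @param min_informative Minimum number of strains with an unambiguous
#'   A/C/G/T call (default 60).
#' @return List with `pass` (logical) and `reason` (`NA` or one of
#'   `heterozygous_line`, `informative_lt_<n>`, `not_biallelic`).
#' @export
site_filters <- function(site, min_informative = 60L) {
  syms <- site$alleles
  if (any(syms %in% HET_CODES)) {
    return(list(pass = FALSE, reason = "heterozygous_line"))
  }
  informative <- sum(syms %in% DNA_BASES)
  if (informative < min_informative) {
    return(list(pass = FALSE,
                reason = sprintf("informative_lt_%d", min_informative)))
  }
  alleles <- unique(syms[syms %in% DNA_BASES])
  if (length(alleles) != 2L || !site$ref_base %in% alleles) {
    return(list(pass = FALSE, reason = "not_biallelic"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Classify a coding SNP against every isoform of a gene
#'
#' Substitutes the alternate base into the affected codon of each isoform
#' (strand-aware) and compares translations.  Per isoform: a stop gain is
#' `nonsense` with truncation fraction `(T - j) / (T - 1)` where `T` is
#' the isoform's codon count (annotated stop included) and `j` the 1-based
#' index of the new stop codon; an amino-acid change is `missense`; a
#' silent change is `synonymous`.  A substitution creating a stop at the
#' annotated stop position is not premature and positions whose reference
#' codon is already a stop are classified `other`.  The SNP is
#' `constitutive` when it is a stop gain in every isoform.
#'
#' @param site A `site_panel` (or list with `chrom`, `pos`, `ref_base`).
#' @param gene A `gene_model` overlapping the site.
#' @param reference Named character vector of chromosome sequences.
#' @param alt Alternate base on the reference strand; by default the
#'   unique non-reference base observed in `site$alleles`.
#' @return An object of class `classified_snp`: list with `chrom`, `pos`,
#'   `ref`, `alt`, `gene_id`, `site_class`, `per_isoform` (`data.frame`
#'   with `transcript_id`, `in_cds`, `class`, `disrupts`,
#'   `truncation_fraction`), `constitutive`, `min_truncation`.
#' @export
classify_coding_snp <- function(site, gene, reference, alt = NULL) {
  ref <- site$ref_base
  if (is.null(alt)) {
    obs <- unique(site$alleles[site$alleles %in% DNA_BASES])
    alt <- setdiff(obs, ref)
    if (length(alt) != 1L) {
      stop("input error: site ", site$chrom, ":", site$pos,
           " is not biallelic; pass `alt` explicitly")
    }
  }
  per <- lapply(names(gene$isoforms), function(tx) {
    posvec <- cds_genomic_positions(gene, tx)
    k <- match(site$pos, posvec)
    if (is.na(k)) {
      return(data.frame(transcript_id = tx, in_cds = FALSE, class = "other",
                        disrupts = FALSE, truncation_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    cds <- extract_cds(gene, reference, tx)
    codons <- codons_of(cds)
    T_codons <- length(codons)
    j <- (k - 1L) %/% 3L + 1L
    off <- (k - 1L) %% 3L + 1L
    ref_codon <- codons[j]
    alt_t <- if (gene$strand == "-") comp_base(alt) else alt
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt_t
    ref_aa <- unname(CODON_TABLE[ref_codon])
    alt_aa <- unname(CODON_TABLE[alt_codon])
    cls <- if (is.na(ref_aa) || ref_aa == "*") {
      "other"
    } else if (is.na(alt_aa)) {
      "other"
    } else if (alt_aa == "*") {
      "nonsense"
    } else if (alt_aa != ref_aa) {
      "missense"
    } else {
      "synonymous"
    }
    data.frame(transcript_id = tx, in_cds = TRUE, class = cls,
               disrupts = cls == "nonsense",
               truncation_fraction = if (cls == "nonsense") {
                 (T_codons - j) / (T_codons - 1L)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  site_class <- if (any(per$class == "nonsense")) "nonsense"
  else if (any(per$class == "missense")) "missense"
  else if (any(per$class == "synonymous")) "synonymous"
  else "other"
  disrupted <- per$truncation_fraction[per$disrupts]
  structure(list(chrom = site$chrom, pos = site$pos, ref = ref, alt = alt,
                 gene_id = gene$gene_id, site_class = site_class,
                 per_isoform = per,
                 constitutive = all(per$disrupts),
                 min_truncation = if (length(disrupted)) min(disrupted)
                 else NA_real_),
            class = "classified_snp")
}

#' @export
print.classified_snp <- function(x, ...) {
  cat(sprintf("<classified_snp> %s:%d %s>%s gene %s: %s%s\n",
              x$chrom, x$pos, x$ref, x$alt, x$gene_id, x$site_class,
              if (isTRUE(x$constitutive)) " (constitutive)" else ""))
  invisible(x)
}

#' Decide whether a classified SNP is an acceptable constitutive PTC
#'
#' Accepts iff the SNP is a stop gain in every isoform and removes at
#' least `min_truncation` (default 5%) of the coding region in each
#' isoform.
#'
#' @param snp A `classified_snp`.
#' @param min_truncation Minimum truncation fraction (inclusive bound).
#' @return List with `accept` (logical) and `reason` (`NA`,
#'   `not_nonsense`, `not_constitutive` or `truncation_lt_min`).
#' @export
call_constitutive_ptc <- function(snp, min_truncation = 0.05) {
  if (snp$site_class != "nonsense") {
    return(list(accept = FALSE, reason = "not_nonsense"))
  }
  if (!snp$constitutive) {
    return(list(accept = FALSE, reason = "not_constitutive"))
  }
  worst <- min(snp$per_isoform$truncation_fraction[snp$per_isoform$disrupts])
  if (worst < min_truncation) {
    return(list(accept = FALSE, reason = "truncation_lt_min"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Flag splice-site disruption
#'
#' Flags substitutions that change one of the first two or last two bases
#' of any intron of any isoform (the canonical GT/AG dinucleotides).
#'
#' @param site A `site_panel` (or list with `pos`, `ref_base`).
#' @param gene A `gene_model`.
#' @param alt Alternate base; defaults to the unique non-reference allele.
#' @return Logical flag.
#' @export
call_splice_disruption <- function(site, gene, alt = NULL) {
  if (is.null(alt)) {
    obs <- unique(site$alleles[site$alleles %in% DNA_BASES])
    alt <- setdiff(obs, site$ref_base)[1L]
  }
  if (is.na(alt) || identical(alt, site$ref_base)) return(FALSE)
  for (tx in names(gene$isoforms)) {
    intr <- gene_introns(gene, tx)
    if (!nrow(intr)) next
    boundary <- c(intr$start, intr$start + 1L, intr$end - 1L, intr$end)
    if (site$pos %in% boundary) return(TRUE)
  }
  FALSE
}

#' Flag constitutive start-codon loss
#'
#' Flags substitutions inside the ATG start codon of every isoform (the
#' same constitutive logic as for PTCs; a change in only some isoforms is
#' not flagged).  Any base change in ATG destroys the start codon.
#'
#' @param site A `site_panel` (or list with `pos`, `ref_base`).
#' @param gene A `gene_model`.
#' @param alt Alternate base; defaults to the unique non-reference allele.
#' @return Logical flag.
#' @export
call_start_loss <- function(site, gene, alt = NULL) {
  if (is.null(alt)) {
    obs <- unique(site$alleles[site$alleles %in% DNA_BASES])
    alt <- setdiff(obs, site$ref_base)[1L]
  }
  if (is.na(alt) || identical(alt, site$ref_base)) return(FALSE)
  all(vapply(names(gene$isoforms), function(tx) {
    site$pos %in% cds_genomic_positions(gene, tx)[1:3]
  }, logical(1L)))
}

#' Scan a strain panel for classified variants
#'
#' Finds every position inside a gene span where any strain differs from
#' the reference, applies the site filters, classifies coding changes
#' against all isoforms of the overlapping gene(s), flags splice and
#' start-codon disruption, and applies the constitutive-PTC rule.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param genes List of `gene_model` objects (post annotation QC).
#' @param panel A `strain_panel` whose sequences have the same length as
#'   the reference chromosomes.
#' @param min_informative Informative-base filter threshold (default 60).
#' @param min_truncation Minimum truncation fraction for a PTC call
#'   (default 0.05).
#' @return `data.frame` with one row per (site, gene): `chrom`, `pos`,
#'   `ref`, `alt`, `gene_id`, `class` (`nonsense`, `missense`,
#'   `synonymous`, `splice`, `start_loss`, `other`), `constitutive`,
#'   `min_truncation`, `n_informative`, `filter` (`PASS` or the fail
#'   reason), `splice_flag`, `start_loss_flag`, `ptc_call`.
#' @export
discover_variants <- function(reference, genes, panel,
                              min_informative = 60L,
                              min_truncation = 0.05) {
  gt <- gene_table(genes)
  gene_ids <- gt$gene_id
  rows_out <- list()

  for (ch in names(panel$chroms)) {
    sub <- gt[gt$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    m <- panel$chroms[[ch]]
    if (nrow(m) != nchar(reference[[ch]])) {
      stop("input error: panel and reference lengths differ on ", ch)
    }
    ref_raw <- charToRaw(reference[[ch]])
    spans <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    scan_rows <- unlist(Map(seq.int, IRanges::start(spans),
                            IRanges::end(spans)), use.names = FALSE)
    mm <- m[scan_rows, , drop = FALSE] != ref_raw[scan_rows]
    poly <- scan_rows[rowSums(mm) > 0L]
    if (!length(poly)) next

    ir_genes <- IRanges::IRanges(sub$start, sub$end)
    hits <- IRanges::findOverlaps(IRanges::IRanges(poly, poly), ir_genes)

    for (h in seq_along(S4Vectors::queryHits(hits))) {
      pos <- poly[S4Vectors::queryHits(hits)[h]]
      gene <- genes[[match(sub$gene_id[S4Vectors::subjectHits(hits)[h]],
                           gene_ids)]]
      site <- extract_site_panel(panel, reference, ch, pos)
      acgt <- site$alleles[site$alleles %in% DNA_BASES]
      non_ref <- setdiff(unique(acgt), site$ref_base)
      if (!length(non_ref)) next  # only masks/hets differ: not a SNP
      if (length(unique(acgt)) < 2L) next  # monomorphic in the sample
      # for reporting on multi-allelic sites, take the most frequent alt
      alt <- names(sort(table(acgt[acgt != site$ref_base]),
                        decreasing = TRUE))[1L]
      filt <- site_filters(site, min_informative)
      splice <- call_splice_disruption(site, gene, alt)
      startl <- call_start_loss(site, gene, alt)
      in_cds <- any(vapply(names(gene$isoforms), function(tx) {
        site$pos %in% cds_genomic_positions(gene, tx)
      }, logical(1L)))
      snp <- if (in_cds) classify_coding_snp(site, gene, reference, alt)
      else NULL
      cls <- if (!is.null(snp) && snp$site_class == "nonsense") "nonsense"
      else if (startl) "start_loss"
      else if (splice) "splice"
      else if (!is.null(snp)) snp$site_class
      else "other"
      constitutive <- if (cls == "nonsense") snp$constitutive
      else if (cls == "start_loss") TRUE
      else NA
      min_trunc <- if (!is.null(snp)) snp$min_truncation else NA_real_
      ptc <- isTRUE(filt$pass) && cls == "nonsense" &&
        isTRUE(constitutive) && isTRUE(min_trunc >= min_truncation)
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        chrom = ch, pos = pos, ref = site$ref_base, alt = alt,
        gene_id = gene$gene_id, class = cls, constitutive = constitutive,
        min_truncation = min_trunc,
        n_informative = sum(site$alleles %in% DNA_BASES),
        filter = if (filt$pass) "PASS" else filt$reason,
        splice_flag = splice, start_loss_flag = startl, ptc_call = ptc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows_out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), class = character(0),
                      constitutive = logical(0), min_truncation = numeric(0),
                      n_informative = integer(0), filter = character(0),
                      splice_flag = logical(0), start_loss_flag = logical(0),
                      ptc_call = logical(0)))
  }
  out <- do.call(rbind, rows_out)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
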