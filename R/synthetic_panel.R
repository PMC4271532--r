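# Strain-panel and outgroup generators: realize planted variants at their
# target derived allele frequencies across strains, inject IUPAC
# heterozygote codes and N masks, and emit outgroup base calls that make
# sites polarizable or not by construction.

IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_pair <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  code <- IUPAC_PAIR[key]
  code[is.na(code)] <- "N"
  unname(code)
}

#' Generate a strain pseudochromosome panel with planted truth
#'
#' Copies the reference into `n_strains` pseudochromosomes, realizes each
#' planted variant in `round(target_daf * n_strains)` randomly chosen
#' carrier strains, then injects heterozygote codes and N masks at the
#' configured per-cell rates (never at planted sites, so realized allele
#' counts stay exact).
#'
#' @param reference Result of [generate_reference()].
#' @param config The same [synthetic_config()].
#' @return List with `panel` (a `strain_panel`) and `truth` (the reference
#'   truth table plus `n_derived`, `realized_daf` and a `;`-separated
#'   `carriers` column).
#' @export
generate_strain_panel <- function(reference, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_strains
    strains <- sprintf("RAL%03d", seq_len(n))
    chroms <- lapply(reference$genome, function(s) {
      matrix(charToRaw(s), ncol = n, nrow = nchar(s),
             dimnames = list(NULL, strains))
    })
    truth <- reference$truth
    truth$n_derived <- as.integer(round(truth$target_daf * n))
    truth$carriers <- rep("", nrow(truth))
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        nd <- truth$n_derived[i]
        if (nd == 0L) next
        carriers <- sample(strains, nd)
        chroms[[truth$chrom[i]]][truth$pos[i], carriers] <-
          charToRaw(truth$alt[i])
        truth$carriers[i] <- paste(sort(carriers), collapse = ";")
      }
    }
    truth$realized_daf <- truth$n_derived / n

    # masks and heterozygote codes at non-planted cells
    for (ch in names(chroms)) {
      m <- chroms[[ch]]
      cells <- length(m)
      planted_rows <- truth$pos[truth$chrom == ch]
      pick_cells <- function(count) {
        if (count == 0L) return(integer(0))
        idx <- sample.int(cells, count)
        keep <- !(((idx - 1L) %% nrow(m)) + 1L) %in% planted_rows
        idx[keep]
      }
      if (config$n_mask_rate > 0) {
        idx <- pick_cells(stats::rbinom(1L, cells, config$n_mask_rate))
        m[idx] <- charToRaw("N")
      }
      if (config$het_rate > 0) {
        idx <- pick_cells(stats::rbinom(1L, cells, config$het_rate))
        if (length(idx)) {
          ref_b <- rawToChar(m[idx], multiple = TRUE)
          idx <- idx[ref_b %in% DNA_BASES]
          ref_b <- ref_b[ref_b %in% DNA_BASES]
        }
        if (length(idx)) {
          other <- vapply(ref_b, function(b) {
            sample(setdiff(DNA_BASES, b), 1L)
          }, character(1L))
          m[idx] <- vapply(iupac_pair(ref_b, other), charToRaw, raw(1L))
        }
      }
      chroms[[ch]] <- m
    }
    list(panel = structure(list(strains = strains, chroms = chroms),
                           class = "strain_panel"),
         truth = truth)
  })
}

#' Generate outgroup base calls at the planted sites
#'
#' For sites planted with `ancestral_is_ref = TRUE` both outgroups carry
#' the reference base (the site is polarizable and the alternate allele is
#' derived); for `ancestral_is_ref = FALSE` both outgroups carry the
#' alternate base, which the conservative reference-anchored rule refuses
#' to polarize.  Each outgroup base is then independently substituted with
#' probability `config$outgroup_divergence`, so a configured fraction of
#' sites becomes unpolarizable through outgroup disagreement.
#'
#' @param reference Result of [generate_reference()].
#' @param truth Truth table (from [generate_strain_panel()] or the
#'   reference skeleton).
#' @param config The same [synthetic_config()].
#' @return `data.frame` with `chrom`, `pos`, `og1`, `og2`.
#' @export
generate_outgroups <- function(reference, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 2L, {
    anc <- ifelse(truth$ancestral_is_ref, truth$ref, truth$alt)
    mutate <- function(b) {
      hit <- stats::runif(length(b)) < config$outgroup_divergence
      b[hit] <- vapply(b[hit], function(x) sample(setdiff(DNA_BASES, x), 1L),
                       character(1L))
      b
    }
    data.frame(chrom = truth$chrom, pos = truth$pos,
               og1 = mutate(anc), og2 = mutate(anc),
               stringsAsFactors = FALSE)
  })
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper chaining [generate_reference()],
#' [generate_strain_panel()] and [generate_outgroups()].
#'
#' @param config A [synthetic_config()].
#' @return List with `genome`, `genes`, `panel`, `truth`, `outgroups`,
#'   `config`.
#' @export
simulate_ptc_study <- function(config) {
  ref <- generate_reference(config)
  sp <- generate_strain_panel(ref, config)
  og <- generate_outgroups(ref, sp$truth, config)
  list(genome = ref$genome, genes = ref$genes, panel = sp$panel,
       truth = sp$truth, outgroups = og, config = config)
}
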