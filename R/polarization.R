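# Polarization: infer ancestral/derived alleles from two outgroups with
# the conservative reference-anchored rule, compute derived allele
# frequencies over unambiguous calls only, and assign frequency groups.

#' Infer the derived allele from two outgroup bases
#'
#' A polymorphism is polarized if and only if the reference base and both
#' outgroup bases are identical; the alternate allele is then derived.
#' Sites where the alternate allele (rather than the reference) matches
#' both outgroups are left unpolarized: the rule is anchored on the
#' reference base, which is the conservative reading adopted here.
#'
#' @param ref_base,alt_base The two segregating alleles.
#' @param outgroup1_base,outgroup2_base Outgroup base calls (`NA`/`N`
#'   allowed).
#' @return List with `polarized` (logical), `ancestral`, `derived`
#'   (`NA` when unpolarized).
#' @export
infer_ancestral <- function(ref_base, alt_base, outgroup1_base,
                            outgroup2_base) {
  ok <- !is.na(outgroup1_base) && !is.na(outgroup2_base) &&
    outgroup1_base %in% DNA_BASES && outgroup2_base %in% DNA_BASES &&
    outgroup1_base == ref_base && outgroup2_base == ref_base
  if (ok) {
    list(polarized = TRUE, ancestral = ref_base, derived = alt_base)
  } else {
    list(polarized = FALSE, ancestral = NA_character_,
         derived = NA_character_)
  }
}

#' Derived allele frequency at a site
#'
#' Counts over unambiguous A/C/G/T calls only; N and heterozygote codes
#' are discarded from both numerator and denominator.
#'
#' @param site A `site_panel`.
#' @param derived The derived base.
#' @return List with `n_derived`, `n_informative`, `daf`.
#' @export
compute_daf <- function(site, derived) {
  acgt <- site$alleles[site$alleles %in% DNA_BASES]
  n_inf <- length(acgt)
  n_der <- sum(acgt == derived)
  list(n_derived = n_der, n_informative = n_inf,
       daf = if (n_inf > 0L) n_der / n_inf else NA_real_)
}

#' Assign derived-allele-frequency groups
#'
#' Bins: low (0, 1.5%], moderate (1.5%, 10%], high (10%, 100%].  Both
#' boundaries are inclusive on the left-hand group, so a DAF of exactly
#' 1.5% is low and exactly 10% is moderate.
#'
#' @param daf Numeric vector of derived allele frequencies in `[0, 1]`.
#' @param low_cut,high_cut Group boundaries (defaults 0.015 and 0.10).
#' @return Character vector in `{low, moderate, high}` (`NA` in, `NA`
#'   out).
#' @export
assign_frequency_group <- function(daf, low_cut = 0.015, high_cut = 0.10) {
  ifelse(is.na(daf), NA_character_,
         ifelse(daf <= low_cut, "low",
                ifelse(daf <= high_cut, "moderate", "high")))
}

#' Polarize classified variants against an outgroup table
#'
#' Joins the discovered variants with the per-site outgroup calls,
#' applies [infer_ancestral()], recomputes allele counts from the panel,
#' and assigns frequency groups.  Unpolarized variants get frequency
#' group `"unassigned"` and `NA` counts.
#'
#' @param variants `data.frame` from [discover_variants()].
#' @param panel The `strain_panel` the variants were called from.
#' @param reference Named character vector of chromosome sequences.
#' @param outgroups `data.frame` with `chrom`, `pos`, `og1`, `og2`.
#' @return `variants` with added columns `anc`, `der`, `n_der`, `n_inf`,
#'   `daf`, `freq_group`.
#' @export
polarize_variants <- function(variants, panel, reference, outgroups) {
  key <- paste(variants$chrom, variants$pos)
  og_key <- paste(outgroups$chrom, outgroups$pos)
  idx <- match(key, og_key)
  n <- nrow(variants)
  anc <- der <- rep(NA_character_, n)
  n_der <- n_inf <- rep(NA_integer_, n)
  daf <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    og1 <- if (is.na(idx[i])) NA_character_ else outgroups$og1[idx[i]]
    og2 <- if (is.na(idx[i])) NA_character_ else outgroups$og2[idx[i]]
    pol <- infer_ancestral(variants$ref[i], variants$alt[i], og1, og2)
    if (!pol$polarized) next
    anc[i] <- pol$ancestral
    der[i] <- pol$derived
    site <- extract_site_panel(panel, reference, variants$chrom[i],
                               variants$pos[i])
    cnt <- compute_daf(site, pol$derived)
    n_der[i] <- cnt$n_derived
    n_inf[i] <- cnt$n_informative
    daf[i] <- cnt$daf
  }
  variants$anc <- anc
  variants$der <- der
  variants$n_der <- n_der
  variants$n_inf <- n_inf
  variants$daf <- daf
  grp <- assign_frequency_group(daf)
  grp[is.na(grp)] <- "unassigned"
  variants$freq_group <- grp
  variants
}

#' Normalized derived-allele-frequency spectrum
#'
#' @param daf Numeric vector of DAFs, or a `data.frame` with columns
#'   `daf` and `class` (one spectrum per class).
#' @param breaks Bin boundaries passed to [cut()]; bins are
#'   left-open/right-closed except the first, which includes its left
#'   edge.
#' @return Named numeric vector of bin proportions, or a matrix with one
#'   row per class.  Empty input gives all-`NaN`-free zero counts of
#'   length `length(breaks) - 1`.
#' @export
daf_spectrum <- function(daf, breaks = seq(0, 1, by = 0.05)) {
  bin_one <- function(x) {
    x <- x[!is.na(x)]
    cts <- table(cut(x, breaks, include.lowest = TRUE))
    if (length(x) == 0L) return(stats::setNames(rep(0, length(cts)),
                                                names(cts)))
    as.numeric(cts) / length(x) -> p
    stats::setNames(p, names(cts))
  }
  if (is.data.frame(daf)) {
    classes <- sort(unique(daf$class))
    out <- t(vapply(classes, function(cl) bin_one(daf$daf[daf$class == cl]),
                    numeric(length(breaks) - 1L)))
    rownames(out) <- classes
    out
  } else {
    bin_one(daf)
  }
}

#' Draw a frequency-matched control sample
#'
#' Draws `n` variants from `pool` whose DAF multiset matches the
#' template's: the template DAFs are recycled to length `n` and each is
#' matched to the still-unused pool variant with the nearest DAF
#' (replacement forbidden; exact matches are preferred, ties broken at
#' random).
#'
#' @param pool_daf Numeric vector of candidate-variant DAFs.
#' @param template_daf Numeric vector of DAFs to match.
#' @param n Sample size (must not exceed `length(pool_daf)`).
#' @param seed Integer seed.
#' @return Integer vector of `n` distinct indices into `pool_daf`.
#' @export
daf_matched_sample <- function(pool_daf, template_daf, n = length(template_daf),
                               seed = 1L) {
  if (n > length(pool_daf)) {
    stop("input error: pool smaller than requested sample")
  }
  withr::with_seed(seed, {
    targets <- rep(template_daf, length.out = n)
    targets <- targets[sample.int(n)]
    free <- rep(TRUE, length(pool_daf))
    picked <- integer(n)
    for (i in seq_len(n)) {
      d <- abs(pool_daf - targets[i])
      d[!free] <- Inf
      best <- which(d == min(d))
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      picked[i] <- pick
      free[pick] <- FALSE
    }
    picked
  })
}
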