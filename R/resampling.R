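# False-positive-rate stratified resampling: generate pseudo datasets by
# randomly removing called variants at group-specific estimated FPRs and
# re-run summary statistics across replicates to check that the headline
# conclusions are stable.

#' Configuration for FPR-stratified resampling
#'
#' @param fpr_by_group Named numeric vector of per-frequency-group false
#'   positive rates; the defaults are the validation-derived estimates
#'   20% / 13% / 0% for the low / moderate / high groups.
#' @param n_replicates Number of pseudo datasets (default 100).
#' @param seed Integer seed.
#' @param fixed_count If `TRUE`, remove exactly `round(fpr * n)` variants
#'   per group instead of independent Bernoulli removal.
#' @return An object of class `resampling_config`.
#' @export
resampling_config <- function(fpr_by_group = c(low = 0.20, moderate = 0.13,
                                               high = 0.0),
                              n_replicates = 100L, seed = 1L,
                              fixed_count = FALSE) {
  if (any(fpr_by_group < 0 | fpr_by_group > 1)) {
    stop("configuration error: FPRs must lie in [0, 1]")
  }
  structure(list(fpr_by_group = fpr_by_group,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 fixed_count = isTRUE(fixed_count)),
            class = "resampling_config")
}

#' One FPR-stratified pseudo dataset
#'
#' Each variant is independently retained with probability
#' `1 - fpr(group)` (or, in fixed-count mode, exactly
#' `round(fpr * n_group)` variants are removed per group).  Fully
#' deterministic given `(config$seed, replicate_index)`.
#'
#' @param variants `data.frame` with a `freq_group` column; groups absent
#'   from `config$fpr_by_group` are always retained.
#' @param config A [resampling_config()].
#' @param replicate_index Replicate number (1-based).
#' @return The retained subset of `variants`.
#' @export
make_pseudo_dataset <- function(variants, config, replicate_index = 1L) {
  stopifnot(inherits(config, "resampling_config"))
  fpr <- config$fpr_by_group[variants$freq_group]
  fpr[is.na(fpr)] <- 0
  withr::with_seed(config$seed + 1000L * replicate_index, {
    keep <- if (config$fixed_count) {
      k <- rep(TRUE, nrow(variants))
      for (g in names(config$fpr_by_group)) {
        idx <- which(variants$freq_group == g)
        n_drop <- round(config$fpr_by_group[[g]] * length(idx))
        if (n_drop > 0L) k[idx[sample.int(length(idx), n_drop)]] <- FALSE
      }
      k
    } else {
      stats::runif(nrow(variants)) >= fpr
    }
    variants[keep, , drop = FALSE]
  })
}

#' Summary-statistic distribution over resampled pseudo datasets
#'
#' Applies `summary_fn` to each pseudo dataset and reports the
#' per-statistic median and 2.5-97.5 percentile band, plus the fraction
#' of replicates in which each user-supplied inequality holds.
#'
#' @param variants `data.frame` with a `freq_group` column.
#' @param config A [resampling_config()].
#' @param summary_fn Function mapping a variant subset to a named numeric
#'   vector.
#' @param checks Optional named list of functions mapping the summary
#'   vector to a logical (headline inequalities to track).
#' @return List with `replicates` (matrix, one row per replicate),
#'   `stats` (`data.frame`: `statistic`, `median`, `lower`, `upper`) and
#'   `check_fractions` (named numeric, `NULL` when no checks given).
#' @export
resampled_summary <- function(variants, config, summary_fn, checks = NULL) {
  stopifnot(inherits(config, "resampling_config"))
  rows <- lapply(seq_len(config$n_replicates), function(i) {
    summary_fn(make_pseudo_dataset(variants, config, i))
  })
  reps <- do.call(rbind, rows)
  qs <- apply(reps, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  stats_df <- data.frame(statistic = colnames(reps),
                         median = qs[2L, ], lower = qs[1L, ],
                         upper = qs[3L, ], row.names = NULL,
                         stringsAsFactors = FALSE)
  check_fractions <- NULL
  if (!is.null(checks)) {
    check_fractions <- vapply(checks, function(f) {
      mean(apply(reps, 1L, function(r) isTRUE(f(r))))
    }, numeric(1L))
  }
  list(replicates = reps, stats = stats_df,
       check_fractions = check_fractions)
}
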