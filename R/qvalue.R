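# Storey q-values with the fixed-lambda pi0 estimator.  The fixed
# lambda = 0.5 estimator is used instead of the spline extrapolation: it
# is reproducible on small variant sets and asymptotically close.

#' Storey q-values (fixed-lambda pi0 estimator)
#'
#' Estimates the null proportion as
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` with `lambda = 0.5`
#' and converts p-values to q-values by the step-up construction
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`.
#'
#' @param p Numeric vector of p-values.
#' @param lambda Tuning parameter of the pi0 estimator (default 0.5).
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalue_storey <- function(p, lambda = 0.5) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  m <- sum(!is.na(p))
  if (m == 0L) return(p)
  pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
  ord <- order(p, na.last = NA)
  q_ord <- pi0 * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- rep(NA_real_, length(p))
  q[ord] <- pmin(q_ord, 1)
  q
}
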