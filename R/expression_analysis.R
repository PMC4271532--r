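# Expression analysis: expression breadth (all-replicates present rule),
# quantile-normalized discretized profiles, the tissue-specificity index
# tau computed on those profiles, top-tissue assignment, and the
# per-variant allele-imbalance (Wilcoxon) test with Storey q-values.

#' Expression breadth per gene
#'
#' A tissue counts toward a gene's breadth iff the gene is called present
#' in ALL replicate arrays of that tissue.
#'
#' @param expr An `expression_set` (see [generate_expression_matrix()]),
#'   or any list with `present` (genes x arrays logical matrix) and
#'   `tissue` (per-column tissue label).
#' @return Named integer vector (tissues per gene).
#' @export
expression_breadth <- function(expr) {
  pt <- present_by_tissue(expr)
  stats::setNames(as.integer(rowSums(pt)), rownames(pt))
}

present_by_tissue <- function(expr) {
  tissues <- unique(expr$tissue)
  out <- vapply(tissues, function(ts) {
    rowSums(!expr$present[, expr$tissue == ts, drop = FALSE]) == 0L
  }, logical(nrow(expr$present)))
  out <- matrix(out, nrow = nrow(expr$present), ncol = length(tissues),
                dimnames = list(rownames(expr$present), tissues))
  out
}

#' Quantile-normalized, decile-discretized expression profiles
#'
#' Per array: log10-transform, subtract the array mean and add the grand
#' mean over all arrays.  Per tissue, the gene's tissue-level value is the
#' median of its normalized replicate values; genes present in all
#' replicates of the tissue are then split into ten equal-density groups
#' by that value (group 1 lowest, 10 highest; group sizes differ by at
#' most one gene), and absent genes are assigned group 0.  Ties at decile
#' boundaries are resolved deterministically by (value, gene id) order.
#'
#' @param expr An `expression_set` (or list with `values`, `present`,
#'   `tissue`).
#' @return List with `profile` (integer matrix genes x tissues, values
#'   0-10), `tissue_value` (numeric matrix of normalized per-tissue
#'   medians) and `present_tissue` (logical matrix).
#' @export
quantile_normalize_profiles <- function(expr) {
  v <- expr$values
  if (any(v <= 0 & expr$present)) {
    stop("input error: non-positive expression value flagged present")
  }
  v[v <= 0] <- NA_real_
  logv <- log10(v)
  arr_mean <- colMeans(logv, na.rm = TRUE)
  norm <- sweep(logv, 2L, arr_mean) + mean(logv, na.rm = TRUE)

  tissues <- unique(expr$tissue)
  tissue_value <- vapply(tissues, function(ts) {
    apply(norm[, expr$tissue == ts, drop = FALSE], 1L, stats::median,
          na.rm = TRUE)
  }, numeric(nrow(norm)))
  dimnames(tissue_value) <- list(rownames(v), tissues)
  present_tissue <- present_by_tissue(expr)

  profile <- matrix(0L, nrow = nrow(v), ncol = length(tissues),
                    dimnames = list(rownames(v), tissues))
  for (ts in tissues) {
    idx <- which(present_tissue[, ts])
    np <- length(idx)
    if (!np) next
    ord <- idx[order(tissue_value[idx, ts], rownames(v)[idx])]
    profile[ord, ts] <- as.integer(ceiling(10 * seq_len(np) / np))
  }
  list(profile = profile, tissue_value = tissue_value,
       present_tissue = present_tissue)
}

#' Tissue-specificity index tau on a discretized profile
#'
#' `tau = sum_i (1 - x_i / x_max) / (N - 1)` over all `N` tissues
#' (group-0 tissues included).  Undefined (`NA`) when every group is 0,
#' since the maximum in the denominator vanishes.
#'
#' @param profile Numeric vector of per-tissue quantile groups (0-10), or
#'   a matrix with genes in rows.
#' @return Numeric tau in `[0, 1]` (or vector over rows), `NA` where
#'   undefined.
#' @export
compute_tau <- function(profile) {
  tau_one <- function(x) {
    if (length(x) < 2L) stop("input error: tau needs >= 2 tissues")
    xmax <- max(x)
    if (xmax == 0) return(NA_real_)
    sum(1 - x / xmax) / (length(x) - 1L)
  }
  if (is.matrix(profile)) {
    apply(profile, 1L, tau_one)
  } else {
    tau_one(profile)
  }
}

#' Top expressing tissue per gene
#'
#' The tissue with the highest median-over-replicates expression among
#' tissues passing the all-replicates present rule;  `"no_expression"`
#' when no tissue passes.  Ties go to the lexicographically smallest
#' tissue label and are reported in the `tie` column.
#'
#' @param qn Result of [quantile_normalize_profiles()].
#' @return `data.frame` with `gene_id`, `top_tissue`, `tie` (logical).
#' @export
top_tissue <- function(qn) {
  genes <- rownames(qn$tissue_value)
  tissues <- colnames(qn$tissue_value)
  top <- rep("no_expression", length(genes))
  tie <- rep(FALSE, length(genes))
  for (i in seq_along(genes)) {
    ok <- which(qn$present_tissue[i, ])
    if (!length(ok)) next
    vals <- qn$tissue_value[i, ok]
    best <- ok[vals == max(vals)]
    if (length(best) > 1L) tie[i] <- TRUE
    top[i] <- sort(tissues[best])[1L]
  }
  data.frame(gene_id = genes, top_tissue = top, tie = tie,
             stringsAsFactors = FALSE)
}

#' Per-gene expression summary
#'
#' Convenience wrapper combining breadth, tau and top tissue.
#'
#' @param expr An `expression_set`.
#' @return `data.frame` with `gene_id`, `breadth`, `tau`, `top_tissue`,
#'   plus the quantile profile matrix as attribute `"profile"`.
#' @export
summarize_expression <- function(expr) {
  qn <- quantile_normalize_profiles(expr)
  tt <- top_tissue(qn)
  out <- data.frame(gene_id = rownames(expr$values),
                    breadth = unname(expression_breadth(expr)),
                    tau = unname(compute_tau(qn$profile)),
                    top_tissue = tt$top_tissue,
                    stringsAsFactors = FALSE)
  attr(out, "profile") <- qn$profile
  out
}

#' Tissue-specific gene set by tau cutoff
#'
#' Genes with defined tau strictly greater than the cutoff (default
#' 0.85); genes with undefined tau are excluded.
#'
#' @param summaries `data.frame` from [summarize_expression()].
#' @param tau_cutoff Exclusive lower bound on tau.
#' @return Character vector of gene ids.
#' @export
tissue_specific_set <- function(summaries, tau_cutoff = 0.85) {
  summaries$gene_id[!is.na(summaries$tau) & summaries$tau > tau_cutoff]
}

#' Allele-imbalance test between derived and ancestral strains
#'
#' For each variant, compares the host gene's expression between strains
#' carrying the derived allele and strains carrying the ancestral allele
#' with a two-sided Wilcoxon rank-sum test; q-values over all tested
#' variants follow the fixed-lambda Storey estimator (see
#' [qvalue_storey()]).  Variants with fewer than `min_per_class` strains
#' in either class are skipped (row kept, `NA` statistics, `skipped =
#' TRUE`).
#'
#' @param variants `data.frame` with columns `gene_id` and `carriers`
#'   (`;`-separated derived-allele strain ids).
#' @param strain_expr Numeric matrix genes x strains.
#' @param min_per_class Minimum strains per allele class (default 2).
#' @param fdr_threshold Significance threshold on the q-value (default
#'   0.05).
#' @return `data.frame` with `gene_id`, `n_derived`, `n_ancestral`, `p`,
#'   `q`, `direction` (`lower_in_derived`, `lower_in_ancestral`,
#'   `none`), `significant`, `skipped`.
#' @export
allele_imbalance_test <- function(variants, strain_expr,
                                  min_per_class = 2L,
                                  fdr_threshold = 0.05) {
  strains <- colnames(strain_expr)
  n <- nrow(variants)
  p <- rep(NA_real_, n)
  dir <- rep("none", n)
  nd <- na <- rep(NA_integer_, n)
  skipped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    gid <- variants$gene_id[i]
    carr <- intersect(strsplit(variants$carriers[i], ";",
                               fixed = TRUE)[[1L]], strains)
    anc <- setdiff(strains, carr)
    if (!gid %in% rownames(strain_expr) ||
        length(carr) < min_per_class || length(anc) < min_per_class) {
      skipped[i] <- TRUE
      next
    }
    x <- strain_expr[gid, carr]
    y <- strain_expr[gid, anc]
    nd[i] <- length(carr)
    na[i] <- length(anc)
    p[i] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    if (is.na(p[i])) p[i] <- 1
    mx <- stats::median(x); my <- stats::median(y)
    dir[i] <- if (mx < my) "lower_in_derived"
    else if (my < mx) "lower_in_ancestral" else "none"
  }
  q <- rep(NA_real_, n)
  tested <- which(!skipped)
  if (length(tested)) q[tested] <- qvalue_storey(p[tested])
  data.frame(gene_id = variants$gene_id, n_derived = nd, n_ancestral = na,
             p = p, q = q, direction = dir,
             significant = !is.na(q) & q < fdr_threshold,
             skipped = skipped, stringsAsFactors = FALSE)
}
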