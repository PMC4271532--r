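# Statistical layer: simultaneous multinomial confidence ribbon for
# top-tissue category counts, Fisher exact tests for group-wise
# enrichments, per-group top-tissue reports and X-vs-autosome tests.

#' Simultaneous multinomial confidence ribbon
#'
#' Assumes the per-category counts of a gene group follow a multinomial
#' with the genome-wide category proportions.  The band is built by Monte
#' Carlo: draws from the multinomial, with per-category quantiles taken
#' at the Sidak-adjusted level `1 - (1 - family_alpha)^(1/K)` so that the
#' family-wide coverage is approximately `1 - family_alpha`.
#'
#' @param genome_counts Named integer vector of genome-wide per-category
#'   gene counts.
#' @param n_group Number of genes in the group.
#' @param family_alpha Family-wide type-I error rate (default 0.05).
#' @param n_sim Monte Carlo draws (default 100000).
#' @param seed Integer seed.
#' @return `data.frame` with `category`, `p`, `expected`, `lower`,
#'   `upper`.
#' @export
multinomial_ribbon <- function(genome_counts, n_group, family_alpha = 0.05,
                               n_sim = 1e5, seed = 1L) {
  total <- sum(genome_counts)
  if (total <= 0) stop("input error: genome counts sum to zero")
  if (n_group < 1) stop("input error: n_group must be >= 1")
  p <- genome_counts / total
  K <- length(p)
  alpha_c <- 1 - (1 - family_alpha)^(1 / K)
  withr::with_seed(seed, {
    draws <- stats::rmultinom(n_sim, size = n_group, prob = p)
    lower <- apply(draws, 1L, stats::quantile, probs = alpha_c / 2,
                   type = 1L)
    upper <- apply(draws, 1L, stats::quantile, probs = 1 - alpha_c / 2,
                   type = 1L)
  })
  data.frame(category = if (is.null(names(genome_counts)))
    as.character(seq_len(K)) else names(genome_counts),
    p = as.numeric(p), expected = as.numeric(n_group * p),
    lower = as.numeric(lower), upper = as.numeric(upper),
    stringsAsFactors = FALSE)
}

#' Fisher exact test on a 2x2 in/out table
#'
#' Tests whether group A (`a_in` of `a_total`) is enriched relative to
#' group B (`b_in` of `b_total`) with the exact hypergeometric test on
#' `[[a_in, a_total - a_in], [b_in, b_total - b_in]]`.
#'
#' @param a_in,a_total Counts for the first group.
#' @param b_in,b_total Counts for the second group.
#' @param sided `"two"` (default), `"greater"` or `"less"` (alternative
#'   on the first group's odds).
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(a_in, a_total, b_in, b_total,
                              sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  tab <- matrix(c(a_in, a_total - a_in, b_in, b_total - b_in),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("input error: negative cell count")
  ft <- stats::fisher.test(tab, alternative = switch(sided,
                                                     two = "two.sided",
                                                     greater = "greater",
                                                     less = "less"))
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Gene-level frequency-group assignment
#'
#' Deduplicates variants to genes: a gene carrying several accepted PTCs
#' is assigned once, to the group of its highest-DAF variant.
#'
#' @param variants Polarized variant `data.frame` with `gene_id`, `daf`,
#'   `freq_group` and logical `ptc_call`.
#' @return `data.frame` with `gene_id`, `freq_group`, `max_daf`.
#' @export
gene_frequency_groups <- function(variants) {
  v <- variants[variants$ptc_call & !is.na(variants$daf) &
                  variants$freq_group %in% c("low", "moderate", "high"), ,
                drop = FALSE]
  if (!nrow(v)) {
    return(data.frame(gene_id = character(0), freq_group = character(0),
                      max_daf = numeric(0)))
  }
  v <- v[order(v$gene_id, -v$daf), , drop = FALSE]
  v <- v[!duplicated(v$gene_id), , drop = FALSE]
  data.frame(gene_id = v$gene_id, freq_group = v$freq_group,
             max_daf = v$daf, stringsAsFactors = FALSE)
}

#' Per-frequency-group top-tissue report
#'
#' For each frequency group, reports the per-category gene proportions of
#' the top-tissue distribution and a Fisher exact test of each category
#' against the genome-wide background.
#'
#' @param group_counts Named list (`low`, `moderate`, `high`, ...) of
#'   named per-category count vectors, or `NULL` to build them from
#'   `summaries` and `gene_groups`.
#' @param genome_counts Named per-category genome-wide count vector.
#' @param summaries,gene_groups Used when `group_counts` is `NULL`:
#'   per-gene summaries from [summarize_expression()] and gene-level
#'   groups from [gene_frequency_groups()].
#' @param sided Alternative passed to [fisher_enrichment()].
#' @return `data.frame` with `group`, `category`, `count`, `n_group`,
#'   `proportion`, `genome_proportion`, `fet_p`.
#' @export
top_tissue_group_report <- function(group_counts = NULL, genome_counts = NULL,
                                    summaries = NULL, gene_groups = NULL,
                                    sided = "two") {
  if (is.null(group_counts)) {
    stopifnot(!is.null(summaries), !is.null(gene_groups))
    cats <- sort(unique(summaries$top_tissue))
    count_of <- function(ids) {
      tt <- summaries$top_tissue[summaries$gene_id %in% ids]
      vapply(cats, function(ct) sum(tt == ct), integer(1L))
    }
    if (is.null(genome_counts)) genome_counts <- count_of(summaries$gene_id)
    group_counts <- lapply(split(gene_groups$gene_id,
                                 gene_groups$freq_group), count_of)
  }
  genome_total <- sum(genome_counts)
  rows <- list()
  for (g in names(group_counts)) {
    cts <- group_counts[[g]]
    n_group <- sum(cts)
    for (ct in names(cts)) {
      bg <- if (ct %in% names(genome_counts)) genome_counts[[ct]] else 0L
      fet <- if (n_group > 0L) {
        fisher_enrichment(cts[[ct]], n_group, bg, genome_total,
                          sided = sided)$p
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, category = ct, count = cts[[ct]], n_group = n_group,
        proportion = if (n_group > 0L) cts[[ct]] / n_group else NA_real_,
        genome_proportion = bg / genome_total, fet_p = fet,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' X-versus-autosome distribution test per frequency group
#'
#' For each frequency group, a Fisher exact test of the group's X-linked
#' gene count against the genome-wide X fraction.
#'
#' @param gene_groups `data.frame` with `gene_id`, `freq_group`.
#' @param gene_info `data.frame` with `gene_id` and logical `is_X`
#'   covering the genome background (e.g. from [gene_table()]).
#' @param sided Alternative passed to [fisher_enrichment()].
#' @return `data.frame` with `group`, `n_group`, `n_X`, `prop_X`,
#'   `genome_prop_X`, `fet_p`.
#' @export
chromosome_distribution_test <- function(gene_groups, gene_info,
                                         sided = "two") {
  is_x <- stats::setNames(gene_info$is_X, gene_info$gene_id)
  bg_x <- sum(gene_info$is_X)
  bg_n <- nrow(gene_info)
  groups <- split(gene_groups$gene_id, gene_groups$freq_group)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    nx <- sum(is_x[ids], na.rm = TRUE)
    data.frame(group = g, n_group = length(ids), n_X = nx,
               prop_X = nx / length(ids), genome_prop_X = bg_x / bg_n,
               fet_p = fisher_enrichment(nx, length(ids), bg_x, bg_n,
                                         sided = sided)$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
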