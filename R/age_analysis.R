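# Gene-age analysis: cross-tabulate PTC status by age class and
# origination mechanism, compare parent vs child duplicate copies, measure
# synonymous divergence between duplicate pairs (NG86 pathway counting
# with Jukes-Cantor correction), and fit the age-vs-PTC-fraction trend.

#' Age x PTC-frequency cross-tabulation
#'
#' @param ages `data.frame` with `gene_id` and logical `young` (see
#'   [generate_age_table()]).
#' @param gene_groups `data.frame` with `gene_id`, `freq_group` for
#'   PTC-carrying genes (see [gene_frequency_groups()]); genes absent
#'   from it count as PTC-free.
#' @return List with `counts` (old/young x
#'   ptc_free/low/moderate/high integer matrix), `young_pct` (per-column
#'   percentage of young genes, rounded to integer percent) and
#'   `young_with_ptc_fraction` (share of young genes carrying any PTC).
#' @export
age_frequency_crosstab <- function(ages, gene_groups) {
  grp <- gene_group_of(ages$gene_id, gene_groups)
  lev <- c("ptc_free", "low", "moderate", "high")
  counts <- rbind(
    old = table(factor(grp[!ages$young], levels = lev)),
    young = table(factor(grp[ages$young], levels = lev))
  )
  counts <- matrix(as.integer(counts), nrow = 2L,
                   dimnames = list(c("old", "young"), lev))
  tot <- colSums(counts)
  young_pct <- ifelse(tot > 0, round(100 * counts["young", ] / tot), 0)
  n_young <- sum(counts["young", ])
  list(counts = counts, young_pct = young_pct,
       young_with_ptc_fraction = if (n_young > 0)
         sum(counts["young", lev != "ptc_free"]) / n_young else NA_real_)
}

gene_group_of <- function(gene_ids, gene_groups) {
  grp <- gene_groups$freq_group[match(gene_ids, gene_groups$gene_id)]
  grp[is.na(grp)] <- "ptc_free"
  grp
}

#' Origination-mechanism x PTC-frequency cross-tabulation
#'
#' Restricted to young genes with a known origination mechanism.  In
#' strict mode only genes whose parent is strictly older (the
#' `strict_parent_child` flag) are counted; raw mode counts all.
#'
#' @param ages `data.frame` as in [generate_age_table()].
#' @param gene_groups As in [age_frequency_crosstab()].
#' @param strict Use the strict parent-child subset (default `TRUE`).
#' @return List with `counts` (mechanism x frequency-column matrix) and
#'   `summary` (`data.frame` per mechanism: `n`, `n_ptc`, `ptc_fraction`,
#'   `n_modhigh`, `modhigh_fraction`).
#' @export
mechanism_crosstab <- function(ages, gene_groups, strict = TRUE) {
  sel <- ages$young & ages$mechanism != "none"
  if (strict) sel <- sel & ages$strict_parent_child
  sub <- ages[sel, , drop = FALSE]
  grp <- gene_group_of(sub$gene_id, gene_groups)
  lev <- c("ptc_free", "low", "moderate", "high")
  mechs <- c("dna_duplication", "rna_duplication", "de_novo")
  counts <- t(vapply(mechs, function(m) {
    as.integer(table(factor(grp[sub$mechanism == m], levels = lev)))
  }, integer(4L)))
  dimnames(counts) <- list(mechs, lev)
  n <- rowSums(counts)
  n_ptc <- rowSums(counts[, c("low", "moderate", "high"), drop = FALSE])
  n_modhigh <- rowSums(counts[, c("moderate", "high"), drop = FALSE])
  list(counts = counts,
       summary = data.frame(
         mechanism = mechs, n = n, n_ptc = n_ptc,
         ptc_fraction = ifelse(n > 0, n_ptc / n, NA_real_),
         n_modhigh = n_modhigh,
         modhigh_fraction = ifelse(n > 0, n_modhigh / n, NA_real_),
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Parent-versus-child PTC comparison for DNA-based duplicate pairs
#'
#' Over the strict parent-child pairs (child = DNA-based young duplicate,
#' parent strictly older), counts how many child and how many parent
#' copies carry PTCs and compares the two proportions with a Fisher
#' exact test.
#'
#' @param ages `data.frame` as in [generate_age_table()]; pairs are rows
#'   with mechanism `dna_duplication`, `strict_parent_child` and a
#'   non-missing `parent_gene`.
#' @param ptc_genes Character vector of PTC-carrying gene ids.
#' @param sided Alternative passed to [fisher_enrichment()].
#' @return List with `n_pairs`, `n_child_ptc`, `n_parent_ptc`,
#'   `child_fraction`, `parent_fraction`, `fet_p`.
#' @export
parent_child_comparison <- function(ages, ptc_genes, sided = "two") {
  pairs <- ages[ages$mechanism == "dna_duplication" &
                  ages$strict_parent_child & !is.na(ages$parent_gene), ,
                drop = FALSE]
  n <- nrow(pairs)
  n_child <- sum(pairs$gene_id %in% ptc_genes)
  n_parent <- sum(pairs$parent_gene %in% ptc_genes)
  fet <- if (n > 0) fisher_enrichment(n_child, n, n_parent, n,
                                      sided = sided)$p else NA_real_
  list(n_pairs = n, n_child_ptc = n_child, n_parent_ptc = n_parent,
       child_fraction = if (n > 0) n_child / n else NA_real_,
       parent_fraction = if (n > 0) n_parent / n else NA_real_,
       fet_p = fet)
}

# -- NG86 synonymous divergence --------------------------------------------

# fraction of the three possible changes at each codon position that are
# synonymous; changes to stop codons count as nonsynonymous
ng86_site_counts <- function(codon) {
  aa <- CODON_TABLE[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (CODON_TABLE[[mut]] != "*" && CODON_TABLE[[mut]] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons; pathways passing through a stop codon are excluded (all-blocked
# pairs fall back to counting every pathway)
ng86_diff_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  count_path <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (CODON_TABLE[[nxt]] == "*") return(NULL)
      if (CODON_TABLE[[nxt]] == CODON_TABLE[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  count_path_any <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (CODON_TABLE[[nxt]] == CODON_TABLE[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- permutations_of(pos)
  counted <- Filter(Negate(is.null), lapply(paths, count_path))
  if (!length(counted)) counted <- lapply(paths, count_path_any)
  colMeans(do.call(rbind, counted))
}

#' Synonymous divergence between two aligned coding sequences (NG86)
#'
#' Nei-Gojobori (1986) pathway counting: per-codon synonymous site
#' fractions averaged between the two sequences, equal-weight averaging
#' over substitution pathways (pathways through stop codons excluded),
#' and the Jukes-Cantor correction
#' `dS = -(3/4) log(1 - (4/3) pS)`.  Codon pairs containing non-ACGT
#' symbols or a stop codon (including the annotated stop) are skipped.
#'
#' @param cds1,cds2 Equal-length, frame-aligned coding sequences.
#' @return List with `s_value` (dS; `NA` when saturated), `dn`,
#'   `s_sites`, `n_sites`, `sd`, `nd`, `ps`, `pn`, `saturated`.
#' @export
pairwise_ds <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2)) {
    stop("input error: sequences differ in length")
  }
  co1 <- codons_of(toupper(cds1))
  co2 <- codons_of(toupper(cds2))
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(co1)) {
    c1 <- co1[i]; c2 <- co2[i]
    if (is.na(CODON_TABLE[c1]) || is.na(CODON_TABLE[c2])) next
    if (CODON_TABLE[[c1]] == "*" || CODON_TABLE[[c2]] == "*") next
    s_i <- (ng86_site_counts(c1) + ng86_site_counts(c2)) / 2
    S <- S + s_i
    N <- N + 3 - s_i
    d <- ng86_diff_counts(c1, c2)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  list(s_value = jc(ps), dn = jc(pn), s_sites = S, n_sites = N,
       sd = Sd, nd = Nd, ps = ps, pn = pn,
       saturated = !is.na(ps) && ps >= 0.75)
}

#' Binned distribution of synonymous divergence per mechanism
#'
#' @param pairs `data.frame` with `mechanism` and `s_value` (`NA` values
#'   dropped).
#' @param bin_width Bin width on the dS axis (default 0.1).
#' @param max_s Upper edge of the last bin (default: smallest multiple of
#'   `bin_width` covering the data).
#' @return `data.frame` with `mechanism`, `bin_low`, `bin_high`,
#'   `count`, `proportion` (proportions normalized within mechanism).
#' @export
ds_binned_distribution <- function(pairs, bin_width = 0.1, max_s = NULL) {
  pairs <- pairs[!is.na(pairs$s_value), , drop = FALSE]
  if (is.null(max_s)) {
    max_s <- if (nrow(pairs)) {
      bin_width * ceiling(max(pairs$s_value) / bin_width + 1e-9)
    } else bin_width
    max_s <- max(max_s, bin_width)
  }
  breaks <- seq(0, max_s, by = bin_width)
  rows <- lapply(unique(pairs$mechanism), function(m) {
    s <- pairs$s_value[pairs$mechanism == m]
    cts <- as.integer(table(cut(s, breaks, include.lowest = TRUE)))
    data.frame(mechanism = m, bin_low = breaks[-length(breaks)],
               bin_high = breaks[-1L], count = cts,
               proportion = if (length(s)) cts / length(s) else
                 rep(NA_real_, length(cts)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(mechanism = character(0), bin_low = numeric(0),
                      bin_high = numeric(0), count = integer(0),
                      proportion = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Age-branch trend in the fraction of PTC-encoding genes
#'
#' Per age branch: number of genes, number carrying PTCs in the selected
#' frequency groups, and their fraction; Spearman correlation between the
#' branch midpoint (in Mya, negative into the past) and the fraction, and
#' an ordinary least-squares line.
#'
#' @param ages `data.frame` with `gene_id`, `branch`.
#' @param gene_groups As in [age_frequency_crosstab()].
#' @param branch_midpoints Named numeric vector: branch label ->
#'   midpoint age (Mya, negative).
#' @param groups Frequency groups that count as PTC-carrying (default
#'   all three).
#' @param exclude_branches Branch labels dropped before the trend fit
#'   (e.g. the youngest, mapping-compromised branch); still reported in
#'   the table with `excluded = TRUE`.
#' @return List with `table` (`data.frame`: `branch`, `midpoint`,
#'   `n_genes`, `n_ptc`, `fraction`, `excluded`), `rho`, `rho_p`,
#'   `slope`, `intercept`.
#' @export
age_trend <- function(ages, gene_groups, branch_midpoints,
                      groups = c("low", "moderate", "high"),
                      exclude_branches = NULL) {
  grp <- gene_group_of(ages$gene_id, gene_groups)
  is_ptc <- grp %in% groups
  branches <- names(branch_midpoints)
  tab <- do.call(rbind, lapply(branches, function(b) {
    sel <- as.character(ages$branch) == b
    data.frame(branch = b, midpoint = branch_midpoints[[b]],
               n_genes = sum(sel), n_ptc = sum(sel & is_ptc),
               fraction = if (sum(sel)) sum(sel & is_ptc) / sum(sel)
               else NA_real_,
               excluded = b %in% as.character(exclude_branches),
               stringsAsFactors = FALSE)
  }))
  fit_tab <- tab[!tab$excluded & !is.na(tab$fraction), , drop = FALSE]
  if (nrow(fit_tab) >= 3L && stats::sd(fit_tab$fraction) > 0) {
    ct <- suppressWarnings(stats::cor.test(fit_tab$midpoint,
                                           fit_tab$fraction,
                                           method = "spearman"))
    rho <- unname(ct$estimate)
    rho_p <- ct$p.value
  } else {
    rho <- NA_real_
    rho_p <- NA_real_
  }
  coefs <- if (nrow(fit_tab) >= 2L) {
    stats::coef(stats::lm(fraction ~ midpoint, data = fit_tab))
  } else c(`(Intercept)` = NA_real_, midpoint = NA_real_)
  list(table = tab, rho = rho, rho_p = rho_p,
       slope = unname(coefs[["midpoint"]]),
       intercept = unname(coefs[["(Intercept)"]]))
}
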