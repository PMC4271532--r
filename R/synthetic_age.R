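# Gene-age tables: a random generator for synthetic studies, plus a
# packaged fixture that expands the published young/old x PTC-frequency x
# origination-mechanism cross-tabulation into a per-gene table with exactly
# the printed marginal counts.

#' Generate a random gene-age table
#'
#' Assigns each gene an age branch (young branches 1-6, old branches -5-0),
#' a young/old flag, an origination mechanism for young genes (DNA-based
#' duplication, RNA-based duplication/retroposition, or de novo), a parent
#' gene link for duplicates, and a strict parent-child flag (parent
#' strictly older than the child).
#'
#' @param genes List of `gene_model` objects, or a character vector of
#'   gene ids.
#' @param config A [synthetic_config()]; `config$young_fraction` sets the
#'   expected share of young genes.
#' @param mechanism_probs Probabilities of `dna_duplication`,
#'   `rna_duplication` and `de_novo` among young genes.  An all-zero
#'   vector gives every gene mechanism `"none"`.
#' @param strict_prob Probability that a duplicate's parent is strictly
#'   older (sets `strict_parent_child`).
#' @return `data.frame` with `gene_id`, `branch`, `young`, `mechanism`,
#'   `parent_gene`, `strict_parent_child`.
#' @export
generate_age_table <- function(genes, config,
                               mechanism_probs = c(dna_duplication = 0.79,
                                                   rna_duplication = 0.11,
                                                   de_novo = 0.10),
                               strict_prob = 0.8) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- if (is.character(genes)) genes else
    vapply(genes, `[[`, character(1L), "gene_id")
  withr::with_seed(config$seed + 4L, {
    young <- stats::runif(length(ids)) < config$young_fraction
    branch <- integer(length(ids))
    branch[young] <- sample(1:6, sum(young), replace = TRUE)
    branch[!young] <- sample(-5:0, sum(!young), replace = TRUE)
    mechanism <- rep("none", length(ids))
    if (sum(mechanism_probs) > 0 && any(young)) {
      mechanism[young] <- sample(names(mechanism_probs), sum(young),
                                 replace = TRUE, prob = mechanism_probs)
    }
    parent <- rep(NA_character_, length(ids))
    strict <- rep(FALSE, length(ids))
    dup <- mechanism %in% c("dna_duplication", "rna_duplication")
    old_ids <- ids[!young]
    if (any(dup) && length(old_ids)) {
      parent[dup] <- resample(old_ids, sum(dup), replace = TRUE)
      strict[dup] <- stats::runif(sum(dup)) < strict_prob
    }
    data.frame(gene_id = ids, branch = branch, young = young,
               mechanism = mechanism, parent_gene = parent,
               strict_parent_child = strict, stringsAsFactors = FALSE)
  })
}

#' Load the packaged age-by-frequency count fixture
#'
#' Reads the published cross-tabulation of gene counts by age class
#' (old/young), PTC frequency column (PTC-free, low, moderate, high) and
#' origination mechanism, in strict and raw parent-child variants, plus
#' the count of duplicate parent genes that themselves carry PTCs.
#'
#' @return `data.frame` with columns `category`, `relationship`,
#'   `ptc_free`, `low`, `moderate`, `high`.
#' @export
load_table2_counts <- function() {
  path <- system.file("extdata", "age_ptc_counts.tsv", package = "ptcpop")
  if (path == "") path <- file.path("inst", "extdata", "age_ptc_counts.tsv")
  read_tsv(path)
}

#' Expand the packaged count fixture into a per-gene table
#'
#' Builds a deterministic per-gene age table and PTC frequency-group
#' assignment whose marginal counts reproduce the packaged fixture
#' exactly: old/young totals per frequency column, strict and raw
#' mechanism counts, and parent links for the strict DNA-based duplicates
#' (the fixture's count of PTC-carrying parents is apportioned to the
#' low-frequency group, the only unconstrained choice; parent identity per
#' child is synthetic).
#'
#' @param counts Fixture counts, as returned by [load_table2_counts()].
#' @return List with `ages` (per-gene `data.frame` as in
#'   [generate_age_table()]) and `gene_groups` (`data.frame` with
#'   `gene_id`, `freq_group` for every PTC-carrying gene).
#' @export
age_table2_genes <- function(counts = load_table2_counts()) {
  groups <- c("ptc_free", "low", "moderate", "high")
  getrow <- function(cat, rel) {
    r <- counts[counts$category == cat & counts$relationship == rel, groups]
    stopifnot(nrow(r) == 1L)
    unlist(r)
  }
  old_n <- getrow("old", "total")
  mech_names <- c(dna_based = "dna_duplication", rna_based = "rna_duplication",
                  de_novo = "de_novo")

  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  # old genes
  old_ids <- split(sprintf("OG%05d", seq_len(sum(old_n))),
                   rep(groups, old_n))
  for (g in groups) {
    add(data.frame(gene_id = old_ids[[g]], branch = 0L, young = FALSE,
                   mechanism = "none", parent_gene = NA_character_,
                   strict_parent_child = FALSE, freq_group = g,
                   stringsAsFactors = FALSE))
  }

  # young genes, one block per mechanism x frequency column
  yi <- 0L
  for (cat in names(mech_names)) {
    raw <- getrow(cat, "raw")
    strict <- getrow(cat, "strict")
    for (g in groups) {
      n <- raw[[g]]
      if (n == 0L) next
      ids <- sprintf("YG%05d", yi + seq_len(n))
      yi <- yi + n
      add(data.frame(gene_id = ids, branch = 1L, young = TRUE,
                     mechanism = mech_names[[cat]],
                     parent_gene = NA_character_,
                     strict_parent_child = seq_len(n) <= strict[[g]],
                     freq_group = g, stringsAsFactors = FALSE))
    }
  }
  ages <- do.call(rbind, rows)

  # parent links for strict DNA-based duplicates: parents are old genes;
  # the fixture's PTC-carrying parent count comes from the old low group.
  n_parent_ptc <- counts[counts$category == "dna_parent_with_ptc" &
                           counts$relationship == "strict", "low"]
  kids <- which(ages$mechanism == "dna_duplication" &
                  ages$strict_parent_child)
  parents <- c(old_ids$low[seq_len(n_parent_ptc)],
               old_ids$ptc_free[seq_len(length(kids) - n_parent_ptc)])
  ages$parent_gene[kids] <- parents

  gene_groups <- ages[ages$freq_group != "ptc_free",
                      c("gene_id", "freq_group")]
  rownames(gene_groups) <- NULL
  list(ages = ages[, setdiff(colnames(ages), "freq_group")],
       gene_groups = gene_groups)
}
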