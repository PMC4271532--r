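# Expression-atlas generator: per-gene archetypes (broad, single-tissue,
# sex-tissue-restricted, silent) over a tissue x replicate array layout,
# plus a whole-body per-strain expression matrix with an optional
# nonsense-mediated-decay-like reduction in PTC carrier strains.
# Values are emitted on a linear scale; the log10 transform happens in the
# analysis step.

#' Generate a synthetic gene x (tissue x replicate) expression matrix
#'
#' Each gene is assigned one archetype: `broad` (present in all tissues),
#' `tissue_specific` (present in one random tissue), `sex_specific`
#' (present in one random sex-related tissue) or `silent` (absent
#' everywhere).  Replicates are noisy copies; absent cells carry positive
#' background signal but a `FALSE` present call.
#'
#' @param genes List of `gene_model` objects, or a character vector of
#'   gene ids.
#' @param config A [synthetic_config()].
#' @param archetypes Optional named character vector (gene id ->
#'   archetype) overriding random assignment.
#' @return An object of class `expression_set`: list with `values` and
#'   `present` matrices (genes x arrays), `tissue` and `replicate` per
#'   array column, `tissue_names`, `sex_tissues`, and the per-gene
#'   `archetype`.
#' @export
generate_expression_matrix <- function(genes, config, archetypes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- if (is.character(genes)) genes else
    vapply(genes, `[[`, character(1L), "gene_id")
  withr::with_seed(config$seed + 3L, {
    tissues <- config$tissue_names
    reps <- config$replicates_per_tissue
    tissue_col <- rep(tissues, each = reps)
    rep_col <- rep(seq_len(reps), times = length(tissues))
    cols <- paste(tissue_col, rep_col, sep = ".")

    if (is.null(archetypes)) {
      archetypes <- sample(names(config$archetype_probs), length(ids),
                           replace = TRUE, prob = config$archetype_probs)
      names(archetypes) <- ids
    } else {
      archetypes <- archetypes[ids]
    }

    values <- matrix(0, nrow = length(ids), ncol = length(cols),
                     dimnames = list(ids, cols))
    present <- matrix(FALSE, nrow = length(ids), ncol = length(cols),
                      dimnames = list(ids, cols))
    background <- function(n) exp(stats::rnorm(n, log(5), 0.3))

    for (i in seq_along(ids)) {
      arch <- archetypes[i]
      expressed <- switch(arch,
        broad = tissues,
        tissue_specific = sample(tissues, 1L),
        sex_specific = sample(config$sex_tissues, 1L),
        silent = character(0))
      level <- switch(arch,
        broad = exp(stats::rnorm(1L, log(200), 0.6)),
        silent = NA_real_,
        exp(stats::rnorm(1L, log(500), 0.5)))
      tissue_level <- stats::setNames(rep(NA_real_, length(tissues)), tissues)
      if (length(expressed)) {
        tissue_level[expressed] <- level * exp(stats::rnorm(length(expressed),
                                                            0, 0.3))
      }
      v <- background(length(cols))
      on_cols <- tissue_col %in% expressed
      v[on_cols] <- tissue_level[tissue_col[on_cols]] *
        exp(stats::rnorm(sum(on_cols), 0, 0.1))
      values[i, ] <- v
      present[i, on_cols] <- TRUE
    }
    structure(list(values = values, present = present, tissue = tissue_col,
                   replicate = rep_col, tissue_names = tissues,
                   sex_tissues = config$sex_tissues, archetype = archetypes),
              class = "expression_set")
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "<expression_set> %d genes x %d arrays (%d tissues x %d replicates)\n",
    nrow(x$values), ncol(x$values), length(x$tissue_names),
    max(x$replicate)))
  invisible(x)
}

#' Generate whole-body per-strain expression for allele-imbalance tests
#'
#' Emulates a strain-level expression panel: every gene gets a lognormal
#' baseline with strain-to-strain noise, and strains carrying a planted
#' nonsense allele have their expression of the host gene multiplied by
#' `nmd_effect`, mimicking nonsense-mediated decay.
#'
#' @param truth Truth table from [generate_strain_panel()].
#' @param strains Character vector of strain ids.
#' @param gene_ids Character vector of gene ids to emit.
#' @param config A [synthetic_config()].
#' @param nmd_effect Multiplicative expression effect in carrier strains
#'   for nonsense variants (1 = no effect; default 0.4).
#' @return Numeric matrix genes x strains.
#' @export
generate_strain_expression <- function(truth, strains, gene_ids, config,
                                       nmd_effect = 0.4) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 5L, {
    m <- exp(stats::rnorm(length(gene_ids), log(100), 0.5)) *
      matrix(exp(stats::rnorm(length(gene_ids) * length(strains), 0, 0.2)),
             nrow = length(gene_ids),
             dimnames = list(gene_ids, strains))
    ptc <- truth[truth$class == "nonsense" & nzchar(truth$carriers), ,
                 drop = FALSE]
    for (i in seq_len(nrow(ptc))) {
      gid <- ptc$gene_id[i]
      if (!gid %in% gene_ids) next
      carr <- intersect(strsplit(ptc$carriers[i], ";", fixed = TRUE)[[1L]],
                        strains)
      m[gid, carr] <- m[gid, carr] * nmd_effect
    }
    m
  })
}
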