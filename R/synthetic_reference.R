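# Synthetic reference generator: designs multi-isoform gene models on both
# strands, plants variants of known class/effect into the reference codons,
# and assembles chromosome sequences.  Every generated gene passes the
# annotation-QC rules by construction (codon-aligned exons drawn from sense
# codons, ATG start, canonical stop, GT..AG introns).

MIN_EXON_CODONS <- 8L

#' Generate a synthetic reference genome with planted variant sites
#'
#' Designs `config$n_genes` gene models distributed round-robin over the
#' configured chromosomes on alternating strands, resolves the planted
#' variants of `config$planted_variants` to concrete reference positions
#' (overwriting reference codons so each planted substitution has exactly
#' the intended effect), and assembles the chromosome sequences.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `genome` (named character vector), `genes`
#'   (named list of `gene_model`), and `truth` (a `data.frame` skeleton of
#'   planted sites: `variant_id`, `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `class`, `constitutive`, `target_daf`, `ancestral_is_ref`,
#'   `min_truncation`).  Carrier strains are added by
#'   [generate_strain_panel()].
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_reference_impl(config))
}

generate_reference_impl <- function(config) {
  n <- config$n_genes
  designs <- lapply(seq_len(n), function(i) design_gene_structure(i, config))
  names(designs) <- vapply(designs, `[[`, character(1L), "gene_id")

  plants <- resolve_planted_genes(config$planted_variants, designs)
  # overwrite reference codons / intron bases so each plant is realizable
  for (i in seq_len(nrow(plants))) {
    designs[[plants$gene_id[i]]] <-
      apply_plant_to_design(designs[[plants$gene_id[i]]], plants[i, ])
  }

  assembled <- assemble_chromosomes(designs, config)
  truth <- build_truth_skeleton(plants, assembled$designs)
  list(genome = assembled$genome, genes = assembled$genes, truth = truth)
}

# -- gene structure ---------------------------------------------------------

design_gene_structure <- function(i, config) {
  gene_id <- sprintf("G%04d", i)
  chrom <- config$chrom_names[(i - 1L) %% length(config$chrom_names) + 1L]
  strand <- if (i %% 2L == 0L) "-" else "+"
  T <- sample_range(config$codons_per_gene)

  k_max <- max(1L, min(config$exons_per_gene[2L], T %/% MIN_EXON_CODONS))
  k_min <- min(config$exons_per_gene[1L], k_max)
  k <- sample_range(c(k_min, k_max))

  extra <- T - k * MIN_EXON_CODONS
  exon_codons <- rep(MIN_EXON_CODONS, k) +
    if (extra > 0L) tabulate(sample.int(k, extra, replace = TRUE), k) else 0L

  n_internal <- max(0L, k - 2L)
  iso_max <- min(config$isoforms_per_gene[2L], 1L + n_internal)
  iso_min <- min(config$isoforms_per_gene[1L], iso_max)
  n_iso <- sample_range(c(iso_min, iso_max))
  skipped <- if (n_iso > 1L) resample(seq(2L, k - 1L), n_iso - 1L)
  else integer(0)

  codons <- c("ATG", sample(sense_codons(), T - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  intron_len <- if (k > 1L) {
    sample_range(config$intron_length, k - 1L)
  } else integer(0)
  introns <- vapply(intron_len, function(L) {
    paste0("GT", random_dna(L - 4L), "AG")
  }, character(1L))

  list(gene_id = gene_id, chrom = chrom, strand = strand,
       is_X = chrom == config$x_chrom,
       T = T, k = k, exon_codons = exon_codons, skipped = skipped,
       codons = codons, introns = introns, plants = list())
}

# codon index -> exon index
exon_of_codon <- function(design, j) {
  findInterval(j, cumsum(c(0L, design$exon_codons)) + 1L)
}

# codon ranges of a given exon
exon_codon_range <- function(design, e) {
  ends <- cumsum(design$exon_codons)
  starts <- c(1L, ends[-length(ends)] + 1L)
  c(starts[e], ends[e])
}

# -- plant resolution -------------------------------------------------------

resolve_planted_genes <- function(plants, designs) {
  if (is.null(plants) || nrow(plants) == 0L) {
    return(data.frame(gene_id = character(0), site_class = character(0),
                      target_daf = numeric(0), constitutive = logical(0),
                      truncation_fraction = numeric(0),
                      ancestral_is_ref = logical(0)))
  }
  plants <- as.data.frame(plants)
  taken <- plants$gene_id[!is.na(plants$gene_id)]
  suitable <- function(d, cls, constitutive) {
    if (cls == "splice") return(d$k >= 2L)
    if (cls == "nonsense" && !constitutive) return(length(d$skipped) >= 1L)
    TRUE
  }
  for (i in which(is.na(plants$gene_id))) {
    free <- setdiff(names(designs), taken)
    ok <- free[vapply(designs[free], suitable, logical(1L),
                      cls = plants$site_class[i],
                      constitutive = plants$constitutive[i])]
    if (!length(ok)) {
      # allow several plants per gene when genes run short
      all_ok <- names(designs)[vapply(designs, suitable, logical(1L),
                                      cls = plants$site_class[i],
                                      constitutive = plants$constitutive[i])]
      if (!length(all_ok)) {
        stop("configuration error: no gene can host a ",
             plants$site_class[i], " plant (constitutive = ",
             plants$constitutive[i], ")")
      }
      ok <- all_ok
    }
    plants$gene_id[i] <- ok[1L]
    taken <- c(taken, ok[1L])
  }
  missing <- setdiff(plants$gene_id, names(designs))
  if (length(missing)) {
    stop("configuration error: planted gene_id(s) not generated: ",
         paste(missing, collapse = ", "))
  }
  plants$variant_id <- sprintf("PV%04d", seq_len(nrow(plants)))
  plants
}

# pick a codon index for a plant, honouring constitutive-exon constraints
choose_plant_codon <- function(design, plant) {
  T <- design$T
  used <- vapply(design$plants, function(p) p$codon %||% NA_integer_,
                 integer(1L))
  cls <- plant$site_class
  if (cls == "start_loss") return(1L)
  if (cls == "nonsense" && !plant$constitutive) {
    rng <- exon_codon_range(design, design$skipped[1L])
    cand <- setdiff(seq(rng[1L], rng[2L]), used)
    return(cand[1L])
  }
  tf <- if (cls == "nonsense") plant$truncation_fraction else 0.5
  j <- T - round(tf * (T - 1L))
  j <- max(2L, min(T - 1L, j))
  # constitutive plants in multi-isoform genes must sit in a shared exon
  allowed <- if (length(design$skipped)) {
    c(seq(exon_codon_range(design, 1L)[1L], exon_codon_range(design, 1L)[2L]),
      seq(exon_codon_range(design, design$k)[1L],
          exon_codon_range(design, design$k)[2L]))
  } else {
    seq.int(1L, T)
  }
  allowed <- setdiff(intersect(allowed, seq(2L, T - 1L)), used)
  if (!length(allowed)) {
    stop("configuration error: gene ", design$gene_id,
         " has no free codon for another plant")
  }
  allowed[which.min(abs(allowed - j))]
}

# reference codon motifs for which one substitution has the intended effect
PLANT_MOTIFS <- list(
  nonsense   = list(codon = "CAG", offset = 1L, ref = "C", alt = "T"),  # ->TAG
  missense   = list(codon = "AAA", offset = 1L, ref = "A", alt = "G"),  # ->GAA
  synonymous = list(codon = "GGT", offset = 3L, ref = "T", alt = "C"),  # ->GGC
  start_loss = list(codon = "ATG", offset = 1L, ref = "A", alt = "G")   # ->GTG
)

apply_plant_to_design <- function(design, plant) {
  cls <- plant$site_class
  if (cls == "splice") {
    if (design$k < 2L) {
      stop("configuration error: splice plant needs an intron in gene ",
           design$gene_id)
    }
    used <- vapply(design$plants,
                   function(p) if (identical(p$class, "splice")) p$intron
                   else NA_integer_, integer(1L))
    intron <- setdiff(seq_len(design$k - 1L), used)[1L]
    if (is.na(intron)) {
      stop("configuration error: gene ", design$gene_id,
           " has no free intron for another splice plant")
    }
    design$plants <- c(design$plants, list(list(
      variant_id = plant$variant_id, class = "splice", intron = intron,
      intron_offset = 1L, ref_t = "G", alt_t = "A",
      target_daf = plant$target_daf, constitutive = TRUE,
      ancestral_is_ref = plant$ancestral_is_ref, codon = NA_integer_)))
    return(design)
  }
  motif <- PLANT_MOTIFS[[cls]]
  j <- choose_plant_codon(design, plant)
  if (cls != "start_loss") design$codons[j] <- motif$codon
  design$plants <- c(design$plants, list(list(
    variant_id = plant$variant_id, class = cls, codon = j,
    codon_offset = motif$offset, ref_t = motif$ref, alt_t = motif$alt,
    target_daf = plant$target_daf,
    constitutive = isTRUE(plant$constitutive),
    ancestral_is_ref = plant$ancestral_is_ref, intron = NA_integer_)))
  design
}

# -- assembly ---------------------------------------------------------------

# local (transcript-orientation) layout of a gene locus
locus_layout <- function(design) {
  k <- design$k
  exon_nt <- design$exon_codons * 3L
  intron_nt <- nchar(design$introns)
  exon_start <- integer(k); exon_end <- integer(k)
  intron_start <- integer(max(0L, k - 1L)); intron_end <- intron_start
  at <- 1L
  for (e in seq_len(k)) {
    exon_start[e] <- at; exon_end[e] <- at + exon_nt[e] - 1L
    at <- exon_end[e] + 1L
    if (e < k) {
      intron_start[e] <- at; intron_end[e] <- at + intron_nt[e] - 1L
      at <- intron_end[e] + 1L
    }
  }
  list(exon_start = exon_start, exon_end = exon_end,
       intron_start = intron_start, intron_end = intron_end,
       len = at - 1L)
}

# CDS coordinate (1-based within spliced CDS) -> local locus coordinate
cds_to_local <- function(layout, design, p) {
  exon_cds_end <- cumsum(design$exon_codons * 3L)
  exon_cds_start <- c(1L, exon_cds_end[-length(exon_cds_end)] + 1L)
  e <- findInterval(p, exon_cds_start)
  layout$exon_start[e] + (p - exon_cds_start[e])
}

locus_sequence <- function(design, layout) {
  k <- design$k
  exon_cds_end <- cumsum(design$exon_codons)
  exon_cds_start <- c(1L, exon_cds_end[-k] + 1L)
  parts <- character(0)
  for (e in seq_len(k)) {
    parts <- c(parts, paste(
      design$codons[seq(exon_cds_start[e], exon_cds_end[e])], collapse = ""))
    if (e < k) parts <- c(parts, design$introns[e])
  }
  paste(parts, collapse = "")
}

assemble_chromosomes <- function(designs, config) {
  by_chrom <- split(designs, vapply(designs, `[[`, character(1L), "chrom"))
  genome <- character(0)
  genes <- list()
  out_designs <- designs

  for (ch in config$chrom_names) {
    ds <- by_chrom[[ch]]
    parts <- character(0)
    at <- 0L
    for (d in ds) {
      gap <- sample_range(config$intergenic_gap)
      parts <- c(parts, random_dna(gap))
      at <- at + gap
      layout <- locus_layout(d)
      seq_local <- locus_sequence(d, layout)
      insert <- if (d$strand == "-") revcomp(seq_local) else seq_local
      d$offset <- at               # locus occupies at+1 .. at+layout$len
      d$layout <- layout
      parts <- c(parts, insert)
      at <- at + layout$len
      out_designs[[d$gene_id]] <- d
      genes[[d$gene_id]] <- design_to_gene_model(d)
    }
    tail_gap <- sample_range(config$intergenic_gap)
    parts <- c(parts, random_dna(tail_gap))
    at <- at + tail_gap
    seq_ch <- paste(parts, collapse = "")
    if (!is.null(config$chrom_length)) {
      if (at > config$chrom_length) {
        stop("configuration error: chromosome ", ch, " needs ", at,
             " bp but chrom_length is ", config$chrom_length)
      }
      seq_ch <- paste0(seq_ch, random_dna(config$chrom_length - at))
    }
    genome[[ch]] <- seq_ch
  }
  list(genome = genome, genes = genes, designs = out_designs)
}

# local locus coordinate -> genomic coordinate
local_to_genomic <- function(design, t) {
  if (design$strand == "-") {
    design$offset + design$layout$len - t + 1L
  } else {
    design$offset + t
  }
}

design_to_gene_model <- function(design) {
  layout <- design$layout
  local_iso <- list()
  full <- seq_len(design$k)
  local_iso[[sprintf("%s.t1", design$gene_id)]] <- full
  if (length(design$skipped)) {
    for (s in seq_along(design$skipped)) {
      local_iso[[sprintf("%s.t%d", design$gene_id, s + 1L)]] <-
        setdiff(full, design$skipped[s])
    }
  }
  isoforms <- lapply(local_iso, function(exons) {
    g1 <- local_to_genomic(design, layout$exon_start[exons])
    g2 <- local_to_genomic(design, layout$exon_end[exons])
    data.frame(start = pmin(g1, g2), end = pmax(g1, g2))
  })
  gene_model(design$gene_id, design$chrom, design$strand, isoforms,
             is_X = design$is_X)
}

# -- truth ------------------------------------------------------------------

# expected min truncation over isoforms for a constitutive nonsense plant
plant_truncation <- function(design, j) {
  exon <- exon_of_codon(design, j)
  trs <- numeric(0)
  iso_skips <- c(NA_integer_, design$skipped)   # NA = full isoform
  for (s in iso_skips) {
    if (!is.na(s) && s == exon) return(list(min = NA_real_, all = FALSE))
    drop <- if (!is.na(s) && s < exon) design$exon_codons[s] else 0L
    Ti <- design$T - if (!is.na(s)) design$exon_codons[s] else 0L
    ji <- j - drop
    trs <- c(trs, (Ti - ji) / (Ti - 1L))
  }
  list(min = min(trs), all = TRUE)
}

build_truth_skeleton <- function(plants, designs) {
  rows <- list()
  for (gid in names(designs)) {
    d <- designs[[gid]]
    for (p in d$plants) {
      if (p$class == "splice") {
        t <- d$layout$intron_start[p$intron] + p$intron_offset - 1L
        min_trunc <- NA_real_
        constitutive <- TRUE
        ref_t <- p$ref_t; alt_t <- p$alt_t
      } else {
        cds_pos <- (p$codon - 1L) * 3L + p$codon_offset
        t <- cds_to_local(d$layout, d, cds_pos)
        if (p$class == "nonsense") {
          tr <- plant_truncation(d, p$codon)
          min_trunc <- tr$min
          constitutive <- tr$all
        } else {
          min_trunc <- NA_real_
          constitutive <- p$constitutive
        }
        ref_t <- p$ref_t; alt_t <- p$alt_t
      }
      pos <- local_to_genomic(d, t)
      flip <- d$strand == "-"
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = p$variant_id, gene_id = gid, chrom = d$chrom,
        pos = pos,
        ref = if (flip) comp_base(ref_t) else ref_t,
        alt = if (flip) comp_base(alt_t) else alt_t,
        class = p$class, constitutive = constitutive,
        target_daf = p$target_daf,
        ancestral_is_ref = p$ancestral_is_ref,
        min_truncation = min_trunc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(variant_id = character(0), gene_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), constitutive = logical(0),
                      target_daf = numeric(0), ancestral_is_ref = logical(0),
                      min_truncation = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
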