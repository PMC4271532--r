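# The synthetic-data generator: determinism, QC-cleanliness by
# construction, planted allele counts, outgroup behaviour, archetypes and
# the packaged age-count fixture.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_strains = 80, n_genes = 10, seed = 11,
                          planted_variants = default_planted_variants(6, 80))
  a <- simulate_ptc_study(cfg)
  b <- simulate_ptc_study(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$outgroups, b$outgroups)
  expect_identical(a$panel$chroms, b$panel$chroms)

  fa1 <- tempfile(fileext = ".fasta"); fa2 <- tempfile(fileext = ".fasta")
  gf1 <- tempfile(fileext = ".gff3"); gf2 <- tempfile(fileext = ".gff3")
  write_genome_fasta(a$genome, fa1); write_genome_fasta(b$genome, fa2)
  write_gff3(a$genes, gf1); write_gff3(b$genes, gf2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gf1), readLines(gf2))
})

test_that("every generated gene passes annotation QC, on both strands", {
  for (seed in c(1, 42)) {
    cfg <- synthetic_config(n_strains = 60, n_genes = 14, seed = seed,
                            planted_variants = default_planted_variants(8, 60))
    ref <- generate_reference(cfg)
    qc <- qc_filter_genes(ref$genes, ref$genome)
    expect_identical(nrow(qc$rejected), 0L)
    strands <- vapply(ref$genes, `[[`, character(1), "strand")
    expect_setequal(unique(strands), c("+", "-"))
    # independent check: Biostrings translation of every isoform
    for (g in ref$genes) {
      for (tx in names(g$isoforms)) {
        cds <- extract_cds(g, ref$genome, tx)
        expect_identical(substr(cds, 1, 3), "ATG")
        aa <- oracle_translate(cds)
        expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
        expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
      }
    }
  }
})

test_that("minus-strand CDS is the reverse complement of the genomic span", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 6, seed = 5)
  ref <- generate_reference(cfg)
  g <- ref$genes[[which(vapply(ref$genes, `[[`, character(1),
                               "strand") == "-")[1]]]
  segs <- g$isoforms[[1]]
  genomic <- paste(substring(ref$genome[[g$chrom]], segs$start, segs$end),
                   collapse = "")
  expect_identical(extract_cds(g, ref$genome), oracle_revcomp(genomic))
  expect_identical(substr(extract_cds(g, ref$genome), 1, 3), "ATG")
})

test_that("FASTA+GFF3 round-trip reproduces every stored CDS exactly", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 8, seed = 9,
                          planted_variants = default_planted_variants(4, 60))
  ref <- generate_reference(cfg)
  fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
  write_genome_fasta(ref$genome, fa)
  write_gff3(ref$genes, gf)
  genome2 <- read_genome_fasta(fa)
  genes2 <- read_gene_models(gf)
  expect_identical(genome2, ref$genome)
  expect_setequal(names(genes2), names(ref$genes))
  for (gid in names(ref$genes)) {
    g1 <- ref$genes[[gid]]; g2 <- genes2[[gid]]
    expect_identical(g2$strand, g1$strand)
    expect_identical(g2$is_X, g1$is_X)
    expect_setequal(names(g2$isoforms), names(g1$isoforms))
    for (tx in names(g1$isoforms)) {
      expect_identical(extract_cds(g2, genome2, tx),
                       extract_cds(g1, ref$genome, tx))
    }
  }
})

test_that("planted variants are realized at exact strain counts", {
  pv <- rbind(planted_variant("nonsense", 0.30, truncation_fraction = 0.5),
              planted_variant("synonymous", 0.10),
              planted_variant("missense", 0))
  cfg <- synthetic_config(n_strains = 100, n_genes = 6, seed = 2,
                          planted_variants = pv)
  st <- simulate_ptc_study(cfg)
  expect_identical(st$truth$n_derived, c(30L, 10L, 0L)[
    match(st$truth$variant_id, sprintf("PV%04d", 1:3))])
  for (i in seq_len(nrow(st$truth))) {
    tr <- st$truth[i, ]
    site <- extract_site_panel(st$panel, st$genome, tr$chrom, tr$pos)
    expect_identical(sum(site$alleles == tr$alt), tr$n_derived)
  }
  # target_daf = 0 for all: panel identical to reference (no masks here)
  m <- st$panel$chroms[[st$truth$chrom[st$truth$n_derived == 0]]]
  pos0 <- st$truth$pos[st$truth$n_derived == 0]
  expect_true(all(m[pos0, ] == charToRaw(st$truth$ref[
    st$truth$n_derived == 0])))
})

test_that("mask and heterozygote injection hits the configured rates and spares planted sites", {
  cfg <- synthetic_config(n_strains = 80, n_genes = 8, seed = 4,
                          het_rate = 0.002, n_mask_rate = 0.004,
                          planted_variants = default_planted_variants(5, 80))
  st <- simulate_ptc_study(cfg)
  all_sym <- unlist(lapply(st$panel$chroms, function(m) {
    rawToChar(as.vector(m), multiple = TRUE)
  }))
  n_cells <- length(all_sym)
  n_N <- sum(all_sym == "N")
  n_het <- sum(all_sym %in% c("R", "Y", "S", "W", "K", "M"))
  expect_gt(n_N, 0); expect_gt(n_het, 0)
  # binomial 4-sigma sanity band
  expect_lt(abs(n_N - n_cells * 0.004), 4 * sqrt(n_cells * 0.004) + 1)
  expect_lt(abs(n_het - n_cells * 0.002), 4 * sqrt(n_cells * 0.002) + 1)
  for (i in seq_len(nrow(st$truth))) {
    site <- extract_site_panel(st$panel, st$genome, st$truth$chrom[i],
                               st$truth$pos[i])
    expect_true(all(site$alleles %in% c("A", "C", "G", "T")))
  }
})

test_that("outgroup table follows the ancestral flags and divergence 0 keeps every site polarizable", {
  pv <- rbind(planted_variant("nonsense", 0.05, ancestral_is_ref = TRUE),
              planted_variant("missense", 0.05, ancestral_is_ref = FALSE))
  cfg <- synthetic_config(n_strains = 60, n_genes = 4, seed = 8,
                          planted_variants = pv, outgroup_divergence = 0)
  st <- simulate_ptc_study(cfg)
  tr <- st$truth[match(st$outgroups$pos, st$truth$pos), ]
  expect_identical(st$outgroups$og1, ifelse(tr$ancestral_is_ref, tr$ref,
                                            tr$alt))
  expect_identical(st$outgroups$og1, st$outgroups$og2)
  # ancestral_is_ref = FALSE sites are refused by the conservative rule
  i <- which(!tr$ancestral_is_ref)
  pol <- infer_ancestral(tr$ref[i], tr$alt[i], st$outgroups$og1[i],
                         st$outgroups$og2[i])
  expect_false(pol$polarized)
})

test_that("expression archetypes behave as designed", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 40, seed = 3)
  expr <- generate_expression_matrix(sprintf("G%04d", 1:40), cfg)
  s <- summarize_expression(expr)
  arch <- expr$archetype
  expect_true(all(s$breadth[arch == "silent"] == 0))
  expect_true(all(s$top_tissue[arch == "silent"] == "no_expression"))
  expect_true(all(s$breadth[arch == "broad"] == cfg$n_tissues))
  expect_true(all(s$tau[arch == "tissue_specific"] == 1))
  expect_true(all(s$top_tissue[arch == "sex_specific"] %in%
                    cfg$sex_tissues))
  expect_true(is.matrix(expr$values) && all(expr$values > 0))
})

test_that("the packaged age-count fixture expands to the printed counts", {
  t2 <- age_table2_genes()
  expect_identical(nrow(t2$ages), 10580L + 460L + 74L + 7L + 764L + 89L +
                     32L + 7L)
  expect_identical(sum(!t2$ages$young & !t2$ages$gene_id %in%
                         t2$gene_groups$gene_id), 10580L)
  expect_identical(sum(t2$ages$young &
                         t2$ages$gene_id %in% t2$gene_groups$gene_id[
                           t2$gene_groups$freq_group == "low"]), 89L)
  # strict DNA-based pairs with parent links
  dna <- t2$ages[t2$ages$mechanism == "dna_duplication" &
                   t2$ages$strict_parent_child, ]
  expect_identical(nrow(dna), 392L)
  expect_identical(anyNA(dna$parent_gene), FALSE)
  expect_identical(anyDuplicated(dna$parent_gene), 0L)
})

test_that("an all-zero mechanism config labels every gene 'none'", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 20, seed = 6)
  ages <- generate_age_table(sprintf("G%04d", 1:20), cfg,
                             mechanism_probs = c(dna_duplication = 0,
                                                 rna_duplication = 0,
                                                 de_novo = 0))
  expect_true(all(ages$mechanism == "none"))
  expect_identical(ages$young, ages$branch >= 1L)
})

test_that("infeasible chromosome length raises a configuration error", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 4, seed = 1,
                          chrom_length = 100)
  expect_error(generate_reference(cfg), "configuration error")
})
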