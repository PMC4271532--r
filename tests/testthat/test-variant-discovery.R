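# SNP classification: site filters, codon-level effect prediction with
# per-isoform truncation fractions, the constitutive 5% PTC rule, splice
# and start-loss flags, and strand symmetry.

test_that("site filters fail for het lines, low informative counts and non-biallelic sites", {
  base <- rep("A", 162)
  s_het <- make_site("A", replace(base, 5, "R"))
  expect_identical(site_filters(s_het)$reason, "heterozygous_line")

  syms <- c(rep("A", 40), rep("T", 19), rep("N", 103))  # 59 informative
  expect_identical(site_filters(make_site("A", syms))$reason,
                   "informative_lt_60")
  expect_true(site_filters(make_site("A", syms),
                           min_informative = 50)$pass)

  s_tri <- make_site("A", c(rep("A", 80), rep("C", 41), rep("G", 41)))
  expect_identical(site_filters(s_tri)$reason, "not_biallelic")

  s_ok <- make_site("A", c(rep("A", 120), rep("T", 42)))
  expect_true(site_filters(s_ok)$pass)
})

test_that("a stop gain at codon 10 of a 200-codon gene truncates ~0.955 and matches re-translation", {
  codons <- c("ATG", filler_codons(198), "TAA")
  codons[10] <- "CAG"
  toy <- build_toy_gene(codons)
  pos <- toy$cds2g((10 - 1) * 3 + 1)
  site <- make_site("C", c(rep("C", 150), rep("T", 12)), pos = pos)
  snp <- classify_coding_snp(site, toy$gene, toy$genome, alt = "T")
  expect_identical(snp$site_class, "nonsense")
  expect_true(snp$constitutive)
  expect_equal(snp$min_truncation, (200 - 10) / (200 - 1), tolerance = 1e-12)
  expect_equal(round(snp$min_truncation, 3), 0.955)
  # oracle: re-translate the mutant CDS and recompute the truncation
  cds <- extract_cds(toy$gene, toy$genome)
  mut <- cds
  substr(mut, (10 - 1) * 3 + 1, (10 - 1) * 3 + 1) <- "T"
  aa <- oracle_translate(mut)
  j <- regexpr("*", aa, fixed = TRUE)[1]
  expect_identical(j, 10L)
  expect_lt(j, nchar(aa))  # premature: strictly before the annotated stop
  expect_equal(snp$min_truncation, (nchar(aa) - j) / (nchar(aa) - 1))
  expect_true(call_constitutive_ptc(snp)$accept)
})

test_that("synonymous and missense substitutions classify correctly", {
  codons <- c("ATG", filler_codons(48), "TAA")
  codons[20] <- "GCT"
  toy <- build_toy_gene(codons)
  pos3 <- toy$cds2g((20 - 1) * 3 + 3)
  site <- make_site("T", c(rep("T", 100), rep("C", 62)), pos = pos3)
  snp <- classify_coding_snp(site, toy$gene, toy$genome, alt = "C")
  expect_identical(snp$site_class, "synonymous")  # GCT -> GCC, both Ala
  expect_identical(call_constitutive_ptc(snp)$reason, "not_nonsense")

  pos2 <- toy$cds2g((20 - 1) * 3 + 2)
  site2 <- make_site("C", c(rep("C", 100), rep("T", 62)), pos = pos2)
  snp2 <- classify_coding_snp(site2, toy$gene, toy$genome, alt = "T")
  expect_identical(snp2$site_class, "missense")  # GCT -> GTT, Ala -> Val
})

test_that("a nonsense change in one isoform but intronic in another is not constitutive", {
  codons <- c("ATG", filler_codons(58), "TAA")
  codons[25] <- "CAG"  # inside exon 2 (codons 11..40)
  toy <- build_toy_gene(codons, exon_nt = c(30, 90, 60),
                        isoform_exons = list(t1 = 1:3, t2 = c(1, 3)))
  pos <- toy$cds2g((25 - 1) * 3 + 1)
  site <- make_site("C", c(rep("C", 150), rep("T", 12)), pos = pos)
  snp <- classify_coding_snp(site, toy$gene, toy$genome, alt = "T")
  expect_identical(snp$site_class, "nonsense")
  expect_false(snp$constitutive)
  expect_identical(snp$per_isoform$in_cds, c(TRUE, FALSE))
  expect_identical(call_constitutive_ptc(snp)$reason, "not_constitutive")
})

test_that("the 5% truncation bound is inclusive", {
  # 101 codons: a stop gain at codon 96 removes 5/100 of the coding region
  codons <- c("ATG", filler_codons(99), "TAA")
  codons[96] <- "CAG"
  toy <- build_toy_gene(codons)
  site <- make_site("C", c(rep("C", 100), rep("T", 62)),
                    pos = toy$cds2g((96 - 1) * 3 + 1))
  snp <- classify_coding_snp(site, toy$gene, toy$genome, alt = "T")
  expect_equal(snp$min_truncation, 0.05)
  expect_true(call_constitutive_ptc(snp)$accept)

  codons2 <- c("ATG", filler_codons(999), "TAA")  # 1001 codons
  codons2[953] <- "CAG"  # truncation 48/1000 = 0.048 < 0.05
  toy2 <- build_toy_gene(codons2)
  site2 <- make_site("C", c(rep("C", 100), rep("T", 62)),
                     pos = toy2$cds2g((953 - 1) * 3 + 1))
  snp2 <- classify_coding_snp(site2, toy2$gene, toy2$genome, alt = "T")
  expect_lt(snp2$min_truncation, 0.05)
  expect_identical(call_constitutive_ptc(snp2)$reason, "truncation_lt_min")
})

test_that("splice flags cover only the first and last two intron bases", {
  codons <- c("ATG", filler_codons(38), "TAA")
  toy <- build_toy_gene(codons, exon_nt = c(60, 60),
                        introns = "GTACGCATTACAG")
  donor1 <- toy$l2g(toy$intr_start[1])
  donor3 <- toy$l2g(toy$intr_start[1] + 2L)
  acceptor <- toy$l2g(toy$intr_end[1])
  site <- function(p, ref) make_site(ref, c(rep(ref, 100), rep("A", 62)),
                                     pos = p)
  expect_true(call_splice_disruption(site(donor1, "G"), toy$gene,
                                     alt = "A"))
  expect_true(call_splice_disruption(site(acceptor, "G"), toy$gene,
                                     alt = "A"))
  expect_false(call_splice_disruption(site(donor3, "A"), toy$gene,
                                      alt = "C"))
})

test_that("minus-strand donor sites are flagged with strand-aware coordinates", {
  codons <- c("ATG", filler_codons(38), "TAA")
  toy <- build_toy_gene(codons, strand = "-", exon_nt = c(60, 60),
                        introns = "GTACGCATTACAG")
  donor_genomic <- toy$l2g(toy$intr_start[1])
  # on the reference strand the transcript's donor G reads as C
  ref <- substr(toy$genome[[1]], donor_genomic, donor_genomic)
  expect_identical(ref, "C")
  site <- make_site(ref, c(rep(ref, 100), rep("T", 62)), pos = donor_genomic)
  expect_true(call_splice_disruption(site, toy$gene, alt = "T"))
})

test_that("start-loss is flagged only when the ATG of every isoform is hit", {
  codons <- c("ATG", filler_codons(58), "TAA")
  toy <- build_toy_gene(codons, exon_nt = c(30, 90, 60),
                        isoform_exons = list(t1 = 1:3, t2 = c(1, 3)))
  p1 <- toy$cds2g(1)
  site <- make_site("A", c(rep("A", 100), rep("G", 62)), pos = p1)
  expect_true(call_start_loss(site, toy$gene, alt = "G"))
  # a site in codon 5 is not a start loss
  p5 <- toy$cds2g(13)
  site5 <- make_site(substr(toy$genome[[1]], p5, p5),
                     c(rep("G", 100), rep("A", 62)), pos = p5)
  expect_false(call_start_loss(site5, toy$gene, alt = "A"))
  # isoform-specific ATG (second isoform starting elsewhere) is not flagged
  g2 <- toy$gene
  g2$isoforms$alt_start <- g2$isoforms[[1]]
  g2$isoforms$alt_start$start[1] <- g2$isoforms$alt_start$start[1] + 3L
  expect_false(call_start_loss(site, g2, alt = "G"))
})

test_that("classification is invariant under reverse-complementing the locus", {
  codons <- c("ATG", filler_codons(118), "TAA")
  codons[30] <- "CAG"
  for (target in list(c("C", "T", (30 - 1) * 3 + 1),
                      c("C", "T", (60 - 1) * 3 + 3))) {
    fwd <- build_toy_gene(codons, strand = "+", exon_nt = c(180, 180))
    rev <- build_toy_gene(codons, strand = "-", exon_nt = c(180, 180))
    p <- as.integer(target[3])
    site_f <- make_site(target[1], c(rep(target[1], 80), rep(target[2], 20)),
                        pos = fwd$cds2g(p))
    site_r <- make_site(comp_base(target[1]),
                        c(rep(comp_base(target[1]), 80),
                          rep(comp_base(target[2]), 20)),
                        pos = rev$cds2g(p))
    snp_f <- classify_coding_snp(site_f, fwd$gene, fwd$genome,
                                 alt = target[2])
    snp_r <- classify_coding_snp(site_r, rev$gene, rev$genome,
                                 alt = comp_base(target[2]))
    expect_identical(snp_f$site_class, snp_r$site_class)
    expect_identical(snp_f$per_isoform$class, snp_r$per_isoform$class)
    expect_equal(snp_f$min_truncation, snp_r$min_truncation)
  }
})

test_that("each in-CDS isoform receives exactly one class", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 10, seed = 21,
                          planted_variants = default_planted_variants(8, 60))
  st <- simulate_ptc_study(cfg)
  v <- discover_variants(st$genome, st$genes, st$panel)
  coding <- st$truth[st$truth$class %in% c("nonsense", "missense",
                                           "synonymous"), ]
  for (i in seq_len(nrow(coding))) {
    g <- st$genes[[coding$gene_id[i]]]
    site <- extract_site_panel(st$panel, st$genome, coding$chrom[i],
                               coding$pos[i])
    snp <- classify_coding_snp(site, g, st$genome)
    per <- snp$per_isoform
    expect_true(all(per$class[per$in_cds] %in%
                      c("nonsense", "missense", "synonymous", "other")))
    expect_identical(nrow(per), length(g$isoforms))
  }
  expect_true(all(v$class %in% c("nonsense", "missense", "synonymous",
                                 "splice", "start_loss", "other")))
})

test_that("extract_site_panel validates its position and keeps raw symbols", {
  cfg <- synthetic_config(n_strains = 60, n_genes = 4, seed = 2,
                          n_mask_rate = 0.01)
  st <- simulate_ptc_study(cfg)
  expect_error(extract_site_panel(st$panel, st$genome, "2L", 10^9),
               "input error")
  site <- extract_site_panel(st$panel, st$genome, "2L", 50)
  expect_length(site$alleles, 60)
  expect_named(site$alleles, st$panel$strains)
})
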