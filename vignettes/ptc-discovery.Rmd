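---
title: "Calling and characterizing premature termination codons in a strain panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing premature termination codons in a strain panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A premature termination codon (PTC) is a point mutation that creates a stop
codon upstream of a gene's annotated stop, truncating the protein.  Surveys
of inbred strain panels — the motivating case is a *Drosophila
melanogaster* reference panel of 162 resequenced strains — find hundreds of
segregating PTCs, raising the question of which genes tolerate them.  Two
gene properties organize the answer: how broadly the gene is transcribed
(a proxy for pleiotropy) and how recently the gene originated.  `ptcpop`
implements the full analysis path: call PTCs conservatively from
pseudochromosome assemblies, polarize them against two outgroups, bin them
by derived allele frequency (DAF), and cross those bins with expression
breadth, tissue specificity, chromosome, gene age and origination
mechanism.

## The calling model

Variant calling works directly on **pseudochromosomes**: per-strain
chromosome-length consensus sequences on reference coordinates, with `N` at
unresolved positions and IUPAC ambiguity codes (`R,Y,S,W,K,M`) at sites the
assembly could not resolve to a single base.  At each position where any
strain differs from the reference, the pipeline applies three site filters:

* **no heterozygous line** — any strain carrying an ambiguity code
  disqualifies the site (inbred strains should be homozygous; a
  heterozygote signals assembly trouble);
* **informative depth** — at least 60 strains must carry an unambiguous
  A/C/G/T call, so DAF estimates have bounded error;
* **biallelic** — exactly two alleles, one of them the reference base.

Classification substitutes the alternate base into the affected codon of
*every* annotated isoform, strand-aware, and compares translations.  A stop
gain is a nonsense change; its **truncation fraction** in an isoform of
`T` codons (annotated stop included), with the new stop at codon `j`, is
`(T - j) / (T - 1)`.  This denominator choice (codons, excluding the
annotated stop from the countable coding region) is a documented
convention: the 5% rule below needs a precise definition and codon units
are frame-invariant.  A substitution creating a stop at the annotated stop
position truncates nothing and is not a PTC.

A PTC call is accepted iff it is

1. **constitutive** — a stop gain in *all* isoforms (a variant that is
   intronic or synonymous in any isoform is rejected), and
2. **consequential** — removes at least 5% of the coding region in each
   isoform (the bound is inclusive: exactly 5% passes).

Splice disruption is flagged for substitutions in the first two or last
two bases of any intron of any isoform — the minimal canonical GT/AG
definition of an intron boundary.  Start-codon loss is flagged with the
same constitutive logic as PTCs: the site must sit in the ATG of every
isoform.

### Upstream annotation QC

Before calling, gene models are dropped when any isoform (i) has a CDS
length not divisible by three, (ii) contains an internal stop in the
reference translation, or (iii) does not start with ATG or end with
TAA/TAG/TGA.  The annotated stop is taken to be the final three CDS
nucleotides, which makes rules (ii) and (iii) well-defined without UTR
knowledge.  Minus-strand genes are reverse-complemented before
translation and codon positions count in transcription order.

## Polarization and frequency groups

Ancestral states come from two outgroup genomes aligned to reference
coordinates.  The rule is deliberately conservative and anchored on the
reference base: a polymorphism is polarized **iff the reference base and
both outgroup bases are identical**, in which case the alternate allele is
derived.  Sites where the *alternate* allele matches both outgroups are
left unpolarized rather than polarized the other way — errors can only
shrink the polarized set, never flip an assignment.  DAF is the sample
frequency `n_derived / n_informative` over unambiguous calls, with no
finite-sample correction.

Frequency groups follow fixed cutoffs with inclusive left bins:
**low** (0, 1.5%], **moderate** (1.5%, 10%], **high** (10%, 100%].  A DAF
of exactly 1.5% is low and exactly 10% is moderate; the binning is
exhaustive and mutually exclusive by construction.  A gene carrying
several accepted PTCs is counted once, in the group of its highest-DAF
variant.

## Expression analysis

Expression arrives as a gene × (tissue × replicate) matrix of linear
signal values with per-array present/absent calls (30 tissues and 4
replicates per tissue in the emulated design).  The analysis steps:

* **breadth** — the number of tissues where the gene is present in *all*
  replicates;
* **normalization** — per array, log10-transform, subtract the array mean
  and add the grand mean; per tissue, the gene's value is the median of
  its normalized replicates;
* **decile profiles** — per tissue, genes present in all replicates are
  split into ten equal-density groups (sizes differ by at most one gene;
  ties break deterministically by value then gene id), absent genes get
  group 0;
* **τ (tau)** — computed on the decile profile:
  `τ = Σ_i (1 − x_i / x_max) / (N − 1)` over all `N` tissues, group-0
  tissues included in `N`.  τ is undefined (not 0) for genes absent
  everywhere, since `x_max = 0`.  Tissue-specific gene sets use a strict
  cutoff, τ > 0.85;
* **top tissue** — the argmax of the normalized per-tissue medians among
  qualifying tissues, `"no_expression"` when none qualifies; exact ties go
  to the lexicographically smallest label and are reported.

The **allele-imbalance test** compares, per variant, the host gene's
whole-body expression between derived-allele and ancestral-allele strains
with a two-sided Wilcoxon rank-sum test (at least two strains per class).
Multiple testing uses Storey q-values with the fixed `λ = 0.5` estimator,
`π₀ = min(1, mean(p > 0.5) / 0.5)`: the spline extrapolation is noisy on
small variant sets, while the fixed-λ estimator is reproducible and
asymptotically close.  Significance is q < 0.05.

## Enrichment statistics

Top-tissue category counts for a PTC group are modelled as a multinomial
with the genome-wide category proportions.  The simultaneous confidence
ribbon is built by Monte Carlo (default 100,000 seeded draws), taking
per-category quantiles at the Šidák-adjusted level
`1 − (1 − α)^(1/K)` so family-wide coverage is ≈ 95%.  Šidák assumes
independence; multinomial counts are negatively correlated, so the band is
slightly conservative, which the coverage test tolerates.  All 2×2
enrichments (group vs genome, X vs autosomes, young vs old,
mechanism-vs-mechanism) use Fisher's exact test, two-sided unless a
directional hypothesis is stated.

## Gene age and origination mechanism

Gene ages arrive as a table: branch label (young branches 1–6, old
branches −5–0), young/old flag, origination mechanism (DNA-based
duplication, RNA-based duplication/retroposition, de novo), optional
parent link, and a strict flag marking pairs whose parent is strictly
older.  The package cross-tabulates PTC frequency columns against age and
mechanism (strict and raw variants; strict counts can never exceed raw),
compares parent vs child PTC proportions over the strict DNA-based pairs,
and fits the per-branch PTC fraction against branch midpoints (Spearman
plus least squares, with optional exclusion of branches such as the
youngest, whose members suffer read-mapping dropout in real panels).

Duplicate-pair ages are proxied by synonymous divergence, computed with
**NG86 pathway counting**: per-codon synonymous site fractions averaged
between the two sequences, equal-weight averaging over substitution
pathways (pathways through stop codons excluded), and the Jukes–Cantor
correction `dS = −(3/4) ln(1 − (4/3) pS)`, undefined (flagged saturated)
at `pS ≥ 0.75`.  NG86 was chosen over likelihood methods because it is
exactly testable against a brute-force enumeration oracle, which the test
suite runs over an exhaustive stop-free codon sweep; the downstream use
(the shape contrast between DNA-based and RNA-based duplicate dS
distributions) is qualitative.

A packaged fixture (`inst/extdata/age_ptc_counts.tsv`) carries the
published age × frequency × mechanism gene counts;
`age_table2_genes()` expands it into a deterministic per-gene table with
exactly those marginals.  The count of PTC-carrying parent genes is
apportioned to the low-frequency group — the only cell the published
totals do not constrain — and parent identities are synthetic.

## Robustness resampling

Sanger validation of PTC calls in the emulated study estimated
group-specific false positive rates of 20% (low), 13% (moderate) and 0%
(high).  `make_pseudo_dataset()` removes each variant independently with
its group's FPR (Bernoulli removal; a fixed-count mode exists behind a
flag, since the source procedure does not specify which was used), and
`resampled_summary()` re-runs any summary over 100 seeded replicates,
reporting medians, 2.5–97.5% bands and the fraction of replicates
preserving each headline inequality.

## The synthetic-data generator

The generator exists so every stage is testable with known truth and no
downloads.  Its defaults mirror the emulated study design: 162 strains, 30
adult tissues of which six are sex-related, four replicates per tissue,
and a genome of multi-isoform genes on both strands with GT..AG introns.
Generated genes pass annotation QC by construction: codon-aligned exons
drawn from sense codons, ATG start, canonical stop, and isoforms that skip
internal exons only (so frame and termini survive skipping).

Planted variants are realized by *overwriting the reference codon* at the
chosen site with a motif one substitution away from the intended effect
(e.g. CAG→TAG for nonsense), then giving the alternate base to
`round(target_daf × n_strains)` randomly chosen strains.  Nonsense plants
honour a target truncation fraction by codon placement, clamped into
exons shared by all isoforms when the plant must be constitutive.
Heterozygote codes and `N` masks are injected per-cell at configured
rates, never at planted sites, so realized allele counts stay exact.
Outgroup tables carry the ancestral base at polarizable sites and the
alternate base at sites planted `ancestral_is_ref = FALSE`; independent
per-outgroup substitution at the configured divergence rate makes a
predictable fraction unpolarizable.

Expression archetypes are `broad` (present in every tissue),
`tissue_specific` (one tissue), `sex_specific` (one sex-related tissue)
and `silent` (absent everywhere, positive background signal), with
default mixture 0.55 / 0.20 / 0.10 / 0.15 — broad transcription dominates
real transcriptomes, and the silent share is large enough to exercise the
no-expression paths.  Replicates are noisy copies; present calls are
archetype-determined, so breadth and τ have exact expected values in
tests.  A strain-level expression generator multiplies PTC carriers'
expression by a configurable factor (default 0.4) to mimic
nonsense-mediated decay for allele-imbalance tests.

What the generator does **not** emulate: linkage and demography (sites
are independent), indels and structural variants (excluded by design
upstream too), sequencing-error processes (masking is uniform), gene
families and homology (ages and mechanisms are assigned, not evolved),
and realistic expression covariance across tissues.  Passing tests
therefore certify the *computational* pipeline — classification,
filtering, counting and statistics — not the biological error modes of
real assemblies.

## Numerical and design choices

* Coordinates are 1-based inclusive at every public interface (as in
  GFF3).
* Group boundaries (≤ 1.5%, ≤ 10%) are inclusive on the left-hand group.
* The truncation denominator excludes the annotated stop codon; the 5%
  bound is inclusive.
* Sample-monomorphic sites (all strains differ from the reference
  identically) are not polymorphisms and are skipped.
* Multi-allelic handling: sites failing the biallelic filter are
  reported with the most frequent non-reference allele and a fail flag,
  never called.
* Frequency-matched control sampling (`daf_matched_sample`) matches each
  template DAF to the nearest unused pool variant, exact bins preferred,
  without replacement, seeded.
* Degenerate inputs return structured emptiness rather than errors:
  empty spectra, empty histogram bins, `NA` Spearman rho for constant
  fractions, p = 1 for single-gene groups.
* All randomness is seeded; identical seeds give byte-identical outputs,
  and resampling replicates are deterministic in `(seed, replicate)`.

Test and example problem sizes — panels of 60–100 strains, genomes of
10–200 genes, 1,000-variant null calibrations, 100 resampling replicates
— were chosen so the whole suite exercises every code path at full
planted-recovery stringency while remaining quick on a laptop.

## Known limitations

* The polarization rule discards sites where the alternate allele matches
  both outgroups; this loses real derived-reference sites by design.
* τ on decile profiles is coarser than τ on continuous values; the 0.85
  cutoff is calibrated for the decile scale.
* NG86 is a counting method; for highly diverged pairs (`pS ≥ 0.75`) dS
  is reported as saturated rather than extrapolated.
* The multinomial ribbon's Šidák adjustment over-covers slightly for
  small groups with few categories.
* Independent evaluation of multiple SNPs within one codon (each against
  the reference background) ignores haplotype effects, which were rare in
  the emulated study's validation data.
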