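---
title: "Diagnosing a wild F1 hybrid: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing a wild F1 hybrid: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

When two historically allopatric species come into secondary contact — for
instance a tropical species expanding poleward into the range of a temperate
one — a putative wild hybrid may be found on phenotype alone. Confirming its
identity and generation (F1 versus backcross versus later-generation hybrid)
from moderate-coverage resequencing data rests on a small set of
complementary statistics, each of which this package implements and tests:

1. **Maternal ancestry** from a masked mitochondrial consensus matched
   against candidate species.
2. **Biparental ancestry** from phased haplotype blocks, each of whose two
   haplotypes is assigned to its closest candidate parent: a true F1 should
   split its blocks evenly between the two parents, because every block
   carries one haplotype from each.
3. **Triangle statistics**: the hybrid index $h$ (proportion of alleles from
   one parental class across ancestry-informative markers) and interclass
   heterozygosity $H$ (proportion of AIMs carrying one allele from each
   class). An F1 sits at the apex $(h, H) = (0.5, 1)$; backcrosses drift
   toward a parent vertex along the triangle edge.
4. **Windowed heterozygosity** in a conserved gene, where a "synthetic
   hybrid" — one haplotype from each species paired in silico — provides the
   heterozygosity a true F1 must show, for comparison against the natural
   hybrid and against within-species levels.
5. **Occurrence accounting**: how often the two species are recorded
   together on citizen-science checklists, with vagrant filtering, spatial
   thinning, presence/absence threshold selection, and the geometry of the
   overlap between their climatic niches.

Because the original study's inputs (multi-gigabyte read sets, assemblies,
checklist extracts, climate normals) are not desk-scale, the package couples
every analysis step to a seeded synthetic-data generator with recorded
ground truth, so each statistic can be validated by parameter recovery.

# The synthetic-data generator

`simulate_species_pair()` draws an ancestral sequence and makes each site
independently a fixed difference with probability `divergence`, or
polymorphic within one lineage with probability `polymorphism`
(minor-allele frequencies uniform on [0.05, 0.5]). A short mitochondrial
replicon is simulated separately and inherited strictly maternally, with no
heteroplasmy. `simulate_cross()` composes gametes: pure-lineage gametes
sample minor alleles at the lineage's polymorphic sites; gametes from an F1
parent recombine the two lineages with a Poisson number of crossovers
(`recomb_rate`, default 2 per gamete) at uniform positions — the simplest
model adequate for distinguishing F1 from backcross or F2 ancestry. Truth
tracts (per-haplotype ancestry intervals) and the maternal lineage are
recorded on every individual.

`simulate_pileup()` gives every position a Poisson read depth, draws each
read's base from one of the two haplotypes, substitutes errors at
`error_rate`, and attaches base/mapping qualities from rounded, clipped
normal distributions. The masking rule only consumes qualities through a
threshold, so any spread straddling the threshold exercises it; defaults
(BQ ~ N(32, 8), MQ ~ N(42, 12), clipped to 0–60) put modest mass below 20.

`simulate_phase_blocks()` emulates read-backed phasing at modest coverage:
block extents follow a gamma distribution with default mean 339 bp and SD
118 bp (short blocks of a few hundred bases, the regime where per-block
parental assignment is the natural unit), the variants of a block are the
individual's heterozygous sites within its span, and haplotype orientation
is randomized per block, since phasing carries no orientation across
blocks. Switch errors exchange the haplotypes from a variant onward with a
per-interval probability. Block length is defined as
`last variant − first variant + 1`: blocks are delimited by their phased
variants, and the convention is pinned by tests.

`simulate_checklists()` generates localities with fixed coordinates,
per-locality residency for the two focal species, Poisson checklist counts
per year, detection of residents at a per-locality rate, and vagrant
records of non-residents at a small per-checklist rate. Residency and
vagrant labels are kept as attributes so that the retention filters can be
validated against truth.

What the generator does *not* emulate — coalescent demography, linkage
disequilibrium beyond tract structure, indels, alignment artefacts,
reference bias, spatially autocorrelated survey effort — bounds what
passing tests show about real data: they validate the statistics and their
implementations, not the upstream alignment/calling stack.

# Consensus masking

`masked_consensus()` implements the 20/20 rule: a read base contributes to
the consensus only if both its base quality and mapping quality reach the
thresholds, and the "and/or" of the rule is taken as OR — masking when
either quality is low — which is the conservative reading for a
high-quality consensus. Thresholds are strict-below ("below 20" fails), so
a quality of exactly 20 passes. A position is masked `no_depth` with zero
reads, `low_bq`/`low_mq` when no read passes (labelled by the quality that
failed), and `ambiguous` on a majority tie among passing reads: no tie
rule is stated for consensus calling anywhere upstream, and ambiguity
should not fabricate a base. The `ambiguous` reason is an addition to the
reason vocabulary forced by the tie rule itself.

One subtlety is pinned in tests rather than hidden: masking is monotone in
the thresholds (raising them never unmasks) for the quality rule itself,
i.e. on evidence without majority ties. A tie that involves a discordant
low-quality read can, in principle, resolve into a clean majority once a
stricter threshold excludes that read; we keep the tie rule anyway because
fabricating bases is worse than occasionally unmasking one.

`coverage_fraction()` is the unmasked share of the region — the quantity
reported for a mitochondrial consensus covering a fraction of its
reference scaffold.

# Phase-block assignment

Blocks are filtered to `>= 10` variant positions and `>= 100` bp before
assignment; both thresholds are closed (a 10-variant, 100-bp block is
kept). Each haplotype consensus is scored against every candidate by local
affine-gap alignment with match +2, mismatch −3, gap open 5, gap extend 2 —
parameters chosen to mimic default nucleotide BLAST ranking; the decision
semantics (rank by score, tie on equal score) are preserved without
promising bit-score reproduction. Identity is matches over alignment
length, gaps counting against identity. Candidates below the 97% identity
gate are excluded *before* ranking; the survivors' equal top scores form a
tie-set category. Gate-first-then-rank is a deliberate, test-pinned
interpretation — the alternative (rank first, then gate) is equally
defensible on the source material.

Two practical notes. First, a local alignment against a *non-homologous*
sequence typically finds a short perfect segment whose identity is 1.0, so
the identity gate is only meaningful for homologous candidates of
substantial aligned length; ranking by score is what keeps junk hits out
of the top position. Second, `tally_top_hits()` scores each haplotype
against the homologous span of each coordinate-matched candidate (block
span ± 100 bp) rather than a whole scaffold — the decision-equivalent,
desk-scale analogue of restricting the search database to one homologous
scaffold. Queries more than 50% `N` are dropped and counted separately.

`f1_balance_test()` turns the F1 expectation — roughly equal block counts
per parent — into a two-sided exact binomial test of the two parents'
single-label counts against 0.5.

# Triangle statistics

`discover_aims()` computes per-site allele frequencies in each parental
group and keeps biallelic sites with frequency difference `delta` or more
(closed comparison, so `delta = 1` admits exactly the sites fixed for
alternate alleles). With a single diploid per parent — the study design the
generator mirrors — frequencies take values in {0, 0.5, 1} and δ = 1.0
selects opposite homozygotes; the API accepts arbitrarily many parental
samples. Missing data policy: a sample's AIM is excluded (and counted)
when either allele falls outside the two parental classes; no imputation.

For a genotyped sample, $h$ is the fraction of its alleles from the
parent-2 class and $H$ the fraction of AIMs with one allele from each
class. Under error-free simulation these recover their pedigree values
exactly (F1) or in expectation (BC1: $E[h] = 0.25$, $E[H] = 0.5$; F2:
$0.5/0.5$), which the tests check by Monte Carlo within three standard
errors. Independent per-allele genotyping error $e$ moves an F1's
heterozygosity to
$((1-e)^2 + (e/3)^2) / (1 - 2e/3)^2 \approx 1 - 2e$,
the closed form the error-recovery tests pin at $e \in \{0.01, 0.05\}$.

`triangle_coordinates()` flags feasibility, $H \le 2\min(h, 1-h)$ (with a
$10^{-9}$ numeric allowance), and `plot()` draws the triangle.

# Window heterozygosity and synthetic hybrids

`per_site_heterozygosity()` divides differing comparable sites by
comparable sites, where comparable means both haplotypes call a plain base
— masked `N` and alignment gap columns leave both numerator and
denominator. The callable-sites denominator (rather than full window
length) is a deliberate, test-pinned choice: masked bases carry no
genotype information. `make_synthetic_hybrid()` pairs one haplotype from
each species; equal-length windows pair on shared coordinates, others are
aligned globally with free end gaps, refusing length mismatches beyond 20%.
Its expected heterozygosity equals the per-site divergence of the window,
an order of magnitude above within-species polymorphism under the default
parameterization — the contrast that makes a natural F1's window
heterozygosity diagnostic.

# Checklist filtering and niche overlap

An observation of a species is retained if its locality satisfies either
criterion: detections in at least two separate years within the
2019–2023-05-31 window, or detections on at least 50% of the checklists
ever submitted at the locality. The second criterion's denominator is
deliberately all-time, not window-restricted, following the definition of
the filter; it damps vagrant records without rewarding heavily surveyed
sites. Absence localities are those surveyed in every year 2019–2023 with
no detection in that period.

`thin_grid()` keeps one observation per 10-km cell. Cells are built from
an equal-distance approximation: latitude cells of 10 km, and longitude
cells of 10 km at the centre of each point's 1° latitude band. Cell
membership therefore depends only on a point's own coordinates, which
makes thinning idempotent by construction — a property that would fail if
the longitude scaling were derived from the extent of whatever subset is
being thinned. A fixed `center_lat` override restores plain
single-latitude scaling.

Suitability modelling is pluggable; the bundled `fit_envelope_model()` is
a Gaussian distance-envelope scorer, present to exercise threshold
selection and overlap geometry, not a covariate-based niche model.
`youden_threshold()` maximizes sensitivity plus specificity over all
midpoints between consecutive observed scores (classifying
`score >= threshold` as presence), breaking ties toward the lowest
threshold; it is property-tested against brute-force search.
`binarize_and_overlap()` takes the cell-wise AND of the binarized
surfaces and reports area as the sum of spherical-rectangle cell areas
($R^2\,\Delta\lambda\,(\sin\varphi_2 - \sin\varphi_1)$, $R = 6371.0088$
km) with an area-weighted cell-centre centroid — stated conventions, since
no polygon-area method is canonical at this scale.

# Numerical and interface conventions

* Coordinates are 1-based and closed everywhere in R objects, matching the
  R/Bioconductor ecosystem; the BED writer converts to 0-based half-open,
  and the VCF writer emits standard 1-based records with `PS` phase-set
  tags.
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state; seeded runs are bit-reproducible, which the pipeline
  test checks by comparing serialized reports byte for byte.
* Score ties in ranking use a $10^{-9}$ tolerance; δ comparisons allow
  $10^{-12}$ slack; degenerate inputs (all-`N` queries, all-equal scores,
  single-class labels, empty block lists, zero genotyped AIMs) raise
  errors rather than returning silent defaults.

# Problem sizes used by the test-suite

The suite validates distributional claims at the smallest sizes where the
statistics are stable: a 280-kb two-lineage genome (~800 phase blocks,
~590 after filtering) for block-balance and truth-tract recovery; 1,000
fixed sites for exact F1 apex recovery; 4,000-site panels with 200
individuals per pedigree class for Monte-Carlo means; 4.85-kb windows for
divergence recovery at $d \in \{0.005, 0.0165, 0.05\}$; and 100 random
labelled score sets for the threshold oracle. Monte-Carlo bands are three
standard errors; binomial bands three binomial SDs.

# Known limitations

* The alignment scorer reproduces BLAST's decision semantics, not its
  scores; studies needing bit-score-faithful ties should rerun the
  assignment with an external BLAST and feed the tallies back in.
* AIMs from single diploid parents treat drift-fixed polymorphism as fixed
  difference; the package reports the usable-AIM count but cannot correct
  the ascertainment.
* The envelope suitability model is a placeholder interface; overlap areas
  from it characterize the accounting, not any real niche.
* Reference bias (all blocks called against one reference) is represented
  in the simulator only implicitly and is not corrected.
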