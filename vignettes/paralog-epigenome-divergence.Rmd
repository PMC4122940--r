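---
title: "Quantifying epigenome divergence between paralogous regions"
author: "paradiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epigenome divergence between paralogous regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradiverge)
```

## The scientific question

Segmental duplications copy a stretch of DNA — often including CpG islands,
enhancers and promoters — into a new genomic location. Because both copies
then sit in the *same* cell, comparing DNA methylation and chromatin state
between the two copies measures epigenome divergence since the duplication
while controlling for the biological and technical variation that plagues
between-sample comparisons. `paradiverge` implements that within-sample
design end to end: it pairs CpG sites across duplicon copies at base
resolution, calls methylation and chromatin discordance with exact tests,
places discordance in its genomic context (TSS distance, CpG island shores,
repeats, duplicon junctions), extends the logic across species to
lineage-specific Alu insertions and their methylation "spread", and fits an
interaction model linking differentiation-associated methylation change to
paralog divergence.

Every analysis runs against a synthetic-data generator with planted ground
truth, so the statistical machinery is testable without any restricted or
large external dataset.

## Coordinate maps between duplicon copies

A duplicon is a pair of regions longer than 1 kb aligning at more than 90%
identity; records failing either bound are rejected at parse time (the
length rule is applied to the alignment span of the first copy — the
convention had to be fixed one way and the span is what the alignment
actually covers). All coordinates are 0-based half-open internally;
conversion to 1-based conventions happens only at the
`rtracklayer`/`Biostrings` boundary.

The aligned, gapped sequence pair defines a column-level coordinate map.
Copy A is always stored on its plus strand; copy B is stored in the
orientation matching A, so inverted duplications simply walk copy B's plus
strand backwards. Projection through the map is an involution on ungapped
columns — a property the tests fuzz over randomly gapped and inverted
alignments (10^5 positions).

A paralogous CpG pair requires the CG dinucleotide on *both* copies' own
plus strands. CG is its own reverse complement, so inversion maps CpGs to
CpGs; the plus-strand C of the inverted partner is the aligned position of
the source G. Reads from the two strands of one dinucleotide report the
same methylation state and are summed into a single site keyed by the
plus-strand C (the field's usual destranding; declared here because
strand-resolved input is also accepted).

## Methylation discordance

Counts are filtered before testing: at least 6 reads on each copy, at most
100 across the pair (at very high depth, biologically trivial differences
become formally significant), no known SNP on the cytosine or either
flanking base, no alternative-allele reads, and read-level cytosine
evidence where available. The SNP window is three bases centred on the C.
A pair failing several rules is tallied under the first, in a fixed order,
so rejection counts always sum to the input count.

Discordance is a two-sided Fisher exact test on the 2x2 table of
methylated/unmethylated counts, called at p < 5e-7 (approximately a
Bonferroni-corrected 0.05 at the scale of a genome-wide screen; an option
recomputes 0.05/n for other dataset sizes — at n = 82,692 pairs that gives
6.05e-7, consistent with the fixed default). Two-sidedness follows the
minimum-likelihood convention with the same 1e-7 relative tie tolerance as
`stats::fisher.test`, and the implementation is a vectorised enumeration
over the hypergeometric support: a screen touches 10^4–10^5 tables, where
repeated `fisher.test` calls are the bottleneck. The tests verify exact
agreement (to 1e-12) with both `stats::fisher.test` and an independent
binomial-coefficient enumeration over *all* tables with row margins up to
30.

Concordance is summarised as the proportion of pairs within 0.20 absolute
difference plus a Spearman correlation. Its significance comes from a
region-shuffling permutation null: the second member of every pair is
re-drawn without replacement from the pooled set of all paired sites
(random re-pairing across all duplicated regions). A defensible alternative
reading — shuffling the second members among pairs — is available behind
`scheme = "shuffle"`; both destroy the paralogous pairing while preserving
the marginal level distribution, and both are calibrated (uniform p under a
paralog-free null) in the tests. The empirical p is
`(#{perm >= obs} + 1) / (n_perm + 1)`, so 100 permutations bound it below
at 1/101 < 0.01.

For motif export, discordant pairs within 1 kb of each other (on the
corresponding copy) are thinned to one per locus, the survivor chosen
arbitrarily under a fixed seed.

## Chromatin divergence

Read tracks are compared in nonoverlapping 500-bp windows tiled from the
duplicon start. A window position enters the analysis only when it is
ungapped and uniquely mappable in *both* copies — masking is symmetric, so
a mappability hole in either copy silences the position in both. Reads are
assigned to windows by their 5'-most mapped position, which conserves
counts across tiles (the assignment rule is not dictated by the design;
5'-end assignment was chosen as the unambiguous count-conserving option).

Because both windows come from the same library, the null is a fair coin:
a two-sided exact binomial test of the copy-A count against the window
total at probability 0.5, with no library-size normalisation. A window is
called discordant only when its Bonferroni-corrected p (corrected over the
testable windows of that mark; per-mark rather than global correction) is
below 0.05 *and* one copy has exactly zero reads — restricting calls to
complete loss of the feature on one copy, not mere quantitative skew.

## Lineage-specific Alu insertions and methylation spread

Across species the same logic applies with genomes in place of duplicon
copies. Orthology is taken from UCSC-style alignment chains
(`rtracklayer::import.chain` / `liftOver`). A repeat element is a
lineage-specific insertion when under 10% of its span is covered by
alignment blocks in *both* outgroup chains while both 200-bp flanks are at
least half covered in both — the flank condition distinguishes a true
insertion inside syntenic sequence from generally unalignable regions. The
10% / 50% thresholds are this package's choices (an absence criterion has
to tolerate alignment edge slop); on clean chains detection is exact, and
the tests require 100% sensitivity and precision there.

Orthologous CpG sites (combined depth of at least 5 in each species) are
profiled by distance to the nearest insertion breakpoint in sliding 500-bp
windows advanced by 100 bp, with normal-approximation 95% confidence
intervals; a paired t-test compares species within 1 kb of insertion
sites. Distance is measured to the nearest element breakpoint rather than
the midpoint, so it does not depend on element length. Sites of low
outgroup methylation (< 0.4) within 2 kb of an insertion form the
background set; those gaining at least 0.6 in the insertion lineage are
the remodelled foreground, exported for external enrichment tools. Genes
whose promoter (TSS plus or minus 2 kb — a conventional promoter window; the
threshold is configurable) contains a foreground site are tallied by the
sign of their between-species expression difference with an exact sign
test.

For interchromosomal duplications, ancestral and derived copies are
resolved by lifting both CpG sites to the outgroup: if both land on the
same outgroup chromosome, the copy on the syntenic reference chromosome is
ancestral; any failed or ambiguous lift yields "undetermined" rather than
a guess.

## The differentiation interaction model

For each CpG site, let `x1` be its methylation level in the base cell
type, `x2` its signed change after differentiation, and `y` its absolute
methylation difference to the paralogous copy. The model is ordinary least
squares with an interaction:

$$Y_i = \beta_0 + \beta_1 X_{i1} + \beta_2 X_{i2} + \beta_3 X_{i1} X_{i2} + \epsilon_i$$

Four distinct coefficients are fitted; the response is the absolute
paralog difference by default (a signed variant is a one-line change in
the input construction, but absolute divergence is the quantity of
interest). Constant predictors abort with the offending column named
rather than silently dropping a rank-deficient term. Binned summaries use
equal-count bins per axis (rank-then-split with stable ordering, so ties
break deterministically and bin sizes differ by at most one).

## The synthetic-data generator

`simulate_dataset()` emits a full study bundle: a CpG-scrubbed random
genome with duplicons planted as mutated (optionally inverted or
interchromosomal) copies; per-CpG bisulfite coverage for a base and a
differentiated cell type; chromatin read tracks; mappability, SNP, CpG
island, TSS and repeat annotations; chains to two outgroup genomes; a
cross-species coverage pair; an expression table; and a `truth.json`
recording everything planted.

Generative choices, and why:

* **Beta-binomial counts** (`bb_dispersion`, default 0.02) over
  negative-binomial depths (`depth_mean` 30, `depth_dispersion` 0.05):
  captures biological overdispersion and degrades gracefully to
  binomial/Poisson at zero. The depth dispersion was fixed by a
  design-time power analysis: planted discordant pairs (difference 0.9)
  at mean depth 30 must survive the 6/100 depth filters and reach 5e-7,
  which holds with clear margin at dispersion 0.05 but sits on the knife
  edge by 0.15.
* **Bimodal methylation** (35% low around 0.08, 65% high around 0.88):
  the canonical genome-wide methylation landscape.
* **Discordant pairs** are planted at an absolute difference of 0.9
  (levels 0.95 vs 0.05), the regime the discordance caller is meant to
  find.
* **Paralog divergence is generated from the interaction model itself**
  with coefficients (0.03, 0.02, 0.5, -1.0) and Gaussian noise 0.05:
  divergence grows with the magnitude of differentiation change and is
  largest away from mid-range levels, while staying non-negative without
  clamping distortion; the direction of paralog change follows the
  direction of differentiation change.
* **Insertion spread** is an exponential elevation of expected
  methylation, `max_elevation * exp(-d / decay)` (defaults 0.2 and
  300 bp) — the simplest monotone model of methylation seeding from a
  repeat and decaying with distance. A handful of "remodelled" flank
  sites (outgroup 0.10, reference 0.85) plant the strong low-to-high
  transitions the foreground selection looks for.
* **Outgroups are deletion-of-the-insertion chains**: lineage-specific
  elements and derived duplicon spans appear as reference-side gaps,
  outgroup-specific insertions as query-side gaps, and each non-inverted
  derived duplicon gets a paralogy chain to its ancestral outgroup locus
  (inverted derived copies are left unmapped and resolve to
  "undetermined", mirroring real liftover failure).
* **Inverted duplicons** are generated with probability 0.25 so CpG
  pairing is exercised on both orientations.

What the generator does **not** emulate: raw reads or bisulfite
conversion chemistry (counts are drawn directly); alignment error and
chain noise; hierarchical or overlapping duplications (each source has
one target); non-CpG methylation; realistic repeat sequence content
(repeat annotations are intervals, not sequence). Passing tests therefore
demonstrate that the statistical machinery recovers planted structure
under a faithful but idealised data model — not that real data meet the
model's assumptions.

## Numerical choices and problem sizes

Exact-test ties use a 1e-7 relative tolerance, matching the base-R
convention, in both the implementation and its oracles. Permutations,
dedupe choices and every generator draw run off a single integer seed;
the pipeline derives stage seeds from it, and two runs with the same seed
produce byte-identical summaries.

The default study simulates two 700-kb chromosomes with 30 duplicons
(~600 CpG pairs), 20 insertions per lineage and ~3,500 orthologous CpG
sites — sizes chosen so the full pipeline completes in well under a minute
while every stage still has planted structure to find. Calibration tests
use 200 replicate null datasets; recovery tests use 5,000 pairs with 50
planted discordances.

## Known limitations

* The discordance test treats read counts as independent Bernoulli
  trials; clonal reads or allele-specific methylation would violate this.
* The permutation null re-pairs sites without preserving local CpG
  density, which is adequate for a concordance statistic but would be
  anticonservative for statistics sensitive to density itself.
* Ancestral assignment trusts a single outgroup chain plus a synteny
  table; lineage sorting or outgroup-specific rearrangement would
  mislead it.
* The normal-approximation CI in the flanking profile is poor for
  windows with very few sites; such windows are reported with their n so
  downstream consumers can ignore them (a bootstrap alternative was
  considered and rejected as overkill for a descriptive profile).
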