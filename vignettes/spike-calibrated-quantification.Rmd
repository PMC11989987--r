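---
title: "Spike-in calibrated absolute quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated absolute quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it
implements: the quantification model and its assumptions, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the choices made where the design was genuinely open.

## The quantification model

Every sample receives a fixed number `C` of cells of each of two
exogenous calibrator species before DNA extraction — by default
*Imtechella halotolerans* (`Copy16S = 3`) and *Allobacillus
halotolerans* (`Copy16S = 7`) at `C = 500` cells each, the composition
of a widely used commercial spike-in standard. The only modelling
assumption is within-sample proportionality:

> reads assigned to a taxon ∝ (cells of that taxon) × (genomic 16S
> copies per cell),

with one unknown proportionality constant per sample. Each calibrator
measures that constant independently, giving two estimates of any
taxon's cell count; the package reports their arithmetic mean:

$$AB_X = \frac{1}{2}\left(\frac{N_X}{N_{Ih}}\,C\,\frac{3}{Copy16S_X}
 + \frac{N_X}{N_{Ah}}\,C\,\frac{7}{Copy16S_X}\right).$$

Two identities follow and are enforced by tests: the estimate is
linear in $N_X$ at fixed calibrator counts, and under exact
proportionality each calibrator's own estimate equals $C$ and the two
single-calibrator estimates of any taxon coincide. What the model does
**not** correct is taxon-specific extraction or amplification
efficiency: a hard-to-lyse organism is underestimated by exactly its
recovery deficit relative to the calibrators.

`Copy16S_X` is the median genomic 16S copy number of the species; when
no species entry exists the lookup walks up the lineage
(genus → … → domain) and finally falls to a dataset-wide default. The
shipped simulator default is 4.2 copies, a plausible bacterial median;
it is configurable because no terminal value is canonical. The walk
depends only on table content, never on row order.

## Sample quality control

Two exclusion rules run before any quantification:

* **Undetected calibrator** (either count zero): the sample's read
  scale is unusable.
* **Aberrant read ratio**: the Allobacillus/Imtechella read ratio has
  ideal value $7/3 \approx 2.33$; the default acceptance interval is
  `[0.1, 10]`, a symmetric decade around unity. Real retained samples
  cluster within a few-fold of the ideal, while failure modes produce
  ratios in the hundreds to thousands, so any decade-scale interval
  separates the two regimes cleanly; the bounds are exposed because
  the choice within that wide no-man's-land is arbitrary.

## Filtering and aggregation

zOTUs whose **total count across all samples** is ≤ 10 are removed
before aggregation. The scope (per dataset rather than per sample)
follows the convention of the UNOISE-family denoisers that produce
zOTU tables; the threshold is a parameter. Counts are then summed per
species or per genus name. zOTUs unclassified at the target rank are
pooled per lowest classified ancestor as `"<ancestor> unclassified"`,
so pools under different ancestors (e.g. *Atopostipes* vs
*Fretibacterium*) remain distinct rows. Aggregation conserves reads
exactly, a property tested on random tables. Genus-level abundances
are computed from genus-aggregated counts (not re-derived from species
rows), so a genus row includes its unclassified-species reads.

## Sporadic-enrichment screening

Low-biomass case samples may carry genuine taxa in only one or two
individuals, which paired group tests cannot see. The screen flags a
taxon when (a) its abundance reaches `min_pulp_cells` (default 20)
cell equivalents in at least one pulp sample and (b) that maximum is
at least `min_fold` (default 20) times the highest abundance in *any*
dentin or control sample. A taxon absent from all background samples
passes (b) vacuously. Both thresholds are monotone: raising either can
only remove hits. Calibrator rows are excluded from the screen — and
from every biological output — because spiked organisms are controls,
not findings.

## Paired testing and multiplicity

Pulp is compared to dentin and to reagent controls on patient-matched
pairs with the Wilcoxon signed-rank test. Numerical conventions, each
of which some software chooses differently:

* **Zero differences** are discarded before ranking (the dominant
  convention in this ecosystem); Pratt's method (rank with zeros, then
  drop) is available via `zero_policy = "pratt"`.
* **Ties** receive midranks; the exact null distribution is computed by
  convolution over the doubled ranks, so ties are handled exactly.
* **Exact vs approximate**: exact enumeration of all $2^m$ sign
  assignments up to `exact_limit = 25` informative pairs (studies of
  this design have well under 25 pairs, so the exact path always runs);
  beyond that, a normal approximation with tie-exact variance
  $\sum r_i^2/4$ and continuity correction.
* **Two-sided p** doubles the smaller tail, capped at 1 — equivalent to
  the symmetric-tail definition because the null distribution of W is
  symmetric under flipping all signs.

Benjamini–Hochberg correction is applied within each (comparison,
rank) family separately, matching the convention of reporting species
and genus blocks as separate tables; joint correction across families
would be more conservative and is a one-line change for users who
prefer it. Group summaries are median (min; Q1; Q3; max) with type-7
(linear interpolation) quartiles, configurable because no quartile
convention is universal.

Taxa with zero abundance in every sample of both groups are skipped:
their p-value is 1 by construction and they would only dilute the
correction. Comparisons with fewer than two complete pairs are
reported as untestable rather than given a meaningless p-value.

## Dominant-genus summaries

Per sample type, genera are ranked by median cell-equivalent abundance
across that type's samples; genera with a zero median are ordered by
mean abundance (so a genus huge in one sample still surfaces), and
remaining ties break lexicographically for determinism. The top 25 are
reported by default. A per-sample mode is provided as well, because
"top genera for each sample" is ambiguous between the two readings.

## What the simulator emulates — and what it does not

`simulate_truth()` + `simulate_reads()` generate the archetypal
low-biomass spike-in study: 17 patients each contributing one pulp and
one dentin sample, plus 9 reagent controls. The defaults were chosen
once, as plausible for this kind of study, and are not fitted to any
dataset:

* **Contaminant background**: 12 taxa named after genera that dominate
  kit contamination (Burkholderiales prominent), with i.i.d. lognormal
  per-taxon loads (median loads ~8–230 cells, `sdlog` 0.7–0.9),
  identical in distribution across all three sample types — the
  defining signature of reagent contamination.
* **Sporadic oral taxa**: 6 oral species present only in pulp samples,
  each with prevalence 0.12–0.3 and lognormal load; the Treponema
  entry has a high load (median ~800 cells) at the lowest prevalence,
  emulating the occasional pulp sample genuinely dominated by an oral
  spirochete.
* **Calibrators**: exactly 500 cells each, except for per-sample events:
  with probability 0.05 one calibrator (chosen at random) drops out
  entirely, and with probability 0.05 the Allobacillus load is
  multiplied by 100 (distorted recovery manifests as inflated Ah/Ih
  ratios). Events are logged in the ground truth.
* **Reads**: per-sample depth is negative-binomial (mean 50,000,
  size 10 — typical MiSeq variability); reads are allocated
  multinomially with weights load × copy number, then split uniformly
  across each taxon's 2 zOTUs. A per-taxon negative-binomial read
  model is available for robustness checks.

All randomness flows from one root seed; fixtures are byte-for-byte
reproducible.

The simulator deliberately omits: sequence-level error (no FASTQ, no
chimeras), taxon-specific extraction bias, classifier error
(taxonomy is emitted noise-free), cross-sample index bleed, and
compositional correlation between contaminant loads. Passing the
recovery tests therefore shows the *pipeline arithmetic* is faithful
under the model's own assumptions — it does not certify accuracy on
real data, where extraction bias and classification error enter
upstream of anything this package can correct.

## Validation problem sizes

The package validates itself at sizes chosen to make the checks sharp
yet quick: signed-rank p-values are compared with full $2^m$
enumeration on 200 random instances with up to 12 pairs (ties and
zeros included); BH q-values with the closed-form step-up on 1000
random vectors; parameter recovery uses 20 simulated studies at
100,000 reads per sample with events disabled (observed: every
taxon–sample cell with truth ≥ 20 cells recovered within 25%,
requirement ≥ 90%); QC discrimination uses 20 studies at 10,000 reads
with 10% dropout and 10% ×100-distortion probability (observed: the
excluded set equals the event-flagged set exactly, in both
directions).

## Known limitations

* Cell-equivalent estimates inherit every upstream bias the
  calibrators do not share (lysis efficiency, primer mismatch,
  classifier errors); treat absolute values as order-of-magnitude
  anchors rather than counts.
* The ratio-bounds QC rule is a fixed-interval approximation to what
  is, in practice, an outlier judgement; samples with moderately
  distorted ratios inside the bounds are retained and quantified.
* With zero-inflated abundance vectors, the signed-rank test's
  discard-zeros convention can leave very few informative pairs;
  untestable flags and `n_used` make this visible.
* The screen's fold condition compares maxima, so a single aberrant
  background cell-equivalent (e.g. index bleed in one control) can
  veto a genuine hit; inspect `max_background_ab` before discarding.
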