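---
title: "Developmental tracing of aberrant CpG-island methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental tracing of aberrant CpG-island methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

CpG islands are CG-dense intervals, typically promoter-associated and
typically unmethylated in every normal tissue. During early development a
wave of global de novo methylation sweeps the genome while islands are
protected, and that bimodal "ground state" is then maintained through
somatic divisions. Embryonic stem (ES) cells grown in culture, however,
can acquire de novo methylation at islands that are never methylated
anywhere in the organism. The difficulty is defining *never*: no single
reference tissue can say whether an island is constitutively protected.

methtrace implements a developmental-tracing strategy: a panel of normal
tissues defines the set of islands unmethylated in *all* of them, and
excess methylation in ES-like test samples is then called against that
background set. Around the tracer it implements the two quantification
routes the approach relies on (mDIP microarray scoring and bisulfite
count aggregation) and the chromatin-density analyses that explain
*which* islands are targeted (H3K27me3 coupling, H3K4me3 protection).

# mDIP scoring: from two channels to an IMS

An mDIP (methylated-DNA immunoprecipitation) array compares an
antibody-bound fraction against input DNA on a CpG-island probe set. For
each probe we form the log ratio of the background-subtracted channels,

$$ \mathrm{lr}_i = \log_2 \frac{\mathrm{bound}_i}{s \cdot \mathrm{input}_i}, $$

where \(s\) is a linear normalization factor (by default the ratio of
channel medians over probes with both channels positive; probes with a
non-positive channel after background subtraction get a missing log
ratio). Probe signal depends strongly on melting temperature, so log
ratios are converted to Z-scores *within Tm strata*: probes are cut into
`tm_bins` equal-count Tm bins (default 20), and within each stratum

$$ z_i = \frac{\mathrm{lr}_i - \bar{\mathrm{lr}}}{\hat\sigma}, $$

with the population (ddof = 0) standard deviation. The Island
Methylation Score (IMS) is the arithmetic mean of the member probes'
Z-scores. An island is called methylated when IMS > 0.75 (strict), and
constitutively unmethylated islands are those with IMS < 0 (strict) in
every tissue sample.

Design choices worth stating explicitly:

* **Equal-count Tm bins.** Only "stratified by Tm" is inherent to the
  method; the functional form is open. Equal-count bins keep every
  stratum's mean/sd estimate equally stable across the Tm distribution,
  at the cost of wide outer bins in the Tm tails. Strata that fall below
  `min_stratum_size` (default 50) are merged into the Tm-adjacent
  neighbour with the nearer mean Tm (ties toward the lower stratum).
* **Population sd.** Deterministic and matches the classical Z
  definition; a zero-sd stratum yields all-zero Z-scores rather than
  NaNs.
* **Ratio orientation bound/input**, so higher IMS means more
  methylation and the 0.75 call threshold reads naturally.
* **Probe minimum.** No per-island probe minimum is inherent to mDIP
  scoring (the 3-CpG rule below is bisulfite-specific), so
  `min_probes_per_island` defaults to 1, but records built from fewer
  than 3 probes carry `low_probe_flag` so downstream users can filter.
* **IMS-to-percent calibration** is a plain OLS line through paired
  (IMS, percent) observations with predictions clamped to [0, 100]; it
  is an annotation aid, not part of the caller.

# Bisulfite aggregation

Per-CpG counts (RRBS-like) pass two filters in sequence: a CpG
contributes only with total depth >= `min_reads` (default 5; the filter
is on total reads, not methylated reads), and an island is reported only
when >= `min_cpgs` (default 3) CpGs survive. The island percent is the
*unweighted* mean of the surviving per-CpG percents — the depth filter
already guards precision, and equal CpG weighting keeps one deep CpG
from dominating an island. The two filters commute, and tightening
either can only shrink the reported island set; both properties are
tested.

Per-molecule amplicon matrices (rows = sequenced molecules, columns =
CpGs, entries methylated/unmethylated/missing) are summarized the same
way: per-CpG percent over non-missing calls, island percent as the mean
of per-CpG percents.

Thresholds on the percent scale mirror the IMS ones: constitutively
unmethylated means < 20% in all tissues, aberrant means > 60% in at
least one test sample. Both are configuration, not constants, because
different analyses in this tradition have used > 50% or > 25% cutoffs
for "methylated".

# Chromatin density and coupling

Per-island chromatin mark densities are normalized to the all-island
background, taken as the arithmetic mean of the raw scores
(`norm = raw / background`, so normalized densities average exactly 1).
"Polycomb target" means normalized H3K27me3 density strictly above 2 —
twice the all-island average, the only background the method defines. A
subtractive mode is available as configuration but the ratio form is the
default because it makes the > 2 gate scale-invariant.

Two profile constructions relate methylation to density:

* `profile_by_span()` — fixed-width windows on the density axis (default
  width 5, applied to whichever density scale the caller supplies, and
  recorded in output headers); each point is the mean methylation in the
  window.
* `profile_by_decile()` — ten equal-count bins by density rank, with
  ties broken by island id so the binning is order-independent; reports
  mean density and mean methylation per bin.

`protection_curve()` restricts to islands passing the H3K27me3 gate and
profiles methylation against H3K4me3 density, the construction that
exposes the concentration-dependent protective effect of H3K4me3.
`paired_density_change()` compares per-island densities between two
states (e.g. before/after differentiation) inside and outside a
highlighted island set.

# The tracer and its statistics

`constitutive_set()` keeps islands strictly below `constitutive_max` in
*every* tissue sample; an island missing a tissue value is excluded,
because "constitutively unmethylated" is a claim about all panel members
and missingness is not evidence. `aberrant_set()` then keeps background
islands strictly above `aberrant_min` in at least `min_test_samples_hit`
test samples, with missing test values counted as non-hits. Both
inequalities are strict, matching the threshold semantics IMS < 0 and
IMS > 0.75. The aberrant set is a subset of the background set by
construction, and raising `aberrant_min` can only shrink it.

Set overlap significance uses the upper-tail hypergeometric test,
computed in log space (`phyper(..., log.p = TRUE)`) because overlaps of
this kind can reach p-values far below the smallest positive double;
`log10_p` is reported alongside `p`. Group comparisons use the classic
two-tailed, non-paired, equal-variance t-test, with two degenerate cases
handled explicitly (zero pooled variance: p = 1 for equal means, p = 0
with a warning otherwise). Condition contrasts (e.g. serum vs 2i
culture) report the mean per-island difference over a target set with a
seeded bootstrap percentile interval (default 1,000 resamples), since a
single summary difference deserves an uncertainty statement.

`tissue_specific_set()` ("group B") captures the complementary pattern:
methylated in exactly one tissue and unmethylated in all others, using
the same percent-scale threshold pair (> 60 / < 20).

# What the synthetic generator emulates

`simulation_scenario()` pins down a fully seeded study: islands on a
synthetic chromosome; a configurable fraction (default 0.9) truly
unmethylated in all tissues; a planted subset of the constitutive pool
(default 30 of 2,000) gaining methylation in test samples; probe-level
Tm bias (default linear, 0.1 log2 units per degree C); lognormal input
channel intensities with `bound = input * 2^signal`; Poisson read depth
(default mean 30) with binomial methylated reads; and gamma-distributed
chromatin densities in which planted islands are drawn from a
higher-H3K27me3 distribution.

Truth lives on the IMS-like signal scale with unit gain; percent truth
is a logistic squash `100 * plogis(4 * (signal - 1))` of the same
signal, pinned to exactly 0 when the signal is 0, so one truth table
drives both assays. The default planted effect of 1.2 signal units was
chosen to sit clearly above the 0.75 call threshold after
normalization while remaining well below the fully methylated
compartment (2.0) — a "strong but not saturated" aberrant gain. Default
panel sizes (6 tissues, 3 test samples) reflect a modest normal-tissue
panel and a handful of ES lines.

When `k27_coupling > 0` the planted gain is rewritten as
`k27_coupling * k27_norm * max(0, 1 - k4_protection * k4_norm)` plus a
small noise term — methylation gain linearly proportional to prior
polycomb density and attenuated by H3K4me3 — which is the structure the
profile analyses are designed to recover.

Every generator consumes a named substream seeded deterministically from
the single scenario seed, so adding a generator never perturbs the
outputs of existing ones, and the array design (probe positions, Tm) is
fixed across samples while only assay noise differs — as on a real
array platform.

What the generator does *not* emulate: real genome sequence and CpG
spacing, fragment-size and antibody-efficiency effects beyond a single
enrichment scale, spatial array artifacts, dye swaps, incomplete
bisulfite conversion, and biological covariance between neighbouring
islands. Passing the planted-truth tests therefore demonstrates that the
pipeline's logic is correct and well-calibrated under its own model
assumptions, not that those assumptions exhaust real mDIP/RRBS noise.

# Numerical choices and problem sizes

* Coordinates are 0-based half-open (BED) everywhere; a CpG occupies
  2 bp, so a CpG at the last island position still maps inside. A probe
  overlapping two islands is assigned to the larger overlap, exact ties
  to the lexicographically smaller island id — deterministic and
  order-independent. (How boundary-spanning probes were originally
  assigned is not documented anywhere; this rule is this package's
  choice.)
* Equal-count bins (Tm strata, density deciles) differ in size by at
  most one; decile ties break by island id.
* Zero-sd strata, empty density windows, all-missing amplicon columns
  and zero-pooled-variance t-tests all have defined, tested behaviour.
* The test suite and acceptance script exercise the default scenario at
  2,000 islands with ~20,000 probes across 9 samples, 10,000-probe
  normalization panels, 1,000-island RRBS depth checks, and
  1,500-island coupling scenarios — sizes at which the planted effects
  are comfortably identified in seconds while still leaving room for
  the estimators' variance to matter.

# Known limitations

* The Tm normalization reconstructs a stratification whose original
  functional form is unpublished; results are insensitive to the bin
  count in our tests, but a regression-based Tm correction is a
  plausible alternative the config deliberately leaves room for.
* The tracer is a thresholding classifier; it does not model per-island
  measurement error, so its guarantees are about the planted-truth
  regime (effect size comfortably above threshold) rather than
  borderline islands.
* `compare_conditions()` seeds R's global RNG for its bootstrap.
* The genome-wide island counts reported in the literature for mouse
  and human arrays depend on the specific array designs and tissue
  panels; methtrace reproduces the *construction*, not those counts.

# A minimal run

```{r}
library(methtrace)

res <- run_demo("demo_run", simulation_scenario(seed = 17))
res$evaluation   # sensitivity / FDR against the planted truth
res$funnel       # islands -> probes -> background -> aberrant counts
```
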