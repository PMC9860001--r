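---
title: "Quantifying helical tomotherapy plan complexity from the sinogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying helical tomotherapy plan complexity from the sinogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htcomplexity)
```

## The model

A helical tomotherapy (HT) delivery is a fan beam rotating around a
continuously translating couch, shaped by a binary multileaf collimator of
L = 64 leaves. Each gantry rotation is discretized into 51 projections of
duration PT (the projection time, in ms); at projection *i* leaf *j* is
open for the fraction S~ij~ ∈ [0, 1] of PT. The matrix **S** (N
projections × L leaves) is the *sinogram*, and together with PT and a
handful of delivery parameters (field width, couch translation,
prescription) it determines everything this package computes. We store
fractional open times canonically and derive absolute ones as
LOT~ij~ = S~ij~ · PT, so every relative metric is invariant under a change
of PT by construction and never needs separate bookkeeping.

A leaf is *closed* at a projection when its FLOT is exactly zero
(the mask threshold ε defaults to 0 and is configurable). The binary mask
**O** (O~ij~ = 1 iff S~ij~ > ε) drives all geometry metrics, which are
therefore deliberately blind to open-time magnitudes; the open times drive
the distributional and modulation metrics. The metric registry mirrors
this split: Delivery (12 metrics), Absolute LOT (13), Relative LOT (11),
Geometry (13) and Modulation (16) — 65 metrics in total, 29 of which have
prior literature definitions and 36 of which are the newer generation
(threshold families, geometry decompositions, extended variability
indices).

## Conventions that matter

Several estimator-level choices are invisible in a formula but change
numbers; they are fixed as follows and tested as such.

* **Nonzero cells only.** All LOT/FLOT distribution statistics pool the
  nonzero cells of the plan. Structurally closed leaves already dominate
  the geometry family; including their zeros would make every
  distributional statistic a proxy for field size. (The closed-leaf
  fraction is available exactly as CLS.)
* **Strict inequalities.** CLNS~n~ is the fraction of LOTs *strictly*
  below n ms; CLNS~pt,n~ the fraction strictly above PT − n; CFNS
  likewise. A FLOT exactly at a threshold does not count.
* **Moment conventions.** Standard deviations use the sample (n − 1)
  denominator; skewness and kurtosis use population (biased) moments with
  kurtosis non-excess (a normal sample gives ≈ 3), matching the numerical
  environment HT complexity work has historically used. Zero-variance
  samples flag skewness/kurtosis as not available rather than returning
  0/0.
* **Mode of a continuous sample.** Midpoint of the fullest of 100
  equal-width bins over [min, max]; ties take the lowest bin. This is
  deterministic and scales exactly with PT (so moFLOT = moLOT/PT).
* **Empty projections.** The span bounds R~i~, L~i~ do not exist for a
  projection with no open leaf, so TA, centroid, nCC and lengthCC average
  over the projections with at least one open leaf. fDISC and CLS~in~ keep
  all N in the denominator, empty projections contributing zero terms.
  The discontinuity-restricted scores CLS~in,disc~ and CLS~in,area,disc~
  are 0 with an explicit flag when no projection splits.
* **Leaf positions.** For even L the leaf-position array is
  (−L/2, …, −1, +1, …, +L/2): antisymmetric with no zero, the center
  falling between the two central leaves. Centroid and MSA are reported in
  these number-of-leaves units; mirroring the sinogram negates both and
  fixes every other geometry score, which the suite asserts.
* **LnNS normalization.** The open-neighbor scores pool all open cells of
  the plan (not a per-projection average): pooled counting remains stable
  when some projections are nearly empty. Out-of-range neighbors count as
  closed, so L0NS + L1NS + L2NS = 1 whenever the plan has an open cell.
* **ELOTV denominator.** The per-leaf normalization is the leaf's maximum
  opening max~i~ S~ij~ — the only reading under which each leaf term, and
  hence the plan value, lies in [0, 1] and the complement identity
  LOTV = 1 − ELOTV₁ reduces to the classic per-leaf variability score.
  Never-opening leaves contribute 0 to ELOTV (equivalently 1 to LOTV).
* **nOC event model.** Openings are centered within their projection, so a
  partial opening (0 < S < 1) opens and closes inside its own projection:
  an isolated partial cell is one open event plus one close event.
  Adjacent open cells merge into a single continuous opening only when at
  least one side of the shared boundary is fully open (S = 1); a run of
  S = 1 cells with partial caps at its ends is thus a single open/close
  pair. Consequence: with no fully-open cell, events = 2 × (open cells),
  which gives the exact linear relation CLS = 1 − 0.5 · nOC; fully-open
  runs can only merge events, so in general CLS ≤ 1 − 0.5 · nOC. Both
  regimes are asserted exactly in the tests.
* **Modulation factor.** MF = max/mean over *nonzero* open times. With
  zeros included MF would diverge with field size rather than measure
  modulation. TT = N · PT excludes ramp-up and dead time; centers with a
  latency model should adjust before cross-center comparison. When stored
  metadata conflict with sinogram-derived values (a gantry period
  disagreeing with PT × 51 by more than 0.1% relative), the
  sinogram-derived value wins and a warning is raised.
* **Modulation index.** No single MI definition is canonical across
  platforms, so the package adopts a documented sigma-threshold scan
  (fraction of adjacent-projection FLOT changes exceeding f · sd(S),
  integrated over f ∈ (0, 2] in steps of 0.01; 0 for a constant sinogram)
  and isolates it behind a plug-in `method` argument so a different
  definition can be swapped in when cross-validating against another
  library. The adopted definition is recorded on the result.

## Plan I/O

The native exchange format is one JSON document per plan: a header with
the identifier, PT and delivery metadata, plus the row-major sinogram
serialized as shortest-round-trip decimal text. Write-then-read reproduces
the matrix bit for bit and two writes are byte-identical, which the
property tests exercise over random plans.

DICOM RT-Plan reading supports explicit and implicit VR little endian with
nested sequences. Vendors do not publicly document where the sinogram
lives, so the two dialect adapters encode explicit conventions — Precision:
L fractional open times per control point in the MLCX leaf/jaw positions;
RayStation: 2L bank positions whose per-leaf difference is the open time —
and are validated by round-trip and shape checks against generated
fixtures. Field width comes from the ASYMY jaws, couch translation from
the table-top longitudinal positions, the per-fraction dose from the
dose-reference and fraction-group sequences; the projection time, which
has no standard tag, is read from a documented private block. Missing
metadata are flagged `NA` and every dependent metric reports
not-available — never a silent zero. Sinogram values above 1 by at most
1e-9 are clipped with a warning; anything worse is an integrity error
naming the cell.

## What the synthetic generator emulates

`ht_profile()`/`generate_plan()` build plans with a contiguous open span
per projection (width = open_fraction × L, centered at L/2 +
asymmetry_shift), Poisson-distributed closed gaps strictly inside the span
(never at its ends, so the span bounds stay put), and nonzero FLOTs drawn
from one of four shapes. Two shapes emulate the FLOT histogram families
that separate delivery-efficiency classes in clinical HT cohorts: a
*bimodal* distribution (modes near 0.5 and near the maximum opening,
characteristic of heavily time-modulated, less efficient plans) and a
*flat with end peak* distribution (efficient plans that modulate
geometrically and run many leaves near fully open). No quantitative
parameters for these histograms are published, so the mixture weights
(50/50 for the bimodal shape; 45% end peak for the flat shape) and mode
locations (0.50 ± 0.05, 0.93 ± 0.03, 0.97 ± 0.015) are package choices
fixed once — they are qualitative emulations whose job is to give the two
families cleanly separated CFNS₇₅ values, and the cohort tests verify the
separation rather than any clinical histogram.

What the generator does *not* emulate: optimizer output (no dose realism,
no correlation between neighboring projections beyond the fixed span), leaf
latency, or metadata variety (all synthetic plans share FW = 2.5 cm,
PT = 200 ms, a 2 Gy fraction). Passing cohort tests therefore demonstrate
that the statistical machinery recovers structure that is present by
construction; they do not validate the metrics against measured QA
outcomes.

Reproducibility: a plan is a pure function of its profile (including the
seed), and cohorts derive plan *k*'s seed as master_seed + k, so plan k is
identical no matter how many plans are requested. The generator
saves/restores the caller's RNG state.

## Cohort analysis

Spearman's rank correlation (average ranks for ties) is used throughout,
with two-sided p-values from the large-sample t approximation — adequate
for cohorts of tens of plans; below n ≈ 10 the p-values are approximate
and the map should be read through its point estimates. Magnitudes are
graded with the conventional five classes (boundaries 0.2/0.4/0.6/0.8) at
a default significance level of 0.05, and the implementation is checked
against an explicit rank-then-Pearson oracle.

The PSQA screen keeps metrics significantly correlated with the passing
rate, then walks them in decreasing |ρ|, dropping any metric strongly
correlated (|ρ| ≥ 0.6, the lower edge of "strong"; configurable — the
alternative reading "very strong only" corresponds to 0.8) with an
already-kept one, so of a redundant pair the weaker endpoint correlate is
removed. Ties in |ρ| break by metric name for determinism. An empty
selection is a valid outcome, and the suite checks the per-metric
false-keep rate under null endpoints sits near the nominal 5%.

Efficiency stratification follows the CFNS₇₅ quartile rule: plans strictly
below the 25th percentile (linear-interpolation quantiles) are the most
efficient, strictly above the 75th the least; plans exactly at a cutoff
belong to neither group, and a degenerate quartile (e.g. a constant
cohort) is an error rather than an arbitrary split. Group comparisons use
Student's equal-variance t-test by default (Welch via `var_equal =
FALSE`), flagged at 0.05 and 0.01. The per-group FLOT histograms normalize
each plan's histogram to unit sum before pooling, and the band around the
per-bin mean is a 95% Gaussian confidence interval of that mean.

## Problem sizes and numerical checks

The test suite works at deliberately modest sizes — plans of 2–30
projections and 8–64 leaves for property loops (hundreds of random plans
per identity), cohorts of 30–50 plans for recovery tests, 1000 replicate
cohorts for the type-I check — chosen so the full suite runs in well under
a minute while still exercising every degenerate path (all-closed plans,
empty projections, single-projection plans, constant distributions,
exact-1 cells). Exact identities (LOTV + ELOTV₁ = 1, PSTV = EPSTV₁,₁,
CLS = 1 − 0.5 · nOC without full openings, the FLOT = LOT/PT family) are
asserted at machine precision; stochastic recovery checks use the margins
stated in the tests.

## Known limitations

* The DICOM dialect conventions are self-defined until validated against
  vendor sample files; the native JSON format is the interchange substrate
  of record.
* The target length TL is metadata pass-through: the package does not
  attempt to reconstruct target extent from couch travel and field width.
* The MI definition is a package choice among several published ones;
  comparisons across libraries must align definitions first (hence the
  plug-in point).
* Plan-level metrics only: per-leaf or per-projection breakdowns beyond
  the documented intermediates (`projection_geometry`, `lps_metrics`) are
  out of scope, as are gamma-index computation and dose calculation — PSQA
  passing rates enter only as inputs.
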