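---
title: "skinquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{skinquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

skinquant quantifies immunofluorescent skin biopsy sections from
segmentation masks. This vignette records the conventions the package
commits to, why they were chosen, and what its synthetic-data tests do and
do not demonstrate. It is the reference for every numerical decision that a
reader of the results needs to know.

## Inputs and the pixel model

The unit of analysis is a 2D section: multi-channel fluorescence images
(12/16-bit, one channel per marker) plus binary structure masks for
epidermis, dermis, nerve fibers and blood vessels, all on a shared raster
with an isotropic pixel size in micrometers (default 0.61 µm/px, a common
widefield configuration at 20×). Sections are treated as 2D projections;
no 3D morphology is attempted. Masks come from an upstream segmentation
step that this package deliberately does not provide — any tool that emits
per-class label images can feed it. Epidermis and dermis masks must be
disjoint; because real segmentation output can overlap, the documented
pre-step `resolve_mask_overlap()` reassigns overlap pixels to a chosen
class rather than resolving silently.

## Distance geometry

All physical-distance operations reduce to one primitive, `expand_mask()`:
the Euclidean closed ball on pixel centers. A pixel belongs to the
expansion by distance $d$ iff its center lies within $d$ of some
foreground pixel center (`distance <= d`, with a 1e-9 px slack so that
lattice-exact radii such as 5 px retain their boundary pixels). The
implementation is an exact Euclidean distance transform; the test suite
holds it equal, pixel for pixel, to a brute-force all-pairs oracle on
random masks. Expansion is clipped at the image border without
compensation — acquisitions are assumed to frame the full region of
interest.

Two derived regions use this primitive:

* **sub-epidermis** — `expand_mask(epidermis, 50 µm) ∩ dermis`. The 50 µm
  depth is the conventional band in which dermal nerve bundles are
  quantified; it is a `run_config()` parameter.
* **nerve proximity region** — `expand_mask(nerve, 5 µm)`, fibers
  included. Vessels intersecting it count as interacting.

## Basement membrane and IENFD

The basement membrane is the epidermis–dermis interface only: epidermal
boundary pixels with an 8-adjacent dermal neighbour. The free epidermal
surface never contributes length or crossings. The interface is extracted
as ordered polylines by walking each epidermis component's closed boundary
contour and keeping maximal runs of interface pixels. Arc length is the sum
of consecutive center-to-center distances plus one pixel of end extent per
open polyline, so a straight interface of $w$ pixels measures exactly
$w \times$ pixel size. Length is translation- and 90°-rotation-invariant
and scales linearly with pixel size. On smoothly undulating boundaries the
digital polyline overestimates the true arc length by a few percent
(staircase effect); the straight-interface case is exact and is what the
closed-loop length check asserts at 2%.

Crossing detection rasterizes the membrane as a 1-px band and counts
8-connected components of (nerve ∩ band). Decisions, made once:

* one component = one crossing, with **no minimum-size filter** — the
  manual convention counts every immunoreactive fiber crossing the
  membrane, and no size threshold is published;
* a fiber touching the band at two separated loci counts twice. A 2D mask
  carries no fiber identity, so merging is impossible without tracing;
  this is a known bias of mask-based counting relative to manual counts
  and one reason automated and manual counts correlate imperfectly;
* 8-connectivity on the band means diagonal fiber paths cannot tunnel
  through uncounted.

`IENFD = crossings / membrane length`, in fibers/mm, per marker.

## Fluorescence quantification

MFI is the arithmetic mean of channel intensities over (nerve ∩ region).
By default one shared nerve mask (the pan-neuronal PGP9.5-based mask) is
used for every marker of an image, so that marker MFIs are comparable over
the same pixel support; this is configurable. No background subtraction or
flat-field correction is applied: inputs are treated as the
vendor-processed projections they usually are, and the normalized MFI
(target/reference ratio, invariant to common intensity scaling) is the
analysis-level control for staining and imaging variability.

An empty (nerve ∩ region) yields a **missing** MFI, never zero — absence
of fibers is not zero intensity — and missingness propagates through
normalization; downstream statistics drop missing values pairwise.
Area fractions (e.g. CGRP⁺/PGP9.5⁺) are reported in [0, 1]; a ratio above
1 indicates inconsistent masks and is flagged, not clipped.

Per subject, metrics from the (typically two) images are aggregated as the
arithmetic mean with missing images dropped; the aggregation rule is a
config option (`mean`/`median`).

## Vessel–nerve interaction

Vessel quantities are restricted to the dermis (epidermal vessel pixels
are treated as segmentation spillover and excluded). The interaction area
is the dermal vessel area inside the 5 µm proximity region, reported in
µm² per image. Absolute comparability to plots published without units is
not claimed.

## Clinical scores

QST z-scores follow the DFNS convention:
$z = \mathrm{sign} \cdot (\mathrm{domain}(x) - \mu)/\sigma$ against
published reference norms, with CDT, WDT, TSL, PPT, MPT, MPS, WUR, MDT and
VDT transformed to log₁₀ before scoring and CPT/HPT scored linearly. The
sign multiplier is part of the norms table and orients every parameter so
that positive z means gain of sensory function. Published normative tables
are **not bundled** (transcription and licensing risk); norms ship as a
user-editable YAML schema with free-form age/sex stratum keys, and a
clearly labelled synthetic norms table with the same schema is included
for tests. Reference-interval classification treats both tails as abnormal
and boundary values as normal (closed interval — a convention this package
fixes, as none is published); missing values are excluded from
denominators, never counted as normal. NRS pain ratings band as none (0),
mild (1–3), moderate (4–6), severe (≥7); medication-adjusted ratings are
accepted as a flag-only passthrough.

## Relative expression

`fold_change()` implements the standard Livak 2^−ΔΔCT: triplicate Cts are
averaged arithmetically (replicate SD > 0.5 cycles flags the sample, a
common lab QC level; the sample is retained), ΔCT = target − reference
(RPL13A by default), and the calibrator baseline is the arithmetic mean of
calibrator ΔCTs, which forces the calibrator-group geometric mean fold to
1 exactly. Efficiency-corrected quantification is out of scope. Ct values
outside (0, 40] are dropped with a warning; samples without a usable
reference are excluded and reported.

## Statistics layer

* Two-group comparisons route on Shapiro–Wilk at α = 0.05 per sample:
  both normal → t-test, else Mann–Whitney. The Mann–Whitney p is exact by
  enumeration when the combined n ≤ 20 with no ties, otherwise the midrank
  normal approximation with tie and continuity correction; the two agree
  within 0.02 for n ≥ 15 per group, and the routed procedure's type-I
  error on null normal data is 5% ± 1% (both are asserted in tests).
* 2×2 tables use the Yates-corrected χ² (with the continuity correction
  floored at zero) when all expected counts are ≥ 5, else Fisher's exact
  test by full hypergeometric enumeration. This routing reproduces the one
  recoverable published worked example (painful 16/3 vs painless 15/15:
  χ² = 4.48, p = 0.034, OR = 5.33).
* Odds-ratio intervals are Woolf (log-normal); zero cells get the
  Haldane–Anscombe +0.5 correction and a flag. On the worked example
  Woolf gives ≈ 1.28–22.2 where the source reports 1.38–19.45; the
  source's interval method is not identifiable from what is printed, so
  the package documents the discrepancy rather than matching it.
* Correlations are Spearman with midranks.
* Descriptives: mean/SD and median/IQR with type-7 quantiles
  (IQR = Q3 − Q1).
* No multiple-testing correction is applied by default, matching the
  descriptive reporting style the pipeline mirrors; `p.adjust` can be
  applied to the tidy report by the user.

All tests are two-tailed at α = 0.05.

## The synthetic generator

`generate_section()` builds a section from a seed, deterministically: an
epidermal band under a sinusoidally undulating basement membrane
(amplitude 12 µm, wavelength 180 µm by default; amplitude 0 gives the
analytically exact straight case), crossing fibers as smoothed vertical
random walks rasterized at 3 px width, dermal-only fibers, elliptical
dermal vessels placed at programmed center-to-fiber distances (within
1 px, verified by iterative correction), and per-channel intensities:
fiber pixels at `fiber_mean` (PGP9.5 2000, TrkA 400, CGRP 1800 on a
peptidergic subset, GAP43 800 on a subset) with additive zero-mean
Gaussian noise (σ = 50), backgrounds at 120–250, DAPI as elevated
epidermal background, truncated at 0 and quantized to 16 bits. No shot
noise or optical blur is modelled — the metrics under test are mask
statistics and means, which do not depend on those features.

Two properties make the generator a test instrument rather than a demo:

* **planted = countable.** Each crossing fiber is re-drawn until its
  rasterization touches the membrane band in exactly one component,
  separated from its neighbours (≥ 3 px at the interface, enforced via
  spacing plus verification). The planted crossing number is therefore the
  number the counting algorithm *should* return, exactly.
* **complete ground truth.** Membrane length is the analytic arc length of
  the generating curve; the true interaction area is computed by
  brute-force pixel distances, independently of the pipeline's distance
  transform.

`generate_cohort()` plants group effects on top: IENFD multiplier 0.5 and
TrkA intensity multiplier 5 in patients, vessel-area multiplier 1.4, a
3× interaction effect in the painless subgroup only (implemented as 6 vs 2
near vessels of fixed radius at 4 µm from fibers; the patient vessel-area
increase is carried by the far vessels so it cannot leak into the
interaction contrast), NGF folds 0.65/0.92 (painless/painful) and TrkA RNA
fold 0.66 versus control, sensory-loss z-shifts of −1.5 on detection
thresholds, and sural SNAP abnormality rates 0.84/0.50/0.02
(painful/painless/control). Inter-subject variability is lognormal with
CV 0.15. Each subject's two images carry floor and ceiling of the
subject's continuous crossing rate: subject means then track the rate with
at most half a fiber of rounding, instead of adding Poisson noise that
would dominate recovery at realistic small counts. Because counts are
integers, planted-rate recovery is evaluated on group *means* for IENFD
(unbiased under this planting) and on group medians for the continuous
TrkA intensity ratio.

What passing these tests shows: the measurement chain (geometry, counting,
intensity averaging, statistics) recovers known effects of realistic size
at cohort scale, with calibrated false-positive behaviour. What it does
not show: robustness to segmentation errors, optical artifacts, staining
batch effects, or any property of real patient tissue — the generator
emulates the statistical structure the analysis assumes, not histology.

## Problem sizes and determinism

Default sections are 1024×1024 px (0.62 mm of membrane at 0.61 µm/px).
The test and acceptance runs use scaled-down sections (256–320 px wide,
n = 20 subjects/group, two images each; 10,000 simulated null pairs for
the type-I calibration) — sizes chosen so the full suite completes in
minutes while keeping every estimate's Monte-Carlo error well inside the
asserted tolerances. Every stochastic component (sections, cohorts,
simulations) is seed-driven and bit-reproducible; generators save and
restore the caller's RNG state.

## Known limitations

* Membrane length on strongly undulating interfaces carries a few percent
  of digital-curve overestimate; comparisons across sections with similar
  geometry are unaffected, absolute lengths slightly inflated.
* Multi-contact fibers inflate crossing counts (no fiber identity in 2D
  masks).
* The painless subgroup's extra near vessels also raise its total vessel
  area in synthetic cohorts; the emulated "vascular area increased in
  patients" pattern holds, but subgroup equality of vessel area is not
  emulated precisely.
* MFI carries no background or flat-field correction by design; only
  normalized ratios should be compared across staining batches.
* The Woolf odds-ratio interval will not reproduce intervals computed by
  other (unidentified) methods on the same counts.
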