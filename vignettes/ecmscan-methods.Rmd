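---
title: "Quantifying ECM remodeling on myoscaffolds: methods and design notes"
author: "ecmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ECM remodeling on myoscaffolds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmscan)
```

# Scope

Decellularized skeletal-muscle sections ("myoscaffolds") retain the native
extracellular-matrix architecture of muscle — the laminin-rich basement
membrane (BM) ensheathing each fiber and the fibrillar interstitial matrix
(IM) between fibers — and are used as culture substrates to ask how matrix
composition, crosslinking and stiffness govern muscle progenitor behavior.
The measurements such experiments produce are heterogeneous: fluorescence
line scans across the endomysium, peak-intensity surveys before and after
cell culture, live-imaging cell tracks, nuclei/myotube fields, and AFM
force curves. `ecmscan` implements the quantification for each of these,
plus seeded generators that synthesize every input class with exact ground
truth, so the whole pipeline is testable end to end without microscope
access.

# Line-scan segmentation

A line scan perpendicular to the endomysium crosses basement membrane —
interstitium — basement membrane, so the BM marker (red channel, laminin
α2) shows two peaks flanking a valley. The algorithm:

1. **Basal scaling** (`scaleToBasal`). Each channel's background is
   subtracted and negatives are clipped. Subtraction, not division, keeps
   the downstream areas in intensity·µm. The default background estimate is
   an iteratively sigma-clipped median (discard samples above
   median + 2·MAD until convergence): a fixed low percentile needs an
   assumption about how much of the scan is background, and the right
   answer differs between the red channel (background-dominated) and the
   green channel (signal can cover most of the span). Because the
   subsequent Gaussian fits carry no offset term, a background error of
   b units leaves a pedestal of b under the peaks and inflates the fitted
   widths; the clipped median keeps that pedestal near zero for both
   channel geometries. A numeric `basalPercentile` is accepted for users
   who want the plain percentile convention.
2. **Zero-phase smoothing** (`smoothProfile`). An order-3 low-pass
   Butterworth filter at 0.2 × Nyquist applied forward and backward
   (`signal::filtfilt`), so peaks do not shift: the filter design is
   configurable and recorded in the result's parameter list.
3. **Two-peak detection** (`findTwoPeaks`). The two highest local maxima of
   the smoothed red channel separated by at least `minSeparation` (default
   4 × the sample spacing), ties broken leftmost. Maxima below 2% of the
   trace maximum are ignored as filter ripple. Scans without two
   qualifying maxima lack a distinct basement membrane and error out —
   callers treat that as a structured exclusion, never a silent drop.
4. **Peak modeling** (`fitPeak`). Each peak window (± 3.5 µm) is fitted
   with both a single Gaussian and a two-component Gaussian
   (`minpack.lm::nlsLM`). The double model is kept only when it improves
   BIC by more than 2. Because zero-phase filtering leaves roughly a
   `cutoffFraction` share of residuals independent, BIC is evaluated at
   that effective sample size; with the raw count the double model wins
   spuriously on smoothed noise. For a selected double model the
   *effective* mean and SD are the mixture moments (component weights
   ∝ amplitude × SD); for equal, symmetric components at µ ± d this gives
   the exact `sqrt(σ² + d²)`.
5. **Segment points** (`segmentPoints`). `s1..s4` are effective mean ±
   2 × effective SD per peak (95.45% of a Gaussian's mass). BM regions are
   `[s1,s2]` and `[s3,s4]`; IM is `[s2,s3]`. Overlapping windows collapse
   `s2 = s3` to the overlap midpoint and flag the scan `noDistinctIM`, so
   fibrotic scans with expanded BM still yield BM abundance.
6. **Abundance** (`regionAbundance`). Trapezoidal area of the scaled,
   smoothed channel per region on the native grid (segment points are
   interpolated linearly, so the three regions partition the `[s1,s4]`
   integral exactly). The filter has unit DC gain, so areas survive
   smoothing; its only systematic effect is a slight widening of the
   fitted windows that shaves a few percent off a sharply-edged IM
   plateau. The green channel is integrated on the *red-derived* segment
   points, and `stoichiometry` is the green/red ratio of total BM
   abundance — the package's documented reading of "relative
   stoichiometry"; an overlap coefficient was considered and rejected
   because it discards amplitude information.

```{r linescan}
p <- simulateLineScan(seed = 7)
res <- analyzeLineScan(p)
res
```

# Remodeling index

The remodeling index compares peak ECM fluorescence at matched structures
in a control scaffold (no cells) and a cell-seeded scaffold. Control and
treated sections are different physical samples, so locations cannot be
paired; each treated location is referenced to the control mean:
`RI_i = mean(control) / treated_i`, summarized as mean ± SD. RI ≈ 1 means
no remodeling; larger values mean degradation. The inverse orientation is
available behind a flag for users who prefer a post/pre convention.
`percentReduction` covers time-course statements (intensity at t vs t0).

The generator draws the *per-location remodeling ratio* from a lognormal
with mean equal to the requested factor and the requested coefficient of
variation, and sets treated intensity = control mean / ratio. Putting the
noise on the ratio rather than on the treated intensity makes the stored
ratios average exactly to the simulated factor, which is the quantity the
RI estimator targets; with mean-one noise on the intensities instead, the
reciprocal would bias the mean RI upward by `exp(s²)` (≈ 4% at cv = 0.2).
The lognormal choice itself is a stand-in: no distributional description
of endomysial intensity variability is available for real tissue.

# Cell behavior

Tracks are sampled at a fixed 10-minute interval (TI). `intervalSpeeds`
reports one speed per observed consecutive-frame pair (µm/TI); gaps yield
no entry. `meanSpeed` averages per cell inside a half-open time window and
then across cells (mean ± SD). `totalDisplacement` is the cumulative path
length over the first ⌊duration/TI⌋ intervals (default 900 min = exactly
90 intervals); net start-to-end displacement is reported as a secondary
column because the two are routinely conflated — path length is the
headline since speeds are defined per interval and summed behavior over
the window is what the assay observes. Only complete tracks enter the
displacement table; incomplete ones are returned as structured exclusions.

The track generator is a persistent random walk: per-interval step lengths
`Normal(speedMean, speedSd)` truncated at zero, heading increments
`Normal(0, (1 − persistence)·π)`. It reproduces the fixed-interval
sampling, dropout and speed scale of live imaging; it does not model
confinement, collisions, or the matrix-guided anisotropy of real cells, so
passing tests demonstrate metric correctness, not biological realism.

`fusionEfficiency` classifies each α-actinin⁺ region by nucleus count
(≥ 3: myotube; 1–2: myocyte) and reports the percentage of *all* nuclei
residing in myotubes; myocyte nuclei count in the denominator only.
Membership is centroid-inside-ellipse with boundary points inside. The
field generator places non-overlapping axis-aligned ellipses (bounded
retries, then an error), which keeps the true index exactly computable;
`rasterizeFusionField` emits a label mask for image-based workflows.
`adhesionPercent` is the plain post/pre percentage with a flag when more
cells are counted after dissociation than before.

# AFM mechanics

The approach segment is modeled with the conical Hertz–Sneddon relation
`F = (2/π)·tan(α)·E/(1 − ν²)·δ²`, with indentation δ = contact − separation.
Defaults: half-angle 35° (a pyramidal probe modeled as its equivalent
cone; the four-sided-pyramid front factor is selectable since the two
differ only by a constant), ν = 0.5 (incompressible soft matter), fit
range bounded by the 3 nN trigger force — which the recorded segment
already respects, so no re-filtering on the noisy measured force is done
(censoring on measured F would drop the highest-leverage points
asymmetrically and bias E).

`detectContactPoint` is threshold-crossing: a least-squares baseline over
the far-field 30% of the approach, then the first sample whose corrected
force exceeds 5 noise SDs for 5 consecutive samples. That detector is
systematically late on noisy curves, and a separately-fitted baseline
extrapolates its uncertainty across the contact region; `fitHertzSneddon`
therefore defaults to a joint nonlinear fit of baseline intercept, slope,
contact point and E over the whole segment, which reaches the estimator's
information bound in simulation. Holding the detected contact fixed
(`refineContact = FALSE`) gives the closed-form linear solution instead.

`ruptureForce` is the magnitude of the deepest negative excursion of the
baseline-corrected retraction. The retraction baseline is refitted with
one-sided outlier rejection (the adhesion dip can leak into the far field
on shallow curves), and the extremum is taken on a moving average much
narrower than any physical dip: the raw minimum of thousands of noisy
samples carries an extreme-value bias of 2–3 noise SDs, while the window
attenuates a generator-default dip by under 0.5%.

The curve generator samples 2000 points per segment — the order of a 2 kHz
capture at the 2 µm/s approach speed — with additive Gaussian force noise,
an optional linear baseline tilt, and a Gaussian-shaped adhesion dip just
past contact on retraction. It does not model cantilever dynamics,
viscoelastic creep, or bottom-effect corrections for thin samples.

```{r afm}
fc <- simulateForceCurve(youngModulus = 1e4, seed = 1)
analyzeForceCurve(fc)
```

# Pipeline, provenance and problem sizes

`runPipeline` drives every stage from a single config (R list or YAML):
all randomness derives from `config$seed` (generators take explicit seeds
and restore global RNG state), every output embeds the parameter set, the
log records per-stage counts and every exclusion with a reason, and a
rerun with the same config is byte-identical. Defaults per run: 20 line
scans, 20 remodeling locations, 20 cells × 91 frames, one fusion field,
20 force curves — sizes chosen so a full run takes seconds while leaving
every estimator in its asymptotic-enough regime; the test suite uses 200
replicates where recovery rates are asserted.

# Known limitations

* Basal scaling assumes the background is the densest intensity mode; a
  scan that is nearly all signal would be mis-scaled.
* The ±2σ windows inherit the smoothing filter's slight peak widening; IM
  abundances of sharply-edged distributions are the most sensitive
  quantity, with a few percent systematic shave at the default cutoff.
* Fitted effective SDs carry an irreducible ~2% estimation error at
  realistic noise, which propagates to region boundaries; joint
  sub-percent recovery of every abundance on noisy scans is not
  achievable by any estimator under these conditions.
* Outlier removal (e.g. ROUT) applied in some statistics packages is out
  of scope; summaries are plain mean ± SD.
* No tracking, no 2D image segmentation, no cantilever calibration: the
  package consumes already-extracted profiles, tracks and curves.
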