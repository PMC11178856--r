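---
title: "Models and numerical choices behind nanomem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices behind nanomem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomem)
```

`nanomem` analyzes three kinds of measurements made with solvatochromic
membrane probes: two-detector emission-ratio images, fluorescence-lifetime
(FLIM) stacks, and single-molecule tracks. This vignette explains the models
each stage assumes, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical decisions
that were genuinely open.

## Ratiometric mapping

Solvatochromic dyes red-shift their emission in polar (loosely packed)
membranes. With two detection bands, the per-pixel ratio det1/det2 (far-red
over red) is a monotone proxy for that shift, so lower ratios indicate
tighter lipid packing. The pipeline is: Gaussian-smooth each detector image
(`sigma`, default 1.5 px), threshold both smoothed images at a strictly
positive `background`, and form the ratio on pixels passing both thresholds.

Choices worth knowing:

* **Smooth, then threshold.** Thresholding the smoothed images (not the raw
  ones) keeps the valid mask consistent with the values actually ratioed,
  and a positive background guarantees no division by zero.
* **Reflective filter boundaries.** Circular or zero-padded convolution
  darkens image borders, which would bias ratios of border-touching
  structures such as the plasma membrane; the separable kernel (truncated at
  4 sigma) therefore mirrors the image at its edges.
* **Background is an explicit parameter.** In practice background levels are
  picked per image; for unattended runs the pipeline stage defaults to the
  60th percentile of nonzero pixels per detector, trading a little
  sensitivity for reproducibility.
* **Normalization.** "Normalized ratio" is not a standardized quantity; the
  default divides by the global median of valid pixels, with a
  reference-region mode when one compartment should define 1.0. The constant
  is stored so the operation is auditable and idempotent.
* **Outlier removal** keeps values within k = 3 scaled median absolute
  deviations (consistency constant 1.4826, as in `stats::mad` and common
  MATLAB practice). When the MAD is zero, only values equal to the median
  survive.

Lipid droplets are separated from other vesicles by their green emission:
connected components of the vesicle mask whose mean green intensity exceeds
a threshold are relabeled. The threshold has no canonical value and is a
parameter; droplet counts are non-increasing in it, which the tests verify.

Vesicle sizes are estimated by fitting an axis-aligned elliptical 2D
Gaussian plus offset in a window of 7 nominal PSF sigmas around each local
maximum, brighter peaks claiming overlapping windows first. FWHM is
2·sqrt(2·ln 2)·sigma per axis; fits that fail to converge or exceed the
window are discarded rather than reported.

## Lifetime fitting

Each FLIM pixel holds a photon-arrival histogram on bins of width 0.21 ns
spanning 19.9 ns (bin centres at offset + (k − 1/2)·width; the acquisition
offset of a few ns stands in for pulse/IRF avoidance — no deconvolution is
attempted). The single-exponential model is I(t) = I0·exp(−t/τ).

Two estimators:

* **Log-linearized:** OLS on ln I versus t, τ = −1/slope. This is fast and
  exact on noiseless data for any τ > 0 (verified to machine precision), but
  it must drop bins with non-positive counts — exactly the bins uniform
  noise corrupts most — and the log transform turns symmetric count noise
  into asymmetric log noise. The result is a strong upward bias at low I0.
  Ordinary (unweighted) least squares is used deliberately: the linearized
  route exists for speed, and weighting would reintroduce the cost it
  avoids.
* **Nonlinear:** least squares on the raw counts, keeping negative bins.
  The amplitude enters linearly, so it is profiled out in closed form
  (variable projection), leaving a 1-D problem in τ solved by a log-spaced
  grid search (80 points) plus secant refinement of dSSR/dτ = 0, vectorized
  over pixels; the linearized estimate, where finite, joins the candidate
  set, which also makes the noiseless case exact. Pixels whose best
  amplitude is non-positive, with fewer than 3 usable bins, or with a
  non-decaying slope are flagged rather than given meaningless lifetimes.

`noise_bias_study()` quantifies both estimators on the simulation grid the
package ships as defaults: I0 from 20 to 300 in steps of 40 (8 patches of
16×16 pixels), τ = 4 ns, uniform integer noise of amplitude 0–40. Statistics
are pooled over successfully fitted pixels; the per-cell accumulators work
on deviations from the true τ so that a zero-noise column reports exactly
zero spread instead of floating-point cancellation dust.

The uniform noise model reads "integer noise around zero of amplitude A" as
the symmetric integer uniform on [−A, A]; the original analysis used an
integer random generator whose re-centring convention is not recorded, so
the symmetric reading is documented as a choice. Counts may go negative and
the generator keeps them — deciding what to do with impossible counts is the
fitter's job, and the two fitters decide differently (that asymmetry is the
point of the study). The deterministic part of the simulated decay is left
continuous-valued; only the noise term is discrete. A Poisson noise model is
also provided for shot-noise-limited scenarios.

## Noise-corrected PCA

Exponentials are not orthogonal, so multi-component decay fitting is
ill-posed; NC-PCA sidesteps the model-order question. Each time-bin image is
divided by the square root of its mean intensity (approximate Poisson
variance stabilization; factors are recorded, and the operation is
intentionally not idempotent), then every foreground pixel's corrected decay
is an observation in bin space and the pooled second-moment matrix is
eigen-decomposed.

The decomposition is deliberately **uncentered**. The first eigenvector then
points along the intensity-weighted mean decay — score 1 resembles an
intensity image and is expected to be similar between biological groups —
while the second captures the leading decay-shape contrast, which is where
lifetime differences surface. Mean-centring first would move exactly that
between-group contrast into component 1 and make "score 2" a noise
component; both projections are nevertheless available (`scores`,
`scores_centered`). Sum of eigenvalues equals the mean squared norm of the
pooled corrected decays (trace identity), which the tests check.

Other conventions: eigenvector signs are fixed by making each vector's
largest-magnitude element positive (PCA signs are otherwise arbitrary and
group comparisons need a convention); four components are retained by
default (higher ones sit at the noise level); the covariance pools only
foreground pixels (total counts above a threshold) so background does not
swamp component 1; and when several stacks are analyzed together one basis
is computed on the pooled pixels — per-stack bases are available by calling
`ncpca()` per stack, but score values are then not comparable across stacks,
and `compare_scores()` refuses mismatched bases.

## Tracking analytics

Tracks are taken as given by `track_id` — no gap closing or re-linking,
since burst-mode single-molecule tracking emits contiguous bursts and track
ends are dominated by unbinding/bleaching. Durations are last minus first
time. Rolling speed uses a centred 35 ms window over the accumulated path
length divided by the actual time span; edge positions with partial windows
are dropped because a truncated window systematically underestimates speed.
Units are fixed at nm and ms internally (1 nm/ms = 1 µm/s).

Photon counts per localization are summarized by closed-form log-normal
maximum likelihood. Localization precision uses L/(2·sqrt(2·N)) for probing
range L and N photons, valid for L well below fwhm/sqrt(ln 2) (a warning
fires otherwise); since the instrument's L is acquisition-dependent it is
always a user input. Precision histograms are summarized by Gumbel or GEV
maximum likelihood fitted directly by `optim` on the analytic
log-likelihood.

The MSD is time-averaged with overlapping pairs, pooled across tracks with
per-lag pair weighting (short tracks contribute what they can), after
resampling onto a regular grid by averaging localizations per bin —
burst-mode localizations are irregular in time, so some binning is always
implied. Brownian fits use least squares through the origin on
MSD = 4Dτ; anomalous fits use the log-log linearization of MSD = 4Dτ^α
over, by default, the first quarter of available lags (minimum 3), with
non-positive MSD values excluded and counted.

**Why shortening trajectories looks superdiffusive.** Averaging positions
within bins of width Δ depresses the MSD by the classic motion-blur term
(MSD(kΔ) ≈ 4DΔ(k − 1/3) for Brownian motion), which is relatively largest
at the first lags. A long trajectory's fit range spans many bins, so the
fitted α stays near 1; clipping the same data to a few bins puts the whole
fit range where the depression is strongest, and the log-log slope rises
above 1. `truncation_study()` (default 10 ms analysis bin) reproduces this
apparent superdiffusion mechanistically — no anomalous transport is
simulated, which is the methodological warning: a minimum trajectory length
is needed before an α estimate means anything. `binning_study()` shows the
complementary fact that binning alone, at fixed analysis interval, barely
changes the curve shape.

## Synthetic data: what it does and does not emulate

The generators produce (i) two-detector scenes with disk/annulus/line/border
compartments, exact expected ratios before noise, and per-pixel Poisson
noise; (ii) single-exponential FLIM patches on the fixed time grid with
uniform-integer or Poisson noise; (iii) Brownian, ballistic, or
reflectively-confined trajectories with exponential on-times (a single dwell
process — unbinding and photobleaching are not distinguishable in the data
this emulates, so they are not modelled separately), log-normal photons, and
independent per-axis localization noise.

They do **not** emulate: optical PSF blur or depletion physics, detector
cross-talk, spectral bleed-through, autofluorescence, multi-exponential or
environment-dependent decays, irregular localization timestamps, or motion
during a localization. Passing tests on this data therefore validates the
estimators and their documented failure modes, not instrument-specific
artifacts.

Determinism: every generator draws all randomness under its config seed and
restores the caller's RNG state, so a fixed seed gives bit-identical output.

## Problem sizes used in the validation suite

The shipped tests run the bias study at 16×16 pixels with up to 100
replicate patches, NC-PCA separation on a 24×48 two-region stack at a
photon budget of I0 = 2000 (chosen so the decay-shape contrast between 2 ns
and 4 ns regions clearly exceeds shot noise — the high-SNR regime the score
comparison is meant for), and diffusion recovery on 500 tracks of 1 s at
D = 1 µm²/s. These sizes give comfortable statistical margins for every
property tested while keeping the whole suite around a minute of compute.

## Known limitations

* The linearized fitter's positive-bin selection makes its bias grow with
  noise amplitude; that is a property of the method, reported, not patched.
* The uniform-noise convention ([−A, A], integer) is one reading of an
  under-specified original; both fitters see the same convention, so the
  comparison between them is internally consistent.
* NC-PCA assumes a shared time grid and approximately Poisson counts;
  heavily pre-processed (e.g. already-corrected) stacks violate the
  stabilization assumption, and re-correction is intentionally not blocked
  but changes values.
* The GEV fit can sit on the Gumbel boundary for small samples; standard
  errors then come from a near-singular Hessian and are flagged `NULL`.
* TIFF storage uses 32-bit scaled samples with a YAML sidecar; integer data
  round-trips exactly, float maps to ~2e-10 of their value range.
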