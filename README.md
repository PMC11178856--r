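# nanomem

Analysis toolkit for super-resolution microscopy of solvatochromic membrane
probes (Nile Red and its derivatives). Such probes shift their emission with
local lipid packing, so a two-detector emission ratio maps membrane order;
their fluorescence lifetime reports complementary bilayer properties; and in
single-molecule tracking they probe lateral mobility within individual
membranes. `nanomem` implements the complete computational layer of such a
study — every stage exercisable on synthetic data with known ground truth, so
no microscopy data is required to run or test it.

## What it computes

**Ratiometric mapping.** For registered detector images the package forms the
per-pixel ratio det1/det2 after Gaussian smoothing (sigma 1.5 px) and
background thresholding; lower ratios indicate tighter lipid packing.
Compartment statistics (vesicle, lipid droplet, tubule, plasma membrane,
filopodium) use integer label masks, median-absolute-deviation outlier
removal (k = 3), and median summaries. Colocalization uses the Pearson
coefficient over a foreground mask; vesicle sizes come from elliptical 2D
Gaussian fits with FWHM = 2·sqrt(2·ln 2)·sigma.

**Lifetime fitting and its noise bias.** FLIM stacks hold per-pixel photon
arrival histograms I(t). Two per-pixel estimators of the single-exponential
model I = I0·exp(−t/τ) are provided: ordinary least squares on ln I versus t
(τ = −1/slope), and a nonlinear least-squares fit with the amplitude profiled
out. `noise_bias_study()` reproduces the simulation design that motivates
them: decays with I0 from 20 to 300 in steps of 40, τ = 4 ns, 0.21 ns bins
over 19.9 ns, and uniform integer noise of amplitude 0–40, fitted by both
routes to quantify how noise biases τ̂ and how the log transform amplifies
that bias.

**Noise-corrected PCA.** Stacks are Poisson-stabilized by dividing each time
bin by the square root of its mean intensity, then the pooled per-pixel
decays are eigen-decomposed; projecting each pixel onto eigenvector v_PC
gives score images s_PC = Σ_i v_PC,i · I_i (score 1 ≈ intensity-weighted mean
decay; score 2 = leading decay-shape contrast). `compare_scores()` contrasts
MAD-filtered score distributions between groups sharing one basis.

**Single-molecule tracking analytics.** Track durations and percentage
histograms; rolling-window speeds (35 ms window, accumulated distance over
elapsed time); maximum-likelihood log-normal photon statistics; localization
precision L/(2·sqrt(2·N)) with an extreme-value summary fit; time-averaged
MSD with bin resampling; Brownian (MSD = 4Dτ) and anomalous (MSD = 4Dτ^α)
fits; and sensitivity studies of α to trajectory truncation and time binning.

**Synthetic data.** `generate_ratiometric_scene()`, `simulate_flim_stack()`
and `simulate_tracks()` generate every input above with known ground truth
and bit-reproducible seeding.

## Worked example

```r
library(nanomem)

## a synthetic two-detector scene: vesicle (ratio 1.2), lipid droplet (1.1,
## bright in green), plasma membrane (0.8), Poisson noise at 3000 counts
cfg <- synth_image_config(
  image_shape = c(96L, 96L), pixel_size = 40, photon_budget = 3000, seed = 1,
  compartments = list(
    list(class = "vesicle",
         shape = list(type = "disk", center = c(30, 60), radius = 9),
         ratio = 1.2, green_frac = 0.05),
    list(class = "LD",
         shape = list(type = "disk", center = c(62, 30), radius = 7),
         ratio = 1.1, green_frac = 0.4),
    list(class = "PM", shape = list(type = "border", width = 4),
         ratio = 0.8)))
scene <- generate_ratiometric_scene(cfg)
rm_ <- normalize_ratio(ratio_map(scene$pair, sigma = 1.5, background = 20))
compartment_stats(rm_, scene$masks)$summary
#>        class label n_pixels median_ratio         mad
#> 1    vesicle     1      249    1.4906783 0.009330137
#> 2         LD     2      147    1.3734746 0.007242052
#> 3     tubule     3        0           NA          NA
#> 4         PM     4     1466    0.9961111 0.007651326
#> 5 filopodium     5        0           NA          NA
```

The medians are the configured ratios divided by the global median (0.804,
dominated by the plasma-membrane pixels), and their ordering — plasma
membrane below vesicles — is exactly what the ratio is designed to resolve.

```r
## lifetime noise bias at I0 = 100 (25 replicate patches per amplitude)
bs <- noise_bias_study(flim_sim_config(I0_start = 100, I0_stop = 100,
                                       I0_step = 40,
                                       noise_amplitudes = c(0, 20, 40),
                                       seed = 1), n_reps = 25)
bs[, c("I0", "amplitude", "method", "mean_tau", "sd_tau")]
#>    I0 amplitude     method mean_tau sd_tau
#> 1 100         0 linearized     4.00  0.000
#> 2 100         0  nonlinear     4.00  0.000
#> 3 100        20 linearized     7.63  0.985
#> 4 100        20  nonlinear     4.01  0.312
#> 5 100        40 linearized    12.68  3.144
#> 6 100        40  nonlinear     4.04  0.620
```

Both estimators are exact without noise; under noise the log-linearized fit
overestimates τ badly (12.7 ns at amplitude 40 for a 4 ns truth) while the
nonlinear fit stays near truth — the bias the log transform amplifies.

```r
## Brownian tracking: 200 tracks, D = 1 um^2/s, dt = 1 ms, 1 s each
ens <- simulate_tracks(synth_track_config(n_tracks = 200, D = 1, dt = 1,
                                          on_time_mean = 1000,
                                          duration_model = "fixed", seed = 1))
fit_msd(msd(ens, time_bin = 1, max_lag = 260), model = "anomalous")
#> <diffusion_fit> anomalous: D = 0.9946 um^2/s, alpha = 1.001 (65 lags)

localization_precision(200, list(L = 50, fwhm = 800))
#> [1] 1.25
```

## Conventions

Images are row-major with the origin at the top-left pixel; x increases along
columns, y along rows; positions are nm, times ms (1 nm/ms = 1 µm/s,
1000 nm²/ms = 1 µm²/s). Label masks encode 0 background, 1 vesicle, 2 lipid
droplet, 3 tubule, 4 plasma membrane, 5 filopodium. Track CSVs have columns
`track_id, t_ms, x_nm, y_nm, photons`.
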