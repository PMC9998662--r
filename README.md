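# filotrace

Quantification of **dendritic filopodium (DF) dynamics** from time-lapse
fluorescence microscopy. Dendritic filopodia are thin, actin-rich
protrusions of neuronal dendrites — precursors of dendritic spines — whose
motility (protrusion and retraction) is driven by actin elongation factors
that enrich at the filopodial tip. `filotrace` is for cell biologists who
track DF tips in TIRF movies and want, from those tracks plus the raw
movie: per-filopodium centerlines and lengths, a standard motility metric
suite, and a statistically principled answer to the question *does tip
enrichment of a tagged protein precede motility, or follow it?*

## What it computes

**Centerline tracing.** Given the manually tracked base and tip of a DF
and the space-filler (e.g. LifeAct) channel, the local orientation of the
DF at pixel *i* is estimated from the intensity-weighted second central
moments over a 15 × 15 pixel domain,

    theta_i = 1/2 * atan2(2*mu11, mu20 - mu02),

and the centerline curve (x(s), y(s)) is obtained by solving the
boundary-value ODE

    d2x/ds2 = -sin(theta) dtheta/ds,   d2y/ds2 = cos(theta) dtheta/ds,

with the tracked base and tip as Dirichlet end conditions, by iterative
relaxation from the straight chord. DF length is the arc length of the
converged curve.

**Motility metrics.** Average tip speed (mean of instantaneous speeds,
i.e. absolute tip displacement per frame interval); motile / non-motile
classification against the substantive-motility threshold of one pixel per
interval (0.0128 µm/s at 0.064 µm pixels and 5 s); percent time motile;
median protrusion and retraction rates (median of length-change rates
exceeding ±threshold); mean tip fluorescence in a 384 nm-radius disc with
non-cell background masked out, normalized by its temporal minimum; and
the temporal variance of that normalized signal.

**Lead–lag analysis.** The cross-correlation function (CCF) of tip
fluorescence (FTIP) and direction-corrected tip movement (DCTM, the signed
length-change rate), both smoothed with a 3-point moving average:

    CCF(tau) = cor( FTIP(t + tau), DCTM(t) ),

so a peak at negative offset means fluorescence enrichment *precedes*
motility. Per-DF CCF profiles are hierarchically clustered (Ward linkage)
and the cluster with the highest mean peak CCF is the **top-correlating
subcluster (TCS)**. Peak significance uses the `2/sqrt(n - |offset|)`
bound. Population-level significance comes from a **block bootstrap**:
8-frame blocks of each DF's raw motility series are shuffled against its
fluorescence series, the identical analysis is re-run on (by default)
1,000 randomized datasets, and the p-value is the fraction of randomized
TCS mean peaks reaching the observed one.

**Synthetic movies.** A generator renders curved filopodia as
Gaussian-cross-section ridges on a dendrite shaft, with stochastic length
dynamics (constant, sinusoid, Ornstein–Uhlenbeck, or two-state
protrude/retract), a tip-localized fluorescence channel whose enrichment
leads motility by a programmable number of frames, camera noise, and
optional tracking jitter — so every stage of the pipeline is testable
against known ground truth.

## Worked example

Simulate one filopodium whose tip factor leads motility by 2 frames
(10 s), then run the full pipeline:

```r
library(filotrace)

scene <- scene_params(
  n_frames = 60,
  filopodia = list(filo_params(base_xy = c(12, 48),
                               length_model = length_ou(2.5, 60, 0.4),
                               lag_frames = 2, gain = 8,
                               fluor_noise_sd = 0.05)))
ds <- simulate_scene(scene, seed = 7)

cfg     <- pipeline_config()
curves  <- trace_centerlines(ds$geometry, ds$tracks, cfg)
lengths <- centerline_lengths(curves)
series  <- build_df_series(ds$tip_channel, ds$tracks, lengths)

motility_threshold(0.064, 5)
#> [1] 0.0128
summarize_motility_all(series, motility_threshold(0.064, 5))
#> # A tibble: 1 × 10
#>   df_id n_frames avg_tip_speed_um_s is_motile pct_time_motile avg_length_um
#>   <chr>    <int>              <dbl> <lgl>               <dbl>         <dbl>
#> 1 df01        60             0.0240 TRUE                 59.3          3.01

paired <- pair_series(series)
ccf_peaks(compute_ccf(paired, 12))
#> # A tibble: 1 × 6
#>   df_id n_pairs peak_value peak_offset sig_bound significant
#>   <chr>   <int>      <dbl>       <int>     <dbl> <lgl>
#> 1 df01       60      0.952          -2     0.263 TRUE
```

The filopodium is classified motile (average speed 0.024 µm/s, well above
the 0.0128 µm/s threshold; 59% of intervals motile), its mean length is
recovered at 3.0 µm, and the CCF peaks at offset −2 frames (−10 s) with
r = 0.95, above the significance bound 2/√60 ≈ 0.26: the programmed
2-frame fluorescence lead is recovered. With several filopodia,
`cluster_tcs()` labels the TCS and `bootstrap_tcs()` attaches the
block-bootstrap p-value (`tidy()`/`glance()` methods and `autoplot()`
included); `plot_ccf()` draws the profile fan.

A thin CLI over the same functions (subcommands `simulate`, `centerline`,
`metrics`, `ccf`) lives at `inst/scripts/filotrace-cli.R`.

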