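---
title: "Methods: centerline tracing and tip-fluorescence lead-lag analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centerline tracing and tip-fluorescence lead-lag analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`filotrace` quantifies dendritic filopodium (DF) dynamics from calibrated
time-lapse movies and manually tracked base/tip positions. This vignette
is the package's own account of the underlying methods: the models, the
numerical choices, and what the validation on synthetic data does and does
not demonstrate.

## Data model and conventions

Pixel coordinates are 0-based, `x` the column index (rightward) and `y`
the row index (downward); `frame` is 1-based. Track tables carry raw pixel
coordinates because they index the image; every derived quantity is
expressed in physical units (µm, s) exactly once, at the point where a
pixel quantity becomes a measurement. Interior frames missing from a track
are tolerated at read time and flagged: metric code treats each maximal
contiguous run of valid frames independently and never differences across
a gap (missing timepoints are dropped, not interpolated). Undefined metric
values — no qualifying protrusion intervals, a fully masked ROI — are
explicit `NA`s and are excluded from population statistics, never coerced
to zero, which would bias rate medians toward the threshold.

All analysis steps are invariant to uniform intensity rescaling, so
movies may arrive in any nonnegative unit; the TIFF writer stores 16-bit
samples normalized to the stack maximum for the same reason.

## Centerline model

The DF long-axis orientation at pixel *i* is the principal axis of the
intensity-weighted second central moments of pixel coordinates in a
15 × 15 pixel window centered there:

$$\theta_i = \tfrac{1}{2}\,\mathrm{atan2}\!\left(2\mu_{11},\;
\mu_{20}-\mu_{02}\right),$$

with $\mu_{pq}$ the intensity-weighted central moments of $(x-\bar x,
y-\bar y)$. Orientation is defined modulo $\pi$ and reported in
$[-\pi/2, \pi/2)$.

Two numerical choices matter here:

* **Inscribed-disc domain.** The moments are restricted to pixels whose
  centers lie within the disc inscribed in the square window
  (radius `window_px/2`). A square domain clips a *curved* ridge
  asymmetrically about the local normal, in a way that depends on the
  ridge orientation relative to the pixel axes; on a circular arc of
  radius 20 px this biases the moment orientation by up to ~0.1 rad
  (verified against a continuous-integral brute force) and drags the
  reconstructed curve toward its chord. The disc domain is rotationally
  symmetric, clips the ridge symmetrically at every orientation, and
  removes the bias. Window pixels outside the image are excluded (no
  padding; fabricating edge intensity would bias orientations toward the
  image axes).
* **Degenerate patches.** Zero total intensity or an isotropic patch
  ($\mu_{11}=0$, $\mu_{20}=\mu_{02}$, e.g. flat background) has no
  orientation; such nodes fall back to the local chord direction of the
  current curve iterate, which keeps the relaxation well defined.

Orientation is only defined modulo $\pi$, but the ODE needs a continuous
signed angle: `continue_branch()` shifts each successive orientation by
the multiple of $\pi$ minimizing the jump from its predecessor, anchoring
the first element within $\pi/2$ of the base-to-tip chord direction.

The centerline $(x(s), y(s))$ solves the second-order system

$$x'' = -\sin\theta\,\theta', \qquad y'' = \cos\theta\,\theta',$$

with Dirichlet conditions at the tracked base and tip. Discretization:
$N = \max(16, \lceil 2 \cdot \mathrm{chord\ length\ (px)}\rceil)$ nodes;
second-order central finite differences (a constant-stencil tridiagonal
solve); $\theta'$ by central differences on the continued branch;
re-parameterization to uniform arc length (linear interpolation of the
chordal arc length) after every iteration. The relaxation starts from the
straight chord, resamples the tangent field at the current nodes each
iteration, and stops when the maximal node displacement falls below
0.05 px (cap 50 iterations; non-convergence is an error carrying the last
iterate). These solver details are this package's own choices, made for
robustness at DF scale (lengths ≲ 10 µm); they are validated against
analytic oracles, not claimed to replicate any particular prior
implementation. In the analytic constant-$\theta$ limit the discrete
solution is exactly the straight chord.

## Motility and fluorescence metrics

The substantive-motility threshold is one pixel of displacement per frame
interval — `pixel_size_um / interval_s`, i.e. 0.0128 µm/s at 100×
(0.064 µm pixels) and 5 s — below which displacement is
indistinguishable from tracking error. Classification uses a strict
inequality (`speed > threshold`); ties are measure-zero on real data.

Tip speed uses Euclidean tip displacement; protrusion/retraction rates
use centerline-length differences. The two are deliberately distinct:
a buckling or wagging DF can move its tip without changing length.
Rate medians are taken only over intervals whose |rate| exceeds the
threshold, separately for positive (protrusion) and negative (retraction)
rates, and are `NA` when no interval qualifies.

Tip fluorescence is the mean intensity in a disc of 384 nm radius around
the tracked tip, with non-cell pixels removed by the mask when present.
Disc membership is by pixel-center distance (no partial-pixel weighting),
matching typical integer-ROI behavior of acquisition software. The series
is normalized by its minimum over valid frames — an expression-level
correction — so the normalized series is ≥ 1 with minimum exactly 1, and
its temporal variance (sample variance, $n-1$ denominator, chosen because
per-DF samples are small) measures the spread of tip enrichment.

For perturbation experiments, `fold_change_bins()` averages a per-frame
quantity in successive fixed-length bins (e.g. 2.5 or 5 min) after a
baseline window and divides by the baseline mean.

## Lead-lag analysis

DCTM (direction-corrected tip movement) is the signed length-change rate
per interval, aligned at the later frame; FTIP is the min-normalized tip
fluorescence. Both are smoothed with a centered 3-point moving average
whose endpoints use the available 2-point mean and which never averages
across a gap (the endpoint rule is this package's documented choice).

$$\mathrm{CCF}(\tau) = \mathrm{cor}\left(\mathrm{FTIP}(t+\tau),\,
\mathrm{DCTM}(t)\right),\qquad \tau = -K,\dots,K,$$

over the overlapping valid frames, so a peak at negative $\tau$ means
fluorescence enrichment precedes motility (the sign convention is fixed
by that interpretation). Offsets whose overlap has zero variance are
undefined and excluded from the peak search; peak ties are resolved to
the smallest $|\tau|$. The per-DF significance bound is
$2/\sqrt{n - |\tau|}$ with $n$ the number of paired valid timepoints.

**TCS.** CCF-versus-offset vectors are clustered agglomeratively
(Euclidean distance, Ward linkage); the tree is cut at the cluster count
in 2–4 maximizing the mean silhouette width; the cluster with the highest
mean peak CCF is the top-correlating subcluster. With exactly two
profiles each forms its own cluster; identical profiles collapse to a
single all-TCS cluster with a warning.

**Block bootstrap.** Each DF's *raw* (unsmoothed) DCTM series is
partitioned into consecutive 8-frame blocks (final partial block kept
intact), the block order is permuted uniformly, and the identical
analysis — smoothing, CCF, clustering, TCS mean peak — is re-applied;
FTIP is untouched. The p-value is the fraction of randomized TCS mean
peaks ≥ the observed one, floored at `1/n_randomizations` so zero is
never reported. Two choices here were genuinely open:

* *What to shuffle.* Shuffling the already-smoothed series leaves the
  observed series systematically smoother than its nulls (block joints
  introduce discontinuities), which shifts the null p distribution away
  from uniform. Shuffling the raw series and re-smoothing restores
  exchangeability under independence; the package's calibration test
  (200 independent experiments × 200 randomizations) checks the p
  distribution against uniformity.
* *How to form the randomized TCS.* The default re-runs the full
  clustering on every randomized dataset, so observed and null statistics
  are computed by the identical procedure — the property that makes the
  p-value calibrated. The alternative reading, constraining the
  randomized TCS to the observed cardinality via the top-k peaks, is
  available as `method = "fixed_k"`; it is deliberately conservative
  (the top-k statistic dominates the clustered one) and is provided for
  comparison, not calibration.

Per-DF z-scoring (`z_score()`) supports pooled scatter analyses by
removing expression-level differences.

## Synthetic data: what it emulates, and what it does not

The generator mirrors the acquisition regime the thresholds were designed
for: 0.064 µm pixels, 5 s intervals, 60-frame movies, DF lengths 1–5 µm.
A scene holds a dendrite shaft (vertical band) with filopodia as
constant-curvature arcs from its edge, rendered as ridges of Gaussian
cross-section (default σ = 1.5 px) by evaluating distance-to-centerline
on a 3× supersampled grid and box-downsampling (avoiding aliasing bias in
orientation estimates). Length dynamics: constant, sinusoid,
Ornstein–Uhlenbeck (exact discretization), or two-state protrude/retract
with exponential dwell times. The tip-factor channel is a dim cell fill
plus a Gaussian tip spot whose amplitude is
$F(t) = \mathrm{baseline} + g\,M(t+k) + \varepsilon$ — fluorescence
leading motility by $k$ frames. Camera noise is additive Gaussian plus
optional Poisson shot noise; tracking jitter (off by default) adds
isotropic Gaussian error to the exported tracks so the noise floor of
speed metrics can be studied explicitly.

Passing the end-to-end tests on these scenes shows that the pipeline
recovers geometry, motility and programmed lead-lag structure under the
modeled conditions. It does not show robustness to what the generator
does not model: photobleaching, TIRF depth decay, non-Gaussian PSFs,
crossing or fasciculating filopodia, drift, or segmentation errors in the
cell mask. Real-data use still depends on the upstream manual tracking
and preprocessing being sound.

## Validation problem sizes

The test suite validates: tangent angles against brute-force moment sums;
centerlines against analytic line and quarter-arc ridges (length within
2%, perpendicular deviation < 1 px); the metric suite against an
independent brute-force implementation on 100 random series (exact
agreement); end-to-end lag recovery on 50 seeded rendered scenes with
leads of 1–2 frames (≥ 90% recovered); planted-cluster TCS recovery with
20 coupled + 20 independent DFs (≥ 90% of coupled DFs labeled TCS);
bootstrap calibration over 200 independent experiments × 200
randomizations (p uniform by Kolmogorov–Smirnov, > 90% of experiments
with p > 0.05) with noise-free coupling pinned at the reporting floor;
and byte-identical reproduction of every stochastic stage under a fixed
seed. `scripts/acceptance.R` re-runs the main computations at these
scales and reports the recovered quantities as JSON.

## Known limitations

* The tangent field is estimated from a single channel; strongly
  overlapping structures (crossing filopodia, nearby debris) within the
  15 px window will bias orientations — mirroring the original manual
  inclusion criteria that exclude such DFs from tracking.
* The centerline is 2-D; out-of-plane excursions shorten apparent length.
* The moment orientation is exact for straight ridges and nearly unbiased
  for arcs down to radius ≈ window size; sharper kinks are smoothed over.
* Block length 8 assumes motility autocorrelation decays within ~40 s;
  substantially longer memory would call for longer blocks.
* The CCF assumes an approximately stationary, linear coupling; strongly
  nonstationary enrichment (e.g. single bursts) is better served by the
  fold-change binning utilities.
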