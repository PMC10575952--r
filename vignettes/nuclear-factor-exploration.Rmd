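---
title: "Mapping how nuclear factors explore chromatin: models and methods"
author: "smtmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping how nuclear factors explore chromatin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smtmsim)
```

Transcription factors and other nuclear factors find their binding sites by
diffusing through a nucleus that is anything but homogeneous: compact
chromatin-dense domains (CDs) are interspersed by the chromatin-poor channel
network of the interchromatin compartment (IC). `smtmsim` implements a
complete analysis chain for asking how a factor's search relates to that
organization: single-molecule tracking (SMT) movies give trajectories;
multifocal structured illumination (mSIM) of a DNA stain gives a
super-resolved density map of the same nucleus; and a set of statistics —
displacement-distribution kinetics, diffusion-state hidden Markov
segmentation, fold anisotropy, and density overlays — connects the two.
Because raw experimental movies are not redistributable, the package also
contains a first-class synthetic-data generator that reproduces the
statistical structure every stage assumes, so the whole chain is testable
end to end.

## The synthetic nucleus and trajectory generator

`make_phantom()` builds a 2D nuclear density map: an elliptical mask holding
a unit background plus isotropic Gaussian CDs, normalized so the mean over
the mask is exactly 1 (the convention used for all mapping: values above 1
are denser than the nuclear average). Defaults — 256 px at 0.1 µm/px, 40
domains of 0.3 µm radius, contrast 2 — give a nucleus of realistic size
(~23 × 18 µm ellipse) with a density range of roughly 0.5–3, comparable to a
normalized DNA-stain image.

`simulate_tracks()` propagates molecules through a hidden Markov chain of
diffusive states. Per frame a molecule first updates its state, then takes
an isotropic Gaussian step with per-axis SD $\sqrt{2 D_{\mathrm{true}}
\Delta t}$, plus an independent axial step; the track ends when the molecule
leaves the detection slice $|z| > \Delta z$ (re-entry is not modelled — an
escaped molecule is simply a lost track, matching how escape enters the
kinetic model below). Recorded positions carry Gaussian localization noise
of SD $\sigma$. Key conventions:

* **Apparent vs true D.** Observed displacement statistics obey
  $D_{\mathrm{app}} = D_{\mathrm{true}} + \sigma^2/\Delta t$. Presets are
  specified in apparent units and the simulator steps with
  $\max(0, D_{\mathrm{app}} - \sigma^2/\Delta t)$. The default p53-like
  preset (below) states an apparent bound-state D of 0.08 µm²/s with
  $\sigma$ = 35 nm at $\Delta t$ = 10 ms; since $\sigma^2/\Delta t$ =
  0.1225 µm²/s already exceeds that, the bound state is truly immobile and
  its realised apparent D is the localization floor 0.1225 µm²/s. This is a
  deliberately conservative (harder) setting for every downstream
  classification task, and tests are calibrated against the realised value,
  not the nominal one.
* **Density coupling.** The probability of a transition *into* state $k$ is
  multiplied by (local normalized density)$^{c_k}$ and the row
  renormalized. The default exponents are graded, $c = (2, 1, 0)$ for
  (bound, slow, fast): binding is strongly enriched in dense chromatin,
  slow diffusion mildly so, fast diffusion not at all. A binding-only
  coupling was evaluated first and discarded: it leaves slow molecules at
  marginally *lower* density than fast ones (slow molecules that reach
  dense regions promptly convert to bound and are counted there), so it
  cannot reproduce the bound > slow > fast density ordering the generator
  exists to emulate.
* **No lateral confinement.** Molecules may step outside the nuclear mask
  (the density bias then falls back to the nuclear mean, and mapping
  functions drop out-of-mask positions). This keeps lateral displacement
  statistics exactly Brownian, which the property tests rely on.

The default "p53-like" preset uses apparent $D$ = (0.08, 1.0, 5.0) µm²/s,
weights (0.35, 0.40, 0.25), $\Delta t$ = 10 ms, $\sigma$ = 35 nm and
$\Delta z$ = 0.5 µm. The per-frame transition matrix is chosen reversible
with respect to the weights, with slow→bound = 0.10 and fast→bound = 0.01 —
a 10× preference for binding out of the slow state. $\Delta z$ is an assumed
value: the half-thickness of a HILO detection slice is instrument-specific
and is therefore an explicit configuration parameter everywhere it enters.
Tracks are capped at 50 frames, emulating a finite observation window;
photophysics beyond this truncation (blinking, bleaching kinetics) is out
of scope.

```{r sim-example}
ph <- make_phantom(seed = 1)
pr <- preset_p53like(n_tracks = 2000, seed = 1)
tracks <- simulate_tracks(ph, pr)
```

What passing tests on these synthetics do *not* show: real movies add
heterogeneous background, uneven photoactivation, detector noise and drift;
real chromatin density is 3D and changes over time; and real factors have
continuous mobility spectra rather than three discrete states. The
generator's role is to verify that each estimator recovers known structure,
not to claim biological realism beyond the modelled features.

## mSIM rendering and reconstruction

The excitation side of mSIM is an equilateral triangular lattice of
diffraction-limited spots (side 16 pixels in the canonical configuration),
scanned in integer-pixel steps. With the vertical period rounded to whole
pixels, $p = \mathrm{round}(16\sqrt{3}/2) = 14$, a complete scan is $16
\times 14 = 224$ frames, after which every pixel has been visited by a spot
center exactly once — a property `coverage_counts()` checks exhaustively
and that holds for any integer row offset (the alternate-row shift is
rounded to $\mathrm{round}(s/2)$ so spot positions stay integer for odd
sides).

`reconstruct()` applies the standard image-scanning-microscopy recipe:

1. **Virtual pinhole** — for each frame and spot, keep camera pixels within
   `pinhole_radius` of the spot (rejecting out-of-focus light; optical
   sectioning is validated through the flat-background rejection property
   only, not 3D stacks).
2. **Pixel reassignment** — place each kept pixel at
   $\mathrm{spot} + (\mathrm{pixel} - \mathrm{spot})/2$ on a 2× grid. This
   half-shift target always lands exactly on an upsampled grid point, so
   bilinear splatting reduces to direct deposition.
3. **Normalization** — divide by per-pixel visitation counts *weighted by
   the mean transmission of each pinhole offset*, estimated from the stack
   itself. Pixels one step from the spot are systematically dimmer than the
   spot pixel; unweighted counts would imprint that fall-off as a
   pixel-parity texture (~5% ripple on a flat sample at pinhole radius 1).
   With transmission weighting the flat-field is clean (<0.5% CV) and, for
   a point source with equal excitation and emission PSFs, the class
   amplitudes cancel exactly, so the reconstructed PSF width converges to
   the theoretical $\sigma/\sqrt{2}$.
4. Upsampled pixels no (spot, offset) combination can reach (a parity
   subset, when the pinhole is smaller than one pixel) are filled by
   iterative neighbour averaging for display; `measure_fwhm()` excludes
   these interpolated pixels from its Gaussian fits, since interpolation
   low-passes the PSF by ~1.5%. Finally the image is rescaled so its total
   equals the post-pinhole photon total (photon bookkeeping).

Resolution improvement is measured by `measure_fwhm()` as the ratio of
widefield to reconstructed FWHM of a noiseless synthetic bead with equal
excitation/emission PSF widths; the measured value is 1.41×, at the
theoretical $\sqrt{2}$ maximum (the test asserts ≥ 1.4). The default
pinhole radius is 1.0 camera pixel. Before density mapping, reconstructed
images are flattened by dividing by a heavily blurred copy (Gaussian SD
2.16 µm, replicated edges) and normalized to the nuclear mean
(`normalize_density()`).

## Spot detection and linking

`log_detect()` applies a zero-sum Laplacian-of-Gaussian filter at the scale
of the expected molecule diameter (default 0.8 µm), takes strict local
maxima of the MAD-normalized response above a unitless quality threshold
(default 5 — the absolute calibration of this number is camera-specific and
no attempt is made to reproduce any particular scanner's scale), and
refines positions by local centroid. `link_tracks()` performs
frame-to-frame linear-assignment linking: an optimal bipartite matching
that maximizes the number of links among pairs closer than $r_{\max}$ and,
among those, minimizes total squared displacement (solved as a weighted
bipartite matching with a per-edge cardinality bonus). There is no gap
closing, splitting or merging: the kinetic model below assumes contiguous
$\Delta t$ displacements.

The linking radius comes from the Brownian escape relation
$P(r > r_{\max}) = e^{-r_{\max}^2 / 4 D \Delta t}$: `choose_rmax(5, 0.01,
0.01)` = 0.96 µm — for the fastest plausible nuclear factor (5 µm²/s) at
100 fps, a 1 µm radius misses fewer than 1% of steps.

## Displacement-distribution kinetic model

Jump lengths $r$ of a $K$-population mixture follow
$$p(r) = \sum_{i=1}^{K} w_i \frac{r}{2 D_i \Delta t}
          e^{-r^2 / 4 D_i \Delta t}, \qquad
  w_i = \frac{f_i\, p(\Delta z, D_i)}{\sum_j f_j\, p(\Delta z, D_j)},$$
where $p(\Delta z, D)$ is the probability that a molecule starting
uniformly inside the detection slice is still inside after one frame:
$$p(\Delta z, D) = \mathrm{erf}\!\left(\frac{\Delta z}{\sqrt{D \Delta t}}\right)
  + \frac{\sqrt{4 D \Delta t / \pi}}{2 \Delta z}
    \left(e^{-\Delta z^2 / D \Delta t} - 1\right).$$
Fast molecules are preferentially lost, so the raw mixture weights
understate fast fractions; the renormalization by $\sum_j f_j p_j$ makes
the density integrate to 1 (the observed histogram is conditioned on
detection in both frames) and the reported $f_i$ are escape-corrected
fractions. With $\Delta z = \infty$ the weights reduce to the fractions and
each component is a plain Rayleigh density with mode $\sqrt{2 D \Delta t}$.

Numerically, both fitting objectives see the *observed* mixture $(w, D)$
and the fractions are recovered afterwards by inverting $w_i \propto f_i
p_i$. The default objective (`method = "cdf"`) is least squares between the
empirical and model CDF, evaluated on at most 2000 order statistics and
optimized by BFGS on $(\log D, \mathrm{logit}\, w)$ seeded from the EM
solution plus ≥5 log-spaced jittered restarts; `method = "mle"` is a
closed-form EM on squared displacements (exponential mixture), which is
fast and monotone. The two agree on D to well within 5% on clean data.
Fitting uses raw displacements, never binned counts; the 20 nm histogram
(`displacement_histogram()`) exists for plotting parity only. Degenerate
all-zero input returns a single immobile component flagged `degenerate`.
$\Delta z$ is a global configuration input (default 0.5 µm, flagged as
assumed), not a fitted parameter.

Model order is chosen by `select_k_bic()`: maximum-likelihood fits for $K =
1..4$ compared by $\mathrm{BIC} = -2\log L + (2K - 1)\ln n$; results below
$n = 100$ carry a low-confidence flag. Condition comparisons
(`compare_conditions()`) use two-sided Kolmogorov–Smirnov tests on per-cell
parameter distributions with Bonferroni correction over the five parameters
(Kruskal–Wallis is available as an alternative; KS is the default).

```{r fit-example}
disp <- track_displacements(tracks)
fit <- fit_displacements(disp$r_um, dt = 0.01, K = 3, dz = 0.5)
coef(fit)
```

## Diffusion-state HMM and bound filtering

`fit_hmm()` is a maximum-likelihood surrogate for variational-Bayes
single-particle-tracking classifiers: same emission and transition
structure, simpler machinery. Emissions are squared jumps $r^2 \sim
\mathrm{Exp}(4 D_k \Delta t)$ — exact for isotropic 2D Brownian steps; the
bound state's D absorbs the localization floor $\sigma^2/\Delta t$, and the
negative correlation that shared localization noise induces between
consecutive displacements is ignored (as it is in the reference
classifiers). Baum–Welch EM runs vectorised across tracks with 10 seeded
restarts; the log-likelihood trace is checked non-decreasing on every run.
Only tracks with at least `min_len = 8` localizations enter the fit
("longer than 8 frames" is implemented inclusively, ≥ 8, and is
configurable). `segment_tracks()` returns the Viterbi path per track plus
the forward–backward posterior bound probability per displacement; BIC uses
$K^2 + K - 1$ free parameters.

`filter_bound()` removes bound track segments before anisotropy analysis.
A displacement is dropped when its Viterbi label is bound *or* its
posterior bound probability exceeds 0.25; remaining contiguous diffusing
runs of ≥ 2 displacements are returned as segments. The posterior cut is
the one deliberate departure from plain Viterbi splitting: the MAP path
optimizes whole-path probability, not per-step purity, and measurement on
the default preset shows it retains ~7% truly-bound displacements *even
when decoding with the true generating parameters* — above the ≤ 5% purity
this filter is required to deliver. The 0.25 threshold operates at ~3–4%
residual while keeping ~87% of truly diffusing steps; `max_p_bound = 1`
restores pure Viterbi behaviour. `residual_bound_fraction()` audits the
filter against ground truth.

## Diffusional anisotropy

For every interior localization of a diffusing segment,
`compute_angles()` measures the angle between consecutive jump vectors,
folded to [0°, 180°] (displacement statistics are mirror-symmetric).
`f180_over_0()` is the fold-anisotropy metric: counts in the backward
window [150°, 180°] over counts in the forward window [0°, 30°] (window
edges inclusive; the windows are the ±30° bands around 180° and 0° mapped
to folded angles). Free Brownian motion gives 1; confinement and
re-binding give values above 1. `anisotropy_vs_distance()` profiles the
metric against spatial scale, defined as the mean of the two jump lengths
(the defining papers leave "distance run" unspecified; the mean is the
symmetric choice), in log-spaced bins from 50 nm; bins with fewer than 200
angles are flagged. Errors are the SD over 100 random 50% subsamples of the
angles (`bootstrap_sd()`); subsampling is over angles, not cells, matching
how the statistic pools data. Zero-length jumps have undefined direction
and are dropped; no minimum-jump filter is applied by default, but one is
available because localization noise biases the apparent direction of very
short jumps — noise on slow diffusion measurably inflates $f_{180/0}$
above 1, a documented confounder asserted directionally in the tests.

## Density mapping

`density_map()` fixes the reference frame: normalized intensity (nuclear
mean 1) and per-nucleus intensity quartiles of equal pixel count (ties
broken by stable pixel order; quartiles are per nucleus because
normalization is). Overlay statistics:

* `instantaneous_D()` — $D_{\mathrm{inst}} = r^2 / 4\Delta t$ per
  displacement.
* `dinst_density_heatmap()` — frequency of each density class at the
  *starting* position of displacements, per log-spaced $D_{\mathrm{inst}}$
  bin, rows normalized to 1.
* `enrichment_profile()` — class frequencies minus the 0.25 baseline and
  the scalar score (class-4 minus class-1 frequency);
  `correlate_enrichment_vs_boundfraction()` relates the score to fitted
  bound fractions across factors by Pearson correlation.
* `radial_density_profile()` — the 1 µm × 1 µm window around each molecule,
  averaged per diffusion state (windows clipped by the mask are dropped;
  molecules are pooled across cells, with a per-cell option left to the
  caller by passing per-cell position sets), then rotationally averaged on
  a 2× oversampled window grid with annuli at pixel resolution starting at
  radius 0. A two-sided one-sample t-test asks whether the density at the
  molecule position differs from the nuclear average of 1.
* `pair_cross_correlation()` — distances from bound-segment centroids to
  diffusing positions, normalized by the same histogram against uniform
  random points in the mask (20 randomizations by default).
* `register_tracks_to_map()` — a constant translation hook for chromatic
  registration offsets; identity by default.

## Numerical choices and problem sizes

Tolerances and sizes used in the test suite were chosen to keep every check
comfortably significant at desk scale: displacement-statistics properties
use ≥ 10⁵ displacements (MSD within 2%, axial survival within 1% of the
closed form, dwell times within 3% using interior runs of 1000-frame
windows to avoid censoring bias); parameter-recovery checks use 10⁵
displacements (fractions ± 0.05, D ± 15%) and ≥ 2 × 10⁴ displacements for
the HMM (transition entries ± 0.05); BIC consistency is checked over 20
seeded replicates at n = 2 × 10⁴. The end-to-end purity check simulates
10⁴ molecules. Optimizer settings (multi-start counts, D floors at 10⁻⁷
µm²/s, EM tolerance 10⁻⁸ relative) are stated in the function
documentation; ties in quartile ranking are broken by stable pixel order;
degenerate inputs (all-zero displacements, featureless FWHM windows, empty
forward anisotropy windows, empty heatmap rows) return flagged results
rather than errors.

## Known limitations

The simulation is 2D-plus-escape, not 3D; axial re-entry, gap closing, and
motion-blur corrections are not modelled. The HMM reports maximum-
likelihood point estimates, not posterior state-number evidence. The LoG
threshold is scanner-relative. Real-data entry points (track CSV, TIFF
images) are provided, but all quantitative validation in this package rests
on the synthetic generator; conclusions about any particular instrument
require its own calibration of $\sigma$, $\Delta z$ and the detection
threshold.
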