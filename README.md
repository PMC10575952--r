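# smtmsim

Tools for analysing how nuclear factors (transcription factors,
architectural proteins, chromatin components) explore the cell nucleus, by
combining live-cell **single-molecule tracking (SMT)** with **multifocal
structured illumination microscopy (mSIM)** of DNA density. The package
covers the full chain — and, because raw microscopy data of this kind is
rarely redistributable, ships a first-class synthetic-data generator so
every stage is testable end to end:

* **Synthetic data** — nuclear density phantoms with chromatin-dense
  domains (CDs) and interchromatin channels (IC); three-state
  (bound/slow/fast) Markov trajectories with localization noise, axial
  escape from the detection slice, and density-coupled binding; multifocal
  excitation frame stacks and SMT movies.
* **mSIM reconstruction** — triangular scan patterns (224 frames for the
  canonical side-16 lattice), virtual pinholing, pixel reassignment onto a
  2× grid, illumination flattening, FWHM measurement, density
  normalization.
* **Detection & linking** — Laplacian-of-Gaussian spot detection and
  linear-assignment (LAP) frame-to-frame linking with a principled maximal
  displacement: `P(r > r_max) = exp(-r_max² / 4DΔt)`.
* **Displacement-distribution kinetics** — the jump-length mixture
  `p(r) = Σ_i w_i · r/(2 D_i Δt) · exp(-r²/4 D_i Δt)` with
  `w_i ∝ f_i · p(Δz, D_i)`, where `p(Δz, D)` corrects for molecules
  diffusing out of a detection slice of half-thickness Δz; CDF or
  maximum-likelihood fitting, BIC model selection, per-cell condition
  comparisons (KS + Bonferroni).
* **Diffusion-state HMM** — exponential emissions on squared jumps,
  Baum–Welch EM with restarts, Viterbi segmentation, transition-rate
  summaries, and a purity-audited bound-segment filter.
* **Diffusional anisotropy** — fold-anisotropy `f180/0` (backward vs
  forward step probability) versus the distance run, with subsampling
  errors; distinguishes free, compact and guided exploration.
* **Density mapping** — per-nucleus density quartiles, instantaneous-D ×
  density-class heatmaps, radial density profiles around classified
  molecules, and bound/diffusing pair cross-correlation.

## Worked example

```r
library(smtmsim)

# nucleus + 2000 synthetic p53-like trajectories
ph  <- make_phantom(seed = 1)
pre <- preset_p53like(n_tracks = 2000, seed = 1)
tracks <- simulate_tracks(ph, pre)

# three-component kinetic model of the jump-length distribution
disp <- track_displacements(tracks)
fit <- fit_displacements(disp$r_um, dt = pre$dt, K = 3, dz = pre$dz)
fit
#> Displacement-distribution fit (cdf), K = 3, n = 30372
#>  component      f D_um2_s
#>      bound 0.4846  0.1191
#>       slow 0.3918  0.9775
#>       fast 0.1236  4.9060
#>   dz = 0.5 um, dt = 0.01 s, logLik = 31941.00
```

The fractions are *observed-displacement* shares: bound molecules never
leave the axial detection slice while fast ones escape quickly, so bound
steps accumulate (0.48) relative to the initial state weights, and the
bound D sits at the localization floor σ²/Δt = 0.1225 µm²/s rather than
the nominal 0.08. The diffusing coefficients recover the generating values
(1.0 and 5.0 µm²/s) within a few percent.

```r
model <- fit_hmm(tracks, dt = pre$dt, K = 3, min_len = 8, seed = 1)
model
#> Diffusion HMM: 3 states, 1172 tracks, 28413 displacements
#>   D (um^2/s): bound=0.1163, slow=0.9898, fast=4.957
#>   initial weights: 0.48, 0.42, 0.0999
#>   transition matrix (per frame):
#>        to
#> from     bound   slow   fast
#>   bound 0.9009 0.0963 0.0028
#>   slow  0.1160 0.8437 0.0403
#>   fast  0.0081 0.1482 0.8437
#>   logL = 85172.11, BIC = -170231.43

eligible <- tracks[ave(tracks$track_id, tracks$track_id, FUN = length) >= 8, ]
segments <- filter_bound(segment_tracks(eligible, model))
angles <- compute_angles(segments)
f180_over_0(angles)
#> f180/0 of diffusing p53-like molecules: 1.32 (n = 9700 angles)
```

The fitted transition matrix reproduces the simulated kinetics, including
the ~10× preference for entering the bound state from slow rather than
fast diffusion (0.116 vs 0.008 per frame). After bound-segment filtering,
the diffusing molecules still show a backward bias (f180/0 > 1): part is
genuine rebinding/confinement near chromatin, part is localization noise
on slow segments — a confounder the anisotropy functions document and that
`anisotropy_vs_distance()` resolves by spatial scale.

```r
map <- density_map(ph$density, ph$mask, ph$pixel_size)
ep <- enrichment_profile(disp[disp$state_true == 1, c("x_um", "y_um")], map)
ep$freq
#> bound-state class frequencies: 0.2 0.17 0.19 0.44  (enrichment score 0.24)
```

Bound molecules fall in the densest chromatin quartile 44% of the time
(uniform exploration would give 25%; the enrichment score is the class-4
minus class-1 frequency).

A full account of the models, assumptions, parameter defaults and
numerical choices is in `vignettes/nuclear-factor-exploration.Rmd`.

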