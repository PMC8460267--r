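---
title: "Methods: quantifying collective cell sheet mechanics with sheetmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying collective cell sheet mechanics with sheetmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetmech)
```

# Scope

`sheetmech` implements the quantification chain used to characterize
collective keratinocyte migration on nanopatterned polyacrylamide hydrogels:

1. **PIV** — velocity/displacement fields from image pairs by windowed
   normalized cross-correlation;
2. **FTTC** — substrate traction recovery from bead displacements on an
   elastic half-space, with Tikhonov regularization;
3. **MSM** — in-plane monolayer stress recovery from tractions by 2D force
   balance with an elastic-sheet compatibility closure;
4. **spatial autocorrelation** — the lateral velocity and average-normal
   stress correlation functions and their threshold-crossing correlation
   lengths;
5. **focal-adhesion dynamics** — segmentation, tracking, lifetime/area/length
   and density;
6. **nanopattern spacing** — k-nearest-neighbour interparticle distances of
   gold nanoparticle arrays;
7. a **synthetic-data generator** producing every input with known ground
   truth, so each stage is validated by parameter recovery.

Everything below is the package's own account of what is computed, which
knobs matter, and where the estimators have known limits.

# Particle image velocimetry

`compute_piv()` tiles the first image into `window_px` squares (default 32 px,
overlap 0.5, so the vector grid step is half a window) and, per window, finds
the displacement maximizing the normalized cross-correlation against the
second image, searching up to half a window in each direction.  The peak is
refined by the standard 3-point Gaussian fit per axis.  Design points:

* The vector grid is placed so every window keeps its full search range
  inside the image; otherwise border vectors are silently biased whenever the
  true displacement points outside the reachable range.
* When the correlation peak is an exact match (coefficient 1 to numerical
  precision), the integer lag is returned unrefined — a noise-free integer
  translation is then recovered exactly.
* Windows with (near-)zero variance are flagged invalid (`NA`), and
  `replace_outliers()` provides local-median validation.
* The search is single-pass: displacements beyond half a window per frame
  are out of range, and displacement *gradients* across a window smear the
  correlation peak.  The induced error has two parts: a deterministic
  low-pass attenuation of wavelengths comparable to the window, and a
  sampling jitter because each window measures the bead- or
  texture-weighted mean of a spatially varying displacement.  Both are
  quantified in the test suite; the practical rule is to keep displacement
  features several windows wide.

Velocities are displacement × pixel size / frame interval, reported in
µm/hr.  Rigid stage drift between a stressed/relaxed bead pair is estimated
by *phase* correlation (unit-normalized cross-power spectrum,
`displacement_from_beads()`): the phase peak locates rigid translation and
is insensitive to smooth elastic deformation, which plain amplitude
correlation would partially absorb into a false drift.

# Traction recovery (FTTC)

The substrate is a linear-elastic half-space (`elastic_substrate()`), Young's
modulus `E` in Pa (the hydrogels span 11–90 kPa; 23 kPa is the default
condition) and Poisson ratio `ν` defaulting to 0.5 because polyacrylamide is
nearly incompressible; the gel is treated as semi-infinite since it is thick
relative to the decay depth of surface displacements.  Per Fourier mode the
surface displacement is `u(k) = G(k) t(k)` with the tangential Green tensor

```
G(k) = 2 (1 + ν) / (E k³) ·
       [ (1−ν) k² + ν k_y²,  −ν k_x k_y ;
         −ν k_x k_y,          (1−ν) k² + ν k_x² ]
```

`forward_boussinesq()` applies it; `fttc()` inverts per mode with Tikhonov
regularization `t(k) = (GᵀG + λ² s₀² I)⁻¹ Gᵀ u(k)`, where `s₀` is the
Green's-function magnitude at the fundamental mode, making `reg_lambda`
dimensionless.  The `k = 0` mode (net force) is suppressed.  Choices that
matter:

* `pad` (default `TRUE`) zero-pads the displacement grid to twice its extent
  before the FFT, suppressing periodic wrap-around for experimental fields
  that decay inside the view.  Synthetic periodic scenes must be inverted
  with `pad = FALSE`: padding a torus field fabricates edge discontinuities
  and is the dominant error if applied there.
* `reg_lambda = "auto"` picks λ at the L-curve corner (`lcurve_lambda()`),
  the point of maximum curvature of the log residual-norm/solution-norm
  curve over a 41-point log-spaced λ grid.  Flat small-λ segments (where the
  curve barely moves and discrete curvature is numerical noise) are excluded
  by a minimum-speed rule before the corner is taken.
* Measured displacement fields carry node-to-node estimation jitter that the
  inverse operator amplifies as `E·k`; `smooth_field()` (Gaussian, σ of one
  grid node) is the recommended pre-filter before inversion of PIV output.

The spectral inverse is exact: a forward–inverse round trip at λ = 0 on the
generating grid agrees to ~1e-14 relative (tested).  Through the full
measurement chain — bead-image rendering at 0.5 beads/µm² (0.2-µm beads,
PSF σ 1 px), 16-px PIV on an 8-µm grid, σ = 1 node smoothing, L-curve λ —
the recovered traction field agrees with ground truth to 10–15 % relative
L2 across seeds (tested at E = 23 kPa, ν = 0.5).

# Monolayer stress microscopy

`msm_solve()` solves the 2D balance `∂σxx/∂x + ∂σxy/∂y = t_x`,
`∂σxy/∂x + ∂σyy/∂y = t_y` for the line stress tensor (N/m), closing the
underdetermined system with the compatibility of a linear plane-stress sheet
of Poisson ratio `sheet_poisson` (the effective modulus cancels).  `t` is
the traction exerted by the substrate on the monolayer — the reaction of
what TFM measures — and the sign flip is applied by default (`flip_sign`).

Two solvers:

* **periodic** (interior-field mode, the default): for views fully inside a
  confluent monolayer, solved spectrally.  The mean stress is unobservable
  from tractions and is fixed to zero (zero-mean gauge, recorded), so only
  stress variations are meaningful — which is all the correlation analysis
  uses.  On scenes whose stress is elastically compatible the recovery is
  exact to machine precision (tested).
* **free/clamped rectangle**: second-order finite-difference collocation —
  balance at interior nodes, `σ·n = 0` (or pinned displacement) at edge
  nodes — yielding a square system whose interior balance holds to machine
  precision.  One-sided second-order edge stencils keep polynomial solutions
  exact, so the 1D strip oracle (uniform `t₀` from a free edge gives
  `σxx = t₀·x`, e.g. 0.01 N/m at 100 µm under 100 Pa) is reproduced to
  ~1e-13 relative.  Only full-rectangle masks are supported; arbitrary
  monolayer outlines are out of scope.

Choosing the closure's Poisson ratio: the recovered `σ̄` is *not* uniformly
insensitive to `sheet_poisson`.  Decomposing tractions into Fourier modes,
shear-type modes (displacement ⟂ wavevector) are recovered independently of
`ν'` to machine precision, but longitudinal modes scale `σ̄` by
`(1 + ν')/(1 + ν_gen)` — a 20 % swing across `ν' ∈ [0.2, 0.5]`.  The often
quoted robustness of MSM to elastic parameters therefore holds only insofar
as the traction field is shear-dominated or the stress statically
determinate; the package documents and tests the analytic behaviour rather
than a blanket insensitivity claim.  The strip oracle is run at
`sheet_poisson = 0`: that 1D stress state is statically determinate (any
`ν'` gives the same stress analytically), and `ν' = 0` avoids the
Poisson-contraction boundary layer a clamped 2D edge would otherwise
introduce at finite resolution.

`principal_decomposition()` gives per-node principal stresses and the major
axis angle in `[0, π)` (flagged undefined for isotropic tensors);
`stress_profile()` gives axis-averaged `σ̄` profiles with inter-peak
distances as a wavelength diagnostic.

# Correlation functions and the 0.01 crossing

`decompose_velocity()` projects each vector onto the migration axis and its
perpendicular and forms the lateral fluctuation `v = lateral − mean(lateral)`
(the symbol conventions around "lateral" in the source literature are
inconsistent; this package always analyses the component perpendicular to
the migration axis, which is the stated physics).  `velocity_correlation()`
computes

```
C(r) = ⟨ v(r') v(r'+r) ⟩ / [ ⟨v(r')²⟩ ⟨v(r'+r)²⟩ ]^(1/2)
```

binned radially with bin width one grid spacing (pairs assigned by rounded
Euclidean separation), so `C(0) = 1`.  All pair sums run over every valid
ordered node pair via FFT cross-correlation and equal the O(n²) brute-force
double loop to floating-point precision (tested).  `stress_correlation()`
applies the same machinery to `δσ̄ = σ̄ − ⟨σ̄⟩`, normalized per bin by pair
count and variance (the raw prefactor `1/(N·var)` of the printed formula
does not normalize per-bin pair counts; this per-bin normalization is the
deliberate, documented choice so that `C(0) = 1`).  A nematic mode is also
provided — descriptor `σ̄·(cos 2θ, sin 2θ)`, angle-doubled so the ±
symmetry of principal axes is respected — because "stress vectors" with a
dot product admits either reading; the scalar mode is the default.

`correlation_length()` returns the first downward crossing of
`threshold = 0.01`, linearly interpolated between bracketing bins; a curve
that never reaches the threshold is right-censored at the maximum
separation (attribute, not an error).

**Finite-window behaviour.**  Subtracting the sample mean removes
covariance `δ ≈ 4π l²/L²` for a Gaussian correlation of scale `l` in an
`L × L` view.  At the deep 0.01 threshold this matters: at `L/l ≈ 27`
(e.g. `l` = 93 µm in a 2.56-mm view) the crossing is biased ~−11 % and
single-realization curves wander by more than ±10 %.  The calibration
studies therefore (i) sample each kernel scale so the view spans ~100
kernel scales (node spacing `l·100/256` on 256² grids), which keeps both
the deficit (≈ 4π/100² ≈ 0.001) and the tail noise well below the
threshold, (ii) average the curves of 10 independent fields
(`average_correlation()`, pair-count weighted), (iii) remove the residual
plateau deficit via the exact pair-sum identity of mean-subtracted fields
(`plateau_correct()`), and (iv) enforce the monotone decay by antitonic
regression before locating the crossing.  Under these conditions the
estimated crossing matches the closed form
`r* = 2·l·√(ln 100) ≈ 4.29·l` within a few percent (tested within 10 %).
The same estimator pipeline is applied to the stress correlation.  The
pipeline's per-condition report, whose routine movies offer far smaller
view-to-scale ratios, uses the raw averaged curve plus the monotone fit
only: there the deficit is r-dependent and a far-tail correction would
overshoot the mid-range bins.

`sheet_speed()` measures front-edge advance (mean over image rows of the
monolayer boundary position, from masks or intensity thresholds) or the
mean axial PIV velocity; both are provided because either reading of
"migration speed" is defensible, and they agree within 10 % on synthetic
movies (tested).  `delta_speed()` reports the mean speed change across a
treatment switch (the acute-perturbation readout).

# Focal adhesions

`segment_adhesions()` subtracts a large-scale background (spectral Gaussian,
scale `background_scale` px), thresholds at `threshold_k` (default 3) robust
noise SDs, labels 4-connected components and keeps those above `min_area`
(default 0.25 µm²).  The reported area is the FWHM footprint — pixels above
half the component's robust peak — which undoes the PSF skirt the detection
threshold necessarily includes; lengths are ellipse-equivalent major axes
from intensity-weighted second moments.  `track_adhesions()` links
detections greedily by nearest neighbour under a distance gate (default
2 µm per frame; adhesions are nearly stationary) with gap closing over one
missed frame; the simple auditable linker is preferred over an opaque one.
Tracks touching the movie's first or last frame are flagged censored and
excluded from `lifetime_summary()` by default, since their observed
lifetimes truncate the true ones.  Note that the *direction* of the bias
from including censored tracks depends on the birth-time structure —
end-truncated long-lived tracks pull the inclusive mean up while late-born
stubs pull it down — so the package asserts unbiasedness of the excluded
mean under an adequate observation window rather than a universal sign.
`contact_area()` segments the largest supra-threshold region after hole
filling and reports adhesion density as count/area.

On the reference synthetic scene (200 adhesions, exponential lifetimes of
mean 14 min discretized to 2-min frames, 100 frames) the chain recovers
100 % of tracks with lifetimes exact to the frame and a censoring-excluded
mean within 2 SEM of 14 min (tested).

# Nanopattern spacing

`knn_spacing()` reports the mean over points of the mean distance to the
`k = 6` nearest neighbours (six is the neighbour count of a triangular
lattice), excluding points within `edge_margin` of the boundary — default
1.5 lattice constants, since border particles lack a full neighbour shell;
the source protocol is silent on edge handling, so the exclusion is
explicit here.  Perfect lattices at 35/50/70 nm are recovered exactly and
10 %-jittered lattices within 3 % over >600 evaluated points (tested
against an all-pairs oracle).  `detect_spots()` provides sub-pixel spot
centroids (local maxima plus centroid refinement) for spot images.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions.

* **Velocity fields** (`field_spec`/`gen_velocity_field`): uniform drift
  plus fluctuations built by convolving white Gaussian noise with an
  isotropic Gaussian kernel of scale `kernel_scale`, rescaled to
  `fluctuation_sd`.  The construction is chosen because its autocorrelation
  has the closed form `exp(−r²/(4·kernel_scale²))`, giving an analytic
  oracle for the crossing estimator.
* **Stress/traction scenes** (`stress_scene_spec`/`gen_equilibrium_scene`):
  sinusoidal modes snapped to the periodic grid.  Elastically *compatible*
  patterns (`compression`, `shear`, built from displacement modes of a
  plane-stress sheet) are what MSM can recover exactly and are the random
  default; direct component patterns (`xx`, `yy`, `xy`, `iso`) serve the
  analytic divergence checks.  Mode amplitudes have fixed magnitude and
  random sign/orientation/phase so every scene carries comparable signal.
  The balancing traction is the exact analytic divergence; the discrete
  balance check (`balance_residual()`) uses the Fourier-collocation
  derivative of the periodic grid, for which the analytic divergence of
  band-limited fields is exact to machine precision (a centred-difference
  residual would be O(h²) by truncation, which is a property of the
  stencil, not of the scene).  An optional raised-cosine (Hann) envelope —
  itself a finite Fourier series, so band-limitedness is preserved exactly
  — localizes the scene inside the view the way traction decays around a
  cell colony.
* **Bead images** (`bead_image_spec`/`gen_bead_pair`): beads at uniform
  positions (count = density × area), rendered as Gaussian spots truncated
  at 4σ; the stressed image displaces the same beads by the bilinearly
  interpolated displacement field; additive Gaussian noise.  Bead density
  and noise are not stated by any protocol and are package defaults
  (0.05/µm² for 1-µm beads; 0.5/µm² with PSF σ 1 px emulating 0.2-µm
  beads in the traction study).
* **Focal-adhesion movies** (`fa_scene_spec`/`gen_fa_movie`): exponential
  lifetimes discretized to frames (only mean lifetimes are reported in the
  source literature, so the memoryless choice is the least-informative
  one), Poisson-process appearances, static elliptical patches (sharp
  footprint, 0.7-px PSF blur) with gamma-distributed areas.  Placement
  keeps a minimum separation (default 4 µm) against adhesions overlapping
  in time within a ±3-frame guard, so a newcomer never appears where
  another just died — otherwise any gap-closing tracker merges them and no
  tracker could be validated.  The censored flag marks tracks touching the
  first or last frame, matching what a tracker can know.
* **Texture movies** (`gen_texture_movie`): a smooth random texture warped
  by the cumulative displacement of a static (frozen-flow) velocity field,
  optionally restricted to an advancing front for sheet-speed tests.

All randomness flows from one integer seed per spec through deterministic
label-derived sub-streams, so identical specs give bit-identical outputs
and sub-generators stay independent.

What the generator does *not* emulate: camera shot noise and optical
sectioning, cell-shape texture statistics, temporally evolving velocity
fields (frozen flow per movie), adhesion maturation/intensity dynamics,
curved or irregular monolayer boundaries.  Passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
statistical structure, not robustness to every feature of real microscopy
data.

# Study sizes

The test suite and the acceptance script run: FTTC round trips on 128²
grids; the bead-image traction study on a 256-µm scene rendered to 704²
pixel images; correlation-length recovery on 256² node fields, 10 seeds per
kernel scale; the focal-adhesion study with 200 tracks over 100 frames at
480² px; and a three-condition migration sweep of 24 positions per
condition at 512² px, 2 frames each.  The sweep programs (short, long,
short) correlation structure with (slow, fast, slow) fronts and checks that
the middle condition reports both the largest correlation length and the
fastest front — the qualitative biphasic signature, end to end from rendered
movies.  Multiple positions are the variance control for the deep-threshold
crossing: a single field of view carries irreducible realization noise in
the C(r) tail that neither more frames of a frozen field nor longer movies
reduce.

# Known limitations

* Single-pass PIV only: no multi-pass or window deformation; displacements
  must stay within half a window and vary smoothly across it.
* Semi-infinite substrate: no finite-thickness correction to the Green
  tensor.
* MSM supports periodic views and full rectangles with free/clamped edges,
  not arbitrary monolayer outlines; absolute stress level in periodic mode
  is a gauge, only variations are meaningful.
* The 0.01-threshold correlation length needs generous fields of view
  (≳50 correlation scales) and realization averaging; single small curves
  scatter strongly, which mirrors the practical variability of the
  measurement.
* The tracker is greedy nearest-neighbour with a 1-frame gap: adequate for
  near-stationary, well-separated adhesions, not for dense motile spots.
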