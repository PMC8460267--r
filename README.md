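# sheetmech

Mechanics of collective cell migration on nanopatterned hydrogels, in R.

Epithelial sheets (for example keratinocyte monolayers closing a wound)
migrate collectively: each cell coordinates its movement and its forces with
its neighbours. On polyacrylamide hydrogels carrying quasi-hexagonal gold
nanoparticle arrays, the lateral spacing of integrin ligands (35/50/70 nm)
tunes this coordination, and the readouts are mechanical: sheet migration
speed, the spatial correlation length of velocity fluctuations, substrate
tractions, the intercellular stress field and its correlation length, and
focal-adhesion turnover. `sheetmech` implements that entire quantification
chain, plus a synthetic-data generator with known ground truth so every
stage is testable by parameter recovery — no experimental recordings are
required to validate it.

## The chain

| Stage | Function(s) | Model / statistic |
|---|---|---|
| Velocity fields | `compute_piv`, `piv_movie` | windowed normalized cross-correlation, 3-point Gaussian sub-pixel peak |
| Substrate displacement | `displacement_from_beads` | PIV on stressed/relaxed bead images, phase-correlation drift removal |
| Traction recovery | `fttc`, `forward_boussinesq`, `lcurve_lambda` | regularized Fourier-transform traction cytometry on an elastic half-space, per-mode Green tensor G(k), Tikhonov `t(k) = (GᵀG + λ²s₀²I)⁻¹Gᵀu(k)`, L-curve λ |
| Monolayer stress | `msm_solve`, `principal_decomposition`, `stress_profile` | monolayer stress microscopy: 2D force balance `div σ = t` closed by a plane-stress elastic sheet; spectral (periodic interior) or finite-difference (free/clamped rectangle) solves |
| Correlation lengths | `decompose_velocity`, `velocity_correlation`, `stress_correlation`, `correlation_length` | `C(r) = ⟨v(r')v(r'+r)⟩ / [⟨v(r')²⟩⟨v(r'+r)²⟩]^{1/2}`, radially binned; length = first crossing of C = 0.01 |
| Sheet speed | `sheet_speed`, `delta_speed` | front-edge advance or mean axial PIV velocity; speed change across a treatment switch |
| Focal adhesions | `segment_adhesions`, `track_adhesions`, `lifetime_summary`, `contact_area` | background-subtracted segmentation, greedy gated linking, censored-aware lifetimes, density = count/area |
| Nanopattern order | `knn_spacing`, `detect_spots` | mean distance to the k = 6 nearest neighbours, edge-excluded |
| Synthetic data | `gen_velocity_field`, `gen_equilibrium_scene`, `gen_bead_pair`, `gen_fa_movie`, `gen_texture_movie`, `gen_hex_pattern` | fields with closed-form autocorrelation, balanced stress/traction scenes, bead pairs, adhesion movies, jittered lattices |
| Orchestration | `pipeline_config`, `run_pipeline`, `pipeline_report` | multi-condition simulate → analyze runs with checksummed manifests |

## Worked example

Generate a monolayer-like velocity field whose fluctuations have a known
correlation scale, then recover that scale with the package's own
estimator:

```r
library(sheetmech)

spec <- field_spec(grid_shape = 256, node_spacing = 10, drift_speed = 20,
                   fluctuation_sd = 3, kernel_scale = 47, seed = 1)
field <- gen_velocity_field(spec)
field
#> <vector_field> 256 x 256 nodes, spacing 10 um, units um/hr
#>   |v|: mean 20.39, max 30.67; invalid nodes: 0

dec <- decompose_velocity(field, migration_direction = c(1, 0))
dec
#> <decomposed_field> 256 x 256 nodes (um/hr)
#>   mean axial 20.17, mean lateral -0.04519, fluctuation sd 3

curves <- lapply(1:10, function(s)
  velocity_correlation(decompose_velocity(
    gen_velocity_field(field_spec(256, 10, drift_speed = 20,
                                  fluctuation_sd = 3, kernel_scale = 47,
                                  seed = s)), c(1, 0))))
plateau_correct(average_correlation(curves))
#> <correlation_curve> 362 bins, r in [0, 3.61e+03] um
#>   correlation length (C = 0.01 crossing): 191.6 um
```

The sheet drifts at ~20 µm/hr with 3 µm/hr lateral fluctuations; the
estimated C(r) = 0.01 crossing, 191.6 µm, recovers the closed-form value
`2 · 47 · sqrt(log(100)) ≈ 201.7` µm of the generating kernel within 5 %.
The same estimator applied to kernel scale 93 µm yields ~400 µm — the
coordination range of a well-coupled keratinocyte sheet, some 20 cell
diameters.

Nanopattern spacing from a jittered quasi-hexagonal array:

```r
pat <- gen_hex_pattern(spacing = 50, jitter_sd = 5, n_points = 900, seed = 1)
knn_spacing(pat, k = 6, edge_margin = 75)
#> <spacing_summary> k = 6, n = 720 points (edge margin 75 nm)
#>   mean spacing 50.46 nm, sd 2.073 nm
```

See `vignette("sheetmech-methods")` for the models, parameter meanings,
numerical choices and known limitations, and `inst/scripts/sheetmech-pipeline.R`
for a command-line entry point to multi-condition pipeline runs.

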