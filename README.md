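# sphereglide

Quantitative analysis of cytoskeletal gliding assays confined to the inner
surface of spherical giant unilamellar vesicles (GUVs). Actin filaments
propelled by membrane-anchored motors on a sphere of radius R ≈ 18 um
self-organize into a small taxonomy of polar patterns — streams, vortices,
bands, partially and globally jammed states — whose quantification requires
working on the curved surface: projecting voxel stacks to equirectangular
maps, measuring great-circle kinematics, and doing topological bookkeeping
of the defects that the Poincaré–Hopf theorem forces on any fully covered
sphere (total charge +2).

The package is aimed at experimenters and modellers analyzing spherical
surface microscopy of active filament systems, and provides:

* **Geometry** — colatitude/azimuth conventions, the re-projection maps
  r = R(cosφ sinθ, sinφ sinθ, cosθ) (equirectangular) and
  (x, y, ±√(R² − x² − y²)) (confocal), and the arc-length speed
  v = (R/Δt)·cos⁻¹(r_{i+1}·r_i / R²), evaluated in a numerically stable
  atan2 form that resolves nanometre steps on an 18 um sphere.
* **Projection** — algebraic (Coope) least-squares sphere fitting from
  voxel stacks; equirectangular, hemisphere and z maximum projections;
  normalized latitude intensity profiles; area-weighted coverage.
* **Dynamics** — track ingestion from planar annotations, instantaneous
  arc-length speeds (nm/s), time-averaged angular MSDs
  ⟨(θ(t+τ)−θ(t))²⟩ and ⟨(φ(t+τ)−φ(t))²⟩ with seam-free azimuth handling
  and log–log scaling-exponent fits (slope 2 ballistic, 1 diffusive,
  saturation at long lags), a deterministic patch cross-correlation
  feature tracker, and time-averaged surface flow fields.
* **Defects** — exact half-integer charge accounting, Poincaré–Hopf
  validation, the six pair angles θ_ij of four-defect states, and
  tetrahedral (⟨θ_ij⟩ = 109.5°) versus planar (120°) configuration
  classification over time.
* **Patterns** — the five-pattern classifier with auditable feature
  vectors, plus density criteria: surface density ρ from encapsulated
  concentration, packing fraction φ = ρLw, and the Onsager threshold
  ρ\* = 3π/(2L²) for passive hard rods.
* **Synthetic scenes** — seeded kinematic generators (circulating streams,
  vortices, equator-peaked bands, diffusing near-tetrahedral jammed
  defects) rendered to equirectangular maps and voxel stacks with ground
  truth attached, used throughout the test suite.

## Worked example

A vortex circulating at 45 nm/s at colatitude 60° on an 18 um vesicle,
generated, rendered and pushed through the analysis pipeline:

```r
library(sphereglide)

sc <- scene_spec(dt_s = 60, n_frames = 10, seed = 42, structures = list(
  structure_spec("vortex", theta0 = pi/3, speed_nm_s = 45)))

tr <- make_structure_trajectory(sc$structures[[1]], sc)
sp <- instantaneous_speeds(tr)
round(mean_speed(sp), 2)
#>  mean    sd
#> 44.92  0.69

round(as.numeric(msd_scaling_exponent(angular_msd(tr), "phi")), 3)
#> [1] 2.001

maps <- render_scene(sc, n_theta = 90, n_phi = 180)
classify_pattern(maps, structure_speeds = sp$speed_nm_s)
#> pattern: vortex (coverage 0.151, peak theta 59.0 deg, ridge occupancy 1.00)
```

The recovered mean speed (44.92 ± 0.69 nm/s) matches the prescribed
45 nm/s up to the default angular jitter; the azimuthal MSD exponent 2.001
identifies ballistic circulation; and the classifier reads the rendered
movie as a vortex from its closed constant-latitude ridge at partial
coverage (15% of the sphere, peak at 59°).

Defect bookkeeping on a generated jammed state, and the density criteria:

```r
jam <- make_jammed_scene(scene_spec(dt_s = 60, n_frames = 30, seed = 42))
round(mean_pair_angle(jam$configurations[[1]]), 1)
#> [1] 109.5                      # tetrahedral initialization
validate_poincare_hopf(jam$configurations[[1]])$pass
#> [1] TRUE                       # four +1/2 defects sum to +2

round(onsager_critical_density(0.55), 1)
#> [1] 15.6                       # filaments/um^2, passive transition
round(surface_density(density_params(300)), 1)
#> [1] 5.3                        # filaments/um^2 at 300 nM — well below it
```

Observed densities sitting below ρ\* is the quantitative statement that the
patterns are activity-induced rather than a passive liquid-crystal
transition.

A full artifact-producing run (maps TIFF, tracks CSV, defect JSON, speed /
MSD / pair-angle / classification tables with provenance headers):

```r
run_pipeline(list(seed = 1, outdir = "out", scene_kind = "jammed"))
```

See `vignettes/spherical-gliding-analysis.Rmd` for the models, parameter
choices and limitations.

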