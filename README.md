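# splanchnirs

Finite-element simulation of continuous-wave near-infrared light transport
through a parametric model of the infant abdomen, for designing NIRS sensors
that monitor splanchnic (intestinal) oxygenation — a candidate early marker
of necrotizing enterocolitis in infants.

A NIRS sensor is a light source and detectors on the skin. The key design
variable is the source–detector distance (SDD): longer SDDs sample deeper
tissue but collect exponentially less light. `splanchnirs` quantifies that
trade-off end to end:

* **Geometry** — labeled tetrahedral meshes of a layered abdomen (0.008 cm
  epidermis, homogeneous adipose layer, tilted ellipsoidal intestinal region,
  optional SMA/SMV vessels) on graded tensor grids, plus phantom and
  validation blocks; Gmsh MSH 2.2 and legacy VTK I/O.
* **Optics** — per-tissue absorption and reduced scattering at 750 nm, with
  blood absorption from the Beer–Lambert law,
  μa = [Hb](ε_oxy·SO₂ + ε_deoxy·(1 − SO₂)), and the derived diffusion
  constants D = 1/(3(μa + μs′)), ℓtr = 1/μs′,
  zb = 2ℓtr(1 + Reff)/(3(1 − Reff)).
* **Solver** — P1 finite elements for the CW photon diffusion equation
  −∇·D∇φ + μa φ = S with the partial-flux (Robin) condition on every
  air–tissue facet and an isotropic point source buried one transport mean
  free path below the entry point; sparse supernodal Cholesky factorization
  shared across sources. Exact semi-analytic half-space and N-layer Hankel
  solutions ship as validation oracles.
* **Analysis** — modified Beer–Lambert recovery
  Δμa\* = −ln(φ_P/φ₀)/L(SDD) and per-layer sensitivities
  S_i = Δμa\*_i/Δμa_i from baseline + perturbed solves.
* **Noise & CNR** — a synthetic shot-noise-with-floor calibration table, the
  calibration-by-interpolation lookup, and
  CNR = |φ_P − φ₀|/√(var(φ_P) + var(φ₀)) optimized over SDD, acquisition
  rate and adipose thickness.

## Worked example

A coarse desk-scale run (half a minute; the studies in `scripts/` use finer
meshes):

```r
library(splanchnirs)

mesh <- build_abdomen(resolution = 0.5)   # default: adipose 2.4 cm
mesh
#> Labeled tetrahedral mesh (cm)
#>   nodes: 25432, cells: 137214, boundary facets: 9900
#>   adipose      3113.007 cm^3
#>   epidermis       3.200 cm^3
#>   intestine     161.486 cm^3
#>   SMA             0.571 cm^3
#>   SMV             2.239 cm^3

lay <- place_sensor(mesh, "vertical", sdds = c(1, 2, 3, 4.5, 6))
sc  <- run_sensitivity(mesh, lay)         # 1 baseline + 3 perturbed solves
sc
#> Layer-sensitivity curve
#>   orientation vertical:
#>  sdd epidermis adipose intestine
#>  1.0      0.3%   69.2%      0.0%
#>  2.0      0.2%   71.6%      0.0%
#>  3.0      0.1%   74.1%      0.1%
#>  4.5      0.1%   74.7%      0.2%
#>  6.0      0.0%   74.4%      0.3%

cnr_curve(sc, noise_model(), rate = 0.1)
#> CNR curve (vertical, 0.1 Hz, adipose 2.4 cm)
#>  sdd    cnr
#>  1.0 0.2915
#>  2.0 0.8333
#>  3.0 1.2220
#>  4.5 1.0840
#>  6.0 0.5452
#> optimal SDD: 3 cm

blood_absorption(0.98)   # arterial mua at 750 nm, [Hb] = 14.1 g/dL
#> [1] 2.696703
blood_absorption(0.75)   # venous
#> [1] 3.723877
```

Reading the output: each sensitivity is the fraction of an imposed
absorption change (epidermis 1.2→1.5, adipose 0.05→0.08, intestine
0.21→0.24 cm⁻¹) that the modified Beer–Lambert analysis recovers at that
SDD. Adipose dominates at all distances on this flat layered geometry;
intestinal sensitivity grows with SDD and the CNR — contrast from the
intestinal perturbation against the measurement noise — peaks between 3 and
4 cm before the signal decay wins. On the default finer meshes the CNR
optimum sits at 3.5–4 cm and the CNR at 4 cm and 0.1 Hz is ≈ 1. Note that
the sensitivity *magnitudes* for deep layers are specific to the flat
parametric surrogate; see the methods vignette
(`vignettes/methods.Rmd`) for what transfers to curved, CT-derived anatomy
and what does not.

The full study — five adipose thicknesses × two sensor orientations × five
acquisition rates, with tidy CSV/JSON outputs — is one call:

```r
run_full_study(experiment_config(), out_dir = "study-out")
```

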