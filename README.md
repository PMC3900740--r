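# diffmap2d

Quantitative analysis of ion-induced conformational titrations in
**electron crystallography of 2D crystals**, built around the archetypal
case of a membrane Na⁺/H⁺ antiporter (an MjNhaP1-like dimer) switching
between an apo/proton-bound and a sodium-bound state.

In such an experiment each condition (a sodium concentration at a given pH)
yields merged (h,k) amplitude/phase lists from several crystal lattices.
Projection maps are synthesized at ~6 Å, maps of different conditions are
placed on a common unit cell and subtracted, and paired positive/negative
difference peaks reveal helix movements. The strength of each peak set is
quantified by counting contour lines (peak-to-trough) at an **absolute**
contour step of 1.5 σ of a *half-split control* difference map — two random
halves of same-condition data subtracted from each other — which shows a
noise background of about ±2 contour levels (~3 σ). Background-corrected
counts H(c) rise with the Na⁺ concentration c as a single-site saturation
isotherm,

    H(c) = h_max · c / (c + K_D,app),      θ(c) = c / (c + K_D,app),

and the fitted apparent dissociation constant is pH-dependent because Na⁺
and H⁺ compete for a shared site:

    K_D,app(pH) = K_D^Na · (1 + [H⁺] / K_H).

The study conditions encoded in the package defaults: K_D,app ≈ 30 mM at
pH 8 and ≈ 280 mM at pH 4 (≈10-fold weaker acid-side binding), a ~2 Å
lateral shift of the 5c/12e half-helix pair, and a unit cell drifting from
81.2 × 104.2 Å to 80.6 × 107.9 Å at saturation.

Because no public reflection data are deposited for this system, the
package includes a first-class **synthetic crystal generator**: a 15-rod
Gaussian model of the 13-TMH protomer in a p2 dimer, a two-state
conformational difference, occupancy mixing by the competition isotherm,
and per-lattice noise with random phase origins and scale factors. Every
stage of the pipeline is therefore testable against known ground truth.

## What is in the package

| Stage | Functions |
|---|---|
| Synthetic crystals | `default_models()`, `occupancy()`, `mixture_structure_factors()`, `simulate_condition()`, `simulate_lattice()` |
| Merging | `align_phase_origin()`, `standardize_origin_p2()`, `scale_amplitudes()`, `merge_lattices()` |
| Map synthesis | `synthesize_map()`, `analyze_map()`, `rasterize_model()` |
| Difference analysis | `resample_common_cell()`, `subtract_maps()`, `half_split_control()`, `count_contours()`, `background_correct()`, `estimate_displacement()` |
| Affinity fitting | `fit_titration()` (classed model object with `print`/`summary`/`coef`/`predict`/`plot`/`residuals`), `kd_ratio()`, `consistency_report()` |
| Orchestration & I/O | `simulate_titration()`, `run_reproduction()`, reflection tables, minimal CCP4/MRC 2D maps, counts CSV |

## Worked example

Simulate and analyse one pH-8 titration (six lattices per condition), then
fit the apparent dissociation constant of the strongest difference-peak
region:

```r
library(diffmap2d)

tc <- simulate_titration(pH = 8,
                         concentrations = c(0, 20, 50, 100, 250, 500),
                         seed = 42)
subset(as.data.frame(tc), region == "set1_5c12e")
#>    na_mM     region positive negative peak_to_trough corrected
#> 1      0 set1_5c12e        1        1              2         0
#> 6     20 set1_5c12e        9        9             18        16
#> 11    50 set1_5c12e       14       14             28        26
#> 16   100 set1_5c12e       16       17             33        31
#> 21   250 set1_5c12e       19       20             39        37
#> 26   500 set1_5c12e       20       21             41        39
attr(tc, "background_levels")
#> [1] 2

fit <- fit_titration(tc, "set1_5c12e", seed = 1)
fit
#> Saturation-isotherm fit, region set1_5c12e (pH 8)
#>   K_D,app = 31.26 mM  (68% CI 30.21 - 32.52, 496 bootstrap)
#>   h_max = 41.4 levels, RSS = 0.6327
```

The counts rise along the binding isotherm and the fit recovers the 30 mM
ground truth within its bootstrap interval; the half-split control shows
the expected ±2-level background. The same maps give the helix movement:

```r
m <- default_models()
apo_map   <- synthesize_map(structure_factors(m$apo, d_min = 6))
bound_map <- resample_common_cell(
  synthesize_map(structure_factors(m$bound, d_min = 6)), apo_map$cell)
estimate_displacement(apo_map, bound_map, default_regions()$set1_5c12e)
#> [1] 2.015405
```

i.e. the designed 2 Å lateral movement of the 5c/12e pair, recovered from
the 6 Å maps alone. `run_reproduction()` executes the whole study (both pH
series, all regional fits, the acid/base fold change and the displacement)
and writes maps, counts, fits and a summary JSON to an output directory.

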