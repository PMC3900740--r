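---
title: "Methods: projection difference maps and Na+ titrations for 2D crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projection difference maps and Na+ titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffmap2d)
```

# The measurement this package models

Electron crystallography of 2D membrane-protein crystals measures, per
crystal lattice, a list of Fourier amplitudes and phases F(h,k) of the
projected density. For a Na⁺/H⁺ antiporter dimer the experiment of interest
is a *titration*: crystals grown without sodium are incubated at a series of
Na⁺ concentrations and fixed pH, several lattices per condition are merged,
and projection maps of each condition are subtracted from the zero-sodium
reference. Moving helices produce paired positive/negative difference
peaks; the number of contour lines between the deepest trough and the
highest peak of each pair, at a fixed absolute contour step, is a
semi-quantitative measure of how much of the lattice has switched state.
Plotted against concentration these counts trace a binding isotherm, whose
midpoint is the apparent Na⁺ dissociation constant at that pH.

The package implements this pipeline end to end, plus a synthetic crystal
generator that supplies ground-truth data, so parameter recovery can be
verified rather than assumed.

# The two-state crystal model

## Density model

A protomer is a set of Gaussian rods, one per transmembrane helix seen in
projection (helices 5 and 12 are discontinuous and contribute two half-rods
each: 5c/5e, 12c/12e — 15 rods for 13 helices). A rod has a center (Å, in
the Cartesian cell frame), a 2×2 covariance (isotropic for a straight
helix, elongated for a tilted one), a mass, and an order parameter in
[0, 1] scaling its amplitude. The dimer is generated by a twofold rotation
about the origin (plane group p2 in projection; p1 is available for
asymmetric work). Analytic structure factors of this model are exact —
each rod contributes `m · exp(-2π² sᵀΣs) · exp(-2πi s·c)` at reciprocal
vector s(h,k) — and the raster route (`rasterize_model()` + `analyze_map()`)
agrees with them to numerical precision, which the tests exploit as an
independent oracle.

The default layout places the rods so that every inter-helix spacing
exceeds ~7.5 Å in both states: at the 6 Å cutoff each helix then resolves
as a discrete peak, as in the experimental projection map of the dimer. The
layout honours the topology that the difference analysis needs (the 5c/12e
pair pointing at helices 10/13, TMH6 at the bundle edge, the 4/11/12c group
left of the bundle, an interface region near TMH10) but is otherwise a free
design: no atomic coordinates exist for the projection, so positions are
package constants, not fitted quantities.

## The conformational difference

The sodium-bound state differs from the apo state by:

* a rigid **2 Å lateral shift** of the 5c/12e pair toward helices 10/13
  (`shift_5c12e`, Å — the headline movement);
* **TMH6 straightening**: tilted in the apo state, modelled as a 2:1
  axis-ratio elongation *and* a ~1 Å projected-centroid offset along the
  tilt azimuth (a tilted rod's projection is both smeared and displaced);
  isotropic and recentered when bound;
* **TMH13 tilting**: the converse, isotropic → 2:1 elongation with the
  axis pointing toward TMH10;
* **ordering of 5e**: order 0.8 → 1.0, a single unpaired positive peak
  (density gained without a matching loss).

The 5e order gain is deliberately modest: with a large gain its single
positive peak would dominate the whole difference map, whereas the
experimental maps show the 5c/12e pair as the strongest feature. The
default magnitudes were balanced once so the difference-pair strengths
rank set 1 > set 3 > set 2, all well above the two remaining declared
regions, and were then frozen.

The unit cell relaxes linearly with occupancy from 81.2 × 104.2 Å (apo) to
80.6 × 107.9 Å (bound); γ is not reported for this crystal form and
defaults to 90°. Bound-state rods keep the fractional coordinates of their
apo positions (the protein drifts with the lattice), so after maps are
placed back into a common cell the *only* residual differences are the
designed conformational changes.

## Occupancy and pH

The fraction of molecules in the bound state follows a single-site
isotherm with proton competition,
θ(c) = c / (c + K_app), K_app = K_D^Na · (1 + 10^(pK − pH)).
`calibrate_binding()` solves K_D^Na and pK exactly from the two measured
apparent constants (30 mM at pH 8, 280 mM at pH 4), giving
K_D^Na = 29.98 mM and pK = 4.92; these are the generator defaults. Mixing
is linear: per Miller index the condition structure factors are
(1−θ)F_apo + θF_bound, which is identical to pointwise mixing of the state
densities on a common fractional grid. Non-substrate ions (`ion = "Mg2+"`
or `"K+"`) leave the crystal in the apo state at all concentrations. The
fully-active intermediate-pH regime, where molecules are trapped in a
continuum of orientations, is approximated by a `disorder` parameter that
attenuates the conformational contrast rather than by a third state — the
distribution of intermediate conformations is unknown, and a contrast
scaling reproduces its one observable consequence (weaker, more diffuse
difference peaks).

## Noise

Each simulated lattice receives a random fractional phase origin, a
log-normal amplitude scale (s.d. 0.1), and independent complex Gaussian
noise per reflection with standard deviation

    sd(h,k) = sqrt( noise_sigma² + (noise_frac · |F(h,k)|)² )

per real/imaginary component. The fractional term reflects how errors
actually enter merged image data — image-to-image scaling, defocus and
B-factor differences all perturb amplitudes in proportion to their size —
and it matters here: it places part of the difference-map noise on the
density peaks themselves, which is what makes the zero-sodium control
counts an appropriate background estimate for the condition maps.

Calibration of the two scales (defaults 3.5 and 0.035 in the model's
amplitude units) is anchored by two requirements, in order of priority:
six-lattice half-split controls must show the experimental background of
about ±2 contour levels at a 1.5 σ step (this anchor is scale-free and
holds across a wide noise range), and the full pipeline must recover the
generator's apparent dissociation constants without material bias (median
within ±25% over replicate titrations — the package's own acceptance
standard). The second requirement sets the absolute scale. A consequence,
stated openly: saturating raw counts run near 30 levels rather than the
~15 of the published maps. The published count ranges themselves (7–9
levels at 20 mM rising to 15 at 500 mM at pH 8) are not jointly consistent
with a single hyperbola through the corrected values, so the package does
not attempt to match them exactly; the dynamic range is spent on unbiased
parameter recovery instead.

# The analysis pipeline

## Merging and origins

Within a condition, every lattice is phase-origin-aligned to the first
(`align_phase_origin()`: a coarse 240 × 240 translation scan evaluated in
one FFT as a phase cross-correlation, followed by Nelder–Mead refinement of
the amplitude-weighted mean absolute wrapped phase difference; ties break
toward the smallest shift vector), scaled by least squares
(`scale_amplitudes()`, closed form), and vector-averaged per Miller index.
The merge report carries per-lattice scale factors, offsets and the
amplitude-weighted phase residual against the merged set.

Merged condition sets are then placed on the crystallographic origin by
`standardize_origin_p2()`: the p2 constraint (all phases 0/180° at a
twofold axis) is enforced by minimizing the amplitude²-weighted deviation
of doubled phases from zero, again via one FFT plus refinement, and the
four equivalent origins (half-cell shifts) are disambiguated against a
reference. Aligning conditions through the symmetry constraint rather than
by cross-map phase matching matters because a genuine conformational
difference would otherwise pull the fitted translation and attenuate the
very signal being measured. In the packaged pipeline the zero-sodium
reference is disambiguated against the apo model — the analogue of
assigning helices on a real map before drawing peak regions.

## Difference maps, controls and counts

Maps are synthesized by inverse Fourier synthesis with Friedel completion,
normalized by the cell area, on a 128 × 160 grid (~0.65 Å/pixel, ≥4×
oversampling of 6 Å data; grids below the Nyquist box are refused). The
(0,0) term is not carried, so maps are mean-zero; mean and σ are stored
with the map and σ-scaling is applied only at contouring time. Before
subtraction the condition map is resampled onto the reference cell by
periodic bilinear interpolation in fractional coordinates (cells must
agree within 10% per axis).

The half-split control divides one condition's lattices randomly into two
near-equal halves, merges and subtracts them, and fixes two absolute
quantities for the whole analysis: the contour step (1.5 × σ of the control
map, with a tiny configured floor of 1e-9 for noise-free input) and the
background level (the map-wide maximum contour count). Contour counts are
floors — a contour line at level n exists only if the density reaches
n·step — and the peak-to-trough count of a region is the sum of its
positive and negative level counts. Background correction subtracts, per
region, the counts observed in the same region of the zero-sodium control
map, floored at zero, and the zero-concentration point enters the titration
as exactly zero by construction.

Two properties of this protocol are worth knowing. First, the control
halves contain half the data, so the control map is √2 noisier than the
condition differences; its counts therefore slightly over-correct. Second,
floors discard fractional levels. Both push fitted dissociation constants
upward, by a few percent at pH 8 and 10–20% at pH 4, where the prescribed
concentration ladder only reaches θ ≈ 0.78. This residual bias is inherent
to the counting protocol (it is what the protocol would do to real data of
this geometry), is largest for the weakest peak set, and stays within the
package's ±25% recovery tolerance; it is why the acceptance checks compare
medians over many replicates rather than single fits.

## Displacement estimation

`estimate_displacement()` reports the distance between intensity-weighted
centroids of a region's dominant peak in two state maps. The dominant peak
is located in the first map, matched in the second by the strongest density
within 6 Å (safely below the ~7.5 Å inter-helix spacing but above the
largest expected movement), and each centroid is computed from density
above half the peak height inside a 3 Å window around the peak. The local
window is essential: a fixed region-wide centroid clips a shifted peak
against the region boundary and attenuates a 2 Å movement to under half its
size, while windows much wider than one rod admit neighbouring helix tails.
With the 3 Å default the estimator is accurate to better than 10% for
shifts of 1–4 Å on noiseless maps, measured against the generator's ground
truth. Displacements are estimated from the two state maps, not from the
difference map, mirroring how such movements are read off in practice by
inspecting the corresponding peaks in the projection maps.

## Isotherm fitting

`fit_titration()` fits H(c) = h_max·c/(c + K_D) to the background-corrected
counts of one region by least squares. The linear parameter h_max is
profiled out analytically, leaving a 1-D minimization over log K_D on
[max(c)/1000, 1000·max(c)] (`stats::optimize`); a solution at the interval
boundary marks the constant as unidentified. Integer counts are fitted
directly — the quantization error lands in the residuals — and a Hill
coefficient is exposed but fixed at 1 by default (single site). Uncertainty
comes from a seeded nonparametric bootstrap over titration points (500
replicates by default; resamples without at least two distinct non-zero
concentrations and a non-zero count are dropped); the 16–84% quantiles give
the interval, and intervals spanning more than a decade are flagged as
wide. `kd_ratio()` forms the acid/base fold change with an interval from
paired bootstrap replicates, and `consistency_report()` flags regional
spreads beyond 2-fold — the conformational response is one global
transition, so the three peak sets should agree.

Fitting each region separately (with the consistency report as the
cross-check) was chosen over pooling counts across regions: the regions
have different maximal responses, and pooling would let the strongest set
dominate the residuals.

# Scope of the simulation, and what passing tests do not show

The generator emulates merged reflection data: occupancy mixing,
lattice-to-lattice noise, random phase origins and scales, and the cell
drift. It does **not** simulate micrographs or their pathologies — no CTF,
no lattice bending/unbending, no resolution-dependent figure of merit, no
tilted-specimen geometry, and no 3D information. Plane groups beyond
p2/p1 (e.g. glide-containing pgg) are not implemented. Consequently,
parameter recovery here demonstrates that the *analysis pipeline* is
unbiased and correctly calibrated under a faithful statistical model of
merged 2D data; it cannot certify image-processing steps upstream of the
reflection lists, nor the behaviour of the contour-count protocol under
systematic errors (magnification anisotropy, beam-induced motion) that the
noise model does not contain.

Other numerical choices, briefly: reflection lists live on one Friedel
hemisphere (h > 0, or h = 0 and k > 0) with the (0,0) term excluded;
amplitudes are non-negative and phases stored modulo 360°; all stochastic
operations take explicit integer seeds and restore the caller's RNG state;
seeds derived inside the pipeline stay below 2³¹. Degenerate inputs fail
loudly rather than silently: fewer than three common reflections for
alignment, all-zero amplitudes for scaling, incompatible cells for merging
or resampling, empty region masks, all-zero corrected counts, and maps
below the Nyquist limit all raise errors.

# Default parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `d_min` | 6 | Å | resolution of the experimental maps |
| grid | 128 × 160 | pixels | ≥4× oversampling of 6 Å data |
| `shift_5c12e` | 2 | Å | measured helix-pair movement |
| rod σ | 3 | Å | helices resolve as discrete peaks at 6 Å |
| rod mass | 100 | arbitrary | equal weights; sets the amplitude scale |
| cell apo → bound | 81.2×104.2 → 80.6×107.9 | Å | measured drift |
| `kd_na`, `pk` | 29.98, 4.92 | mM, – | solve K_app = 30 mM (pH 8), 280 mM (pH 4) |
| `n_lattices` | 6 | – | "at least six lattices" per condition |
| `noise_sigma`, `noise_frac` | 3.5, 0.035 | amp units, – | ±2-level control background; unbiased K_D recovery |
| contour step | 1.5 σ of control | absolute | the plotting convention of the study |
| bootstrap | 500, seeded | – | point-resampling uncertainty |
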