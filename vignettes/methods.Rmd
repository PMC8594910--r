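---
title: "Volume-conductor modelling and phosphene-threshold simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor modelling and phosphene-threshold simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package models

Transcranial alternating-current stimulation (tACS) drives weak currents
(tens to hundreds of microamperes) through two scalp electrodes. Because the
resulting current density cannot be measured inside the intact eye or brain,
it is estimated with volume-conductor models — and phosphene thresholds
(PTs), the lowest stimulation amplitude at which a subject reliably reports
flickering light percepts, serve as a functional surrogate against which
such models can be evaluated: montages that deliver more current to the
retina should elicit phosphenes at lower amplitudes.

`phosfem` implements that evaluation loop end to end at desk scale:

1. synthetic voxel phantoms (layered spherical head, compartmental eyes,
   cylindrical torso) with 10/20-style electrode montages;
2. a quasi-static finite-element forward solver with two current-injection
   models;
3. closed-form layered-sphere potentials as solver ground truth;
4. region-of-interest summaries of the current-density field, including
   retinal topographic maps;
5. a simulator of the three-step phosphene-threshold staircase protocol
   over synthetic observer cohorts;
6. the statistical battery linking simulated densities to thresholds.

# Forward model

## Physics and discretization

At stimulation frequencies of a few tens of hertz the quasi-static
approximation applies: the potential solves `div(sigma grad phi) = 0` in the
conducting domain with insulating (zero Neumann) boundaries except at the
electrodes, and the current density is `J = -sigma grad phi` (reported in
mA/m^2). Tissue conductivities are isotropic per compartment; the two
shipped presets (`conductivity_preset()`) correspond to the two modelling
traditions the pipeline compares: a coarse "brain model" (homogeneous eye,
0.4 S/m, complete electrode model) and a detailed "retina model" (vitreous
1.55, lens 0.32, aqueous 1.8, retina 0.7, sclera 0.56, cornea 0.5, optic
nerve 0.03 S/m, plus muscle and fat, with point-load Neumann injection).

Voxels are meshed one-to-one as trilinear 8-node hexahedra (2x2x2 Gauss
quadrature). For cubic voxels the element stiffness is `sigma * h * K_ref`
with a single reference matrix, so assembly is a vectorized scatter of 64
entries per conducting voxel into a sparse symmetric positive semi-definite
matrix with zero row sums (the constant potential is the nullspace of the
pure-Neumann operator).

## Current injection

* **Neumann mode** (`build_rhs_neumann()`): the injected current is divided
  equally across the outer nodes of each electrode's electrolyte layer
  (+I/n on the source patch, -I/n on the sink patch). Default electrolyte:
  4 mm at 1.4 S/m.
* **Complete electrode model** (`apply_complete_electrode()`): each
  electrode gets one floating potential unknown `U_e` coupled to its
  contact nodes through a surface impedance `z` (ohm m^2), with the total
  electrode current constrained to +/-I. The configured lumped impedance
  `R` (default 10 kOhm, the impedance ceiling used in practice) is converted
  as `z = R * A_patch`, so the lumped resistance of the whole contact equals
  `R` regardless of patch size. Default electrolyte: 5 mm at 1.5 S/m.
  In the `z -> 0` limit the contact becomes an equipotential (Dirichlet
  pair); at large `z` the interior field is fixed while the contact drop
  grows linearly — both limits are regression-tested.

## Solver

Preconditioned conjugate gradients with a Jacobi preconditioner, relative
residual tolerance 1e-8, at most 10^4 iterations. The constant nullspace is
projected out of the residual every iteration; the returned potential is
gauged to zero mean (a pinned-node gauge is available; the gauge provably
does not affect `J`, and a test asserts it). Load compatibility (zero total
injected current) and source/sink connectivity are checked before the
solve. `check_conservation()` evaluates fluxes in the discretely conserved
sense — the stiffness contributions of the enclosed elements applied to the
solution and summed over interface nodes — so a closed surface separating
the electrodes recovers the injected current to solver precision.

# Phantoms

`build_layered_head()` voxelizes concentric spheres on a grid symmetric
about the origin; a voxel belongs to the innermost shell containing its
center. The default head (`default_head_phantom()`) has outer radii 92
(scalp), 86 (skull), 80 (CSF) and 76 mm (brain; the detailed stack splits
it into gray matter to 64 mm and white matter below). The 4 mm CSF shell is
at the upper end of the anatomical range so that the default head remains
voxelizable at the coarse 2-4 mm desk resolutions; 1 mm grids are supported
when more fidelity is wanted.

Eyes (`embed_eyes()`) are 12 mm spheres centered 75 mm from the head
center, at 25 degrees lateral azimuth and 15 degrees *below* the 10/20
equator — Fp2 then sits on the "forehead" above the orbit and the
suborbital position below it, as on a real head (interpupillary distance
61 mm). The detailed mode builds: an outer element layer split into cornea
(a 40-degree cap about the optic axis), retina (the posterior semi-shell
behind the equatorial plane normal to the optic axis) and sclera; a lens
and an aqueous gap in the anterior interior; vitreous elsewhere; an optic
nerve cylinder (2 mm radius) from the posterior pole toward the head
center; and two kinds of orbital tissue: skull voxels near the globe are
relabeled periorbital fat ("orbit carving", so the eye is enclosed by
conducting tissue and never touches air or bone), and a 10 mm retrobulbar
fat cone embeds the posterior globe. The retrobulbar fat matters
physically: at 0.04 S/m it insulates the back of the eye so that current
entering the orbit must cross the conductive globe and leave through the
retina/sclera instead of diffusing into the brain compartment — without it
the retinal coupling of near-eye montages is badly underestimated.

The torso (`attach_torso()`) is a homogeneous cylinder of
scalp-conductivity tissue (140 mm long, 70 mm radius by default) joined by
a neck, providing the right-shoulder (`rS`) landmark; connectivity to the
head is verified by flood fill.

Electrode patches are geodesic squares (30 x 30 mm nominal) of surface
voxels around fixed 10/20 angles (`montage_positions()`); the patch area is
estimated as the exposed footprint faces projected onto the local tangent
plane and lands within 10% of 900 mm^2 at 2 mm spacing. The suborbital
position So is kept at 25 degrees below the Fp2 meridian point — given the
patch half-width of 15 mm (9.3 degrees on the 92 mm sphere), that is the
closest it can sit to Fp2 without the patches overlapping.

# Analytic oracle and solver validation

For two point electrodes on an N-layer concentric sphere, the potential in
layer `m` is a Legendre series with radial parts
`A_m r^l + B_m r^(-l-1)`; the coefficients follow from continuity of
potential and radial current at the interfaces, regularity at the center
and the surface Neumann source. The per-degree interface systems are solved
directly with a per-layer normalized radial basis (columns scaled by the
layer's outer/inner radius powers), which keeps them well conditioned to
arbitrary order; the homogeneous case reduces to the classical
`I/(4 pi sigma R) * sum ((2l+1)/l) (r/R)^l P_l` series. Default truncation
is L = 120 (L = 200 in the validation); the comparison is
truncation-converged well below that.

`oracle_comparison()` packages the validation case: a 92/86/80 mm
scalp/skull/brain sphere (0.43/0.01/0.33 S/m), point-like electrodes
(single surface-node clusters, no electrolyte pad) at the vertex and the
right temple (90 degrees apart, so the evaluation region is well away from
both injection sites), and the relative L2 error of the potential computed
by midpoint quadrature at element centers — the interior points of the
trilinear interpolant; sampling at nodes instead would over-weight the
staircase boundary layer — outside 10 mm exclusion zones around the
electrodes (which remove the point-versus-cluster modelling mismatch from
the metric). At 2 mm spacing the error is below 5% and it decreases at
1.5 mm; the residual error is dominated by the staircase voxelization of
the thin high-contrast skull shell and shrinks roughly linearly with the
spacing.

# Staircase protocol

The three-step threshold measurement is implemented verbatim:

1. **Ascending series**: 50 to 500 uA in 50 uA steps until the first
   detection (the *reference*); no detection invalidates the subject for
   that montage.
2. **Refinement**: reference -25, +25, +50 uA, each presented twice; the
   lowest intensity detected on both presentations proceeds. The reference
   itself is not re-tested (the protocol wording lists only the three
   offsets); if nothing is detected twice the reference proceeds, flagged.
3. **Final**: the refined value -25/0/+25 uA three times each at 16 Hz in
   randomized order, interleaved with one 5 Hz catch burst per intensity
   (logged, never counted toward the rule). The PT is the lowest intensity
   at or above the 50 uA protocol floor detected in at least two of three
   trials; otherwise the refined value +25 uA is returned flagged invalid.

For a deterministic observer (detect iff intensity >= theta) this machinery
collapses to the quantization law `PT = 25 * ceiling(theta / 25)`, floored
at 50 uA — verified exhaustively for every integer theta in [26, 500]. The
law is what makes population medians recoverable: a cohort with true median
near 95 uA yields a median PT of exactly 100 uA.

Burst timing (10 s bursts, fade-in/out, inter-stimulus intervals) does not
affect the computation and is not modelled.

# Observers and cohorts

An observer detects a burst with probability
`p = gate(freq) * ((1 - lapse) * Psi((I - theta)/s) + fp * (1 - Psi))`,
with `Psi` the standard normal CDF, `s = 0` giving the deterministic step
observer, and `gate = 0` at the 5 Hz control frequency by default (catch
bursts are never detected). Responses with `p` in {0, 1} consume no random
numbers, so deterministic observers are reproducible under any seed and
montage order.

Cohorts come in two modes:

* **direct**: per-montage thresholds from `Normal(mean, SD)` truncated to
  [30, 450] uA — the bounds keep every true threshold inside the protocol's
  measurable range (~50 to 525 uA). Defaults are the reported F7-F8 scale,
  mean 95 and SD 33 uA. Note that truncation shifts the population mean to
  96.97 uA; tests compare against the truncated-normal closed form.
* **coupled**: one retinal current-density threshold per subject,
  `theta_m = 1000 * D / c_m` uA, where `c_m` is the montage's simulated
  mean retinal current density per mA injected. Montages with stronger
  simulated coupling get lower thresholds by construction — the idealized
  version of the negative density-threshold relationship. The default `D`
  distribution (3.7 +/- 1.2 mA/m^2) anchors to the published F7-F8
  coupling; for phantom-derived couplings
  `calibrate_density_threshold()` re-anchors it through the phantom's own
  F7-F8 value so cohorts stay inside the dynamic range at any resolution.

Eye dominance is generated as a label with no threshold effect by default
(`dominance_effect_uA` exists for power exploration). Per-subject RNG
streams are derived from one master seed, and the montage order is
randomized per subject.

# Regions of interest and retinal maps

The anatomical ROIs of a real head cannot be transferred to a sphere, so
fixed geometric stand-ins are used: eye surface = outer element layer of
each globe (optic nerve excluded); retina = the retina-labeled posterior
semi-shell; occipital cortex = brain voxels in a posterior cap (30 degree
half-angle about the occipital pole, outer quarter of the brain radius);
LGN = a 5 mm ball at (+/-12, -15, 0) mm. ROI summaries are volume-weighted
means of element |J| (arithmetic means on the uniform grid), reported in
mA/m^2 and per mA injected.

Retinal maps bin retina elements into 4 quadrants x 2 eccentricity rings
(central: polar angle <= 30 degrees from the posterior pole — the published
figure's degree ranges are internally inconsistent, so this boundary is an
explicit, configurable choice). The visual-field convention flips both
quadrant axes, e.g. the retinal lower-left quadrant is displayed upper
right.

# Statistics

Average ranks are used for ties throughout. Spearman's `r_s` is the Pearson
correlation of rank vectors, with full permutation enumeration for n <= 8
(tie-aware) and the t approximation otherwise; one-tailed directions follow
the physiological hypotheses (negative for eye/retina densities versus PT,
positive for occipital cortex). The Friedman statistic uses the
tie-corrected chi-square form with an exact within-row permutation option
for small tables. The Wilcoxon signed-rank null is computed exactly for
n <= 20 by convolution over the (possibly tied, half-integer) ranks — base
R's implementation declines exactness under ties, which is why these are
implemented here and cross-checked against base R on tie-free inputs and
against exhaustive enumeration oracles in the tests. Bonferroni correction
multiplies by the number of comparisons actually performed (configurable).
The distance analysis correlates per-montage thresholds with the average
electrode distance to the right-eye center and to the occipital-cortex
centroid, excluding So-rS (whose current levels in both targets make the
distance surrogate meaningless for it).

One caveat carried as documentation rather than an assertion: the published
occipital-cortex rank correlation (r_s = 0.929) is not reproducible from
the printed table under average-rank ties (recomputation gives a nearby but
different value for every hemisphere choice), so the package computes and
reports the correlation but does not assert the printed coefficient.

# What the synthetic data can and cannot show

The published current-density magnitudes were obtained on subject-specific
MRI/CT meshes with tens of millions of elements; they depend on that
anatomy and are **not** reproducible on a sphere phantom. They are shipped
as transcribed reference tables (`load_fixtures()`, checksum-guarded), and
every quantity derived from them (the r^2 = 0.65 eye-density regression,
the 48.6 and 30.3 mA/m^2 model differences) is recomputed from the tables,
not from the solver. What the phantom pipeline *does* reproduce is
structure: conservation, symmetry and scaling laws of the field; the
ordering of retinal coupling between near-eye and far montages; the
negative correlation between simulated retinal density and simulated median
PT across 200 replicate studies; and rising thresholds with electrode-eye
distance. Passing these tests says the machinery is consistent and the
qualitative physics is right — it does not validate absolute densities for
any real head.

# Problem sizes and runtime choices

The test suite uses deliberately desk-scale configurations: the solver
validation runs the 92 mm three-layer sphere at 2 mm (~430k unknowns) and
1.5 mm (~1.0M unknowns); geometry checks use the default detailed head at
2 mm; the full pipeline (7 montages, FEM + 200 replicate studies of 15
subjects) runs at 4 mm (~60k unknowns per solve). Stochastic pipeline
observers use a 10 uA psychometric slope with 2% lapse and false-positive
rates — enough response noise to be realistic without destroying the
montage ordering in a 15-subject study.

# Known limitations

* Spherical phantoms: no real anatomy, no orbital bone geometry, no
  frequency dependence (16 Hz is treated as an amplitude), isotropic
  conductivities only.
* The suborbital electrode cannot sit closer than ~40 mm to the Fp2 patch
  center on a 92 mm sphere without overlap, which compresses the montage
  geometry relative to a real face; absolute couplings shift accordingly.
* Model-1 physics is reproduced as a boundary-condition/conductivity preset
  on the same hexahedral mesh (no tetrahedra).
* Retinal thickness is exaggerated to one element layer (2-4 mm at desk
  resolutions), as in any voxel model at this scale.
* The staircase simulator models detection, not percept localization;
  reported phosphene sectors are compared only at the level of retinal map
  sectors.
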