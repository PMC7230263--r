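---
title: "perfushear: models, numerical methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perfushear: models, numerical methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering of `perfushear`: the
flow model and its discretization, the image-quantification contract, what
the synthetic generator does and does not emulate, and the choices made
where the underlying experimental description left the design open.

## 1. Flow model

### Governing equations

The perfusion channel is a flat rectangular duct (width 4 mm across the
flow, height 254 µm) perfused at 2 µL/min. At these scales the Reynolds
number is ~10⁻²–10⁻³, so the flow is governed by the steady incompressible
Stokes equations,

$$ -\mu \nabla^2 \mathbf{u} + \nabla p = 0, \qquad \nabla\cdot\mathbf{u} = 0 ,$$

solved in two dimensions over the streamwise XZ cross-section (unit depth;
the channel is ~16× wider than tall, so away from the side walls the flow
is two-dimensional). Inside a permeable nodule the Brinkman momentum
balance adds the Darcy drag:

$$ -\mu \nabla^2 \mathbf{u} + \frac{\mu}{\kappa}\,\mathbf{u} + \nabla p = 0 .$$

The nodule is an ellipse with semi-minor axis *b* = 40 µm (vertical),
semi-major axis *a* = 40–100 µm (streamwise), centre 20 µm above the floor
so that it protrudes 60 µm into the channel.

Boundary conditions: no slip on floor and ceiling; a fully developed
parabolic profile with mean *U* = *Q*/(*wh*) ≈ 0.033 mm/s at both inlet
and outlet (only the inlet velocity magnitude is physically prescribed;
prescribing the developed profile at both ends is exact when the nodule is
kept ≥ 1 mm from either end, which the default 2.2 mm section guarantees);
gauge pressure pinned to the outlet value in one reference cell.

Closed-form plane-channel anchors are used throughout: wall shear
τ_w = 6µQ/(w·h²) (≈ 7.75·10⁻⁴ Pa = 0.008 dyn/cm² for water-like medium)
and the parabolic profile u(z) = 6U(z/h)(1 − z/h). All nodule-surface shear
values are reported normalized by τ_w. Note two heights coexist: the chip's
adhesive film is 254 µm while the simulated domain of the reference figures
uses 250 µm; the solver takes the height as a parameter, analytic anchors
default to 254 µm and simulations to 250 µm.

### Discretization and solver

No finite-element library is available in this R stack, and the solver is
the package's core contribution, so it is written directly: a MAC staggered
finite-difference grid (pressure at cell centres, velocity components at
face centres) with second-order central differences, assembled as one
sparse saddle-point system and solved by sparse LU (`Matrix`). A uniform
grid with cell size ≤ *b*/10 (default 4 µm) is required so the nodule
surface is resolved. The system is nondimensionalized (lengths by the cell
size, velocities by *U*, pressure by µU/Δ) before assembly; without this
the solid-nodule penalization (below) pushes the matrix outside the LU
conditioning bounds.

The nodule enters only through the spatially varying drag µ/κ(x,z)
evaluated at each staggered node (Brinkman penalization). A solid nodule is
the κ → 0 limit, realized with κ_solid = 10⁻¹⁸ m²; the resulting interior
velocities are ≤ 10⁻⁶ U, i.e. no slip holds to solver accuracy. Because
solid and porous nodules share one code path, the solid-limit consistency
property (porous solution → solid profile as κ → 10⁻¹⁸ m²) holds by
construction and is still verified by test.

The domain is kept symmetric about the nodule centre (even number of cells)
so that, for a symmetric nodule, the discrete operator is mirror-symmetric
and the computed shear profile is symmetric to machine precision — the
symmetry test therefore checks the extraction chain, not luck.

### Surface profiles

*Shear.* σ(s) = µ ∂u_t/∂n is sampled at 181 evenly spaced ellipse angles
over the exposed arc (the part of the ellipse above the floor). The normal
derivative is obtained by interpolating the tangential velocity at one, two
and three cell sizes outward along the surface normal and extrapolating a
quadratic fit to the surface; sampling only outside the penalized boundary
layer avoids its O(Δ) smearing. One visible discretization artefact
remains: near the apex the staircase representation of the grid-aligned
surface slightly flattens the profile, so the discrete maximum appears as
twin peaks a few samples to either side of the apex (the apex value is
within ~10 % of the peak). Orderings, symmetry and normalization are
unaffected; the coincidence test between the shear maximum and the
zero-flux point therefore allows a tolerance of a few degrees of arc.

*Penetration flux.* The normal velocity on the penalized boundary itself is
dominated by staircase noise, so the flux profile is measured on the
ellipse offset two cell sizes *inward*, where the Brinkman (Darcy-like)
interior flow is smooth. Positive flux means flow entering the nodule. The
closed-surface integral (exposed arc plus the no-flow base) vanishes to
discretization accuracy, and the profile is antisymmetric for a symmetric
nodule: the flow enters upstream and exits downstream.

### Permeability default (a deliberate deviation)

Published values for tumor-tissue permeability span 10⁻¹³–10⁻⁹ m². The
low end of that range, κ = 10⁻¹³ m², gives a Brinkman screening length
√κ ≈ 0.32 µm — an order of magnitude below any affordable grid — and makes
the porous nodule numerically indistinguishable from a solid one (the
measured porous-vs-solid peak difference falls below discretization noise
and can even take the wrong sign). Since the reference simulations show a
*noticeably* smaller porous shear, which requires a screening length
comparable to the nodule size, the package defaults to
κ = 10⁻¹⁰ m² (screening length 10 µm = b/4, still within the published
range) with porosity ε = 0.3. Both are configurable; all qualitative
conclusions (orderings, symmetry, flux pattern) are what the tests assert,
and none depends on the exact value.

## 2. Synthetic calcein imaging

The generator emulates what the quantification pipeline actually consumes:
adherent 3D nodules as bright filled ellipses (areas log-normal around
2500 µm², i.e. the regime of the 2000 µm² reference cut-off with a
500–3000 µm² sweep) on a dark background, rendered into a 13 × 3 grid of
512-px tiles with 10 % overlap and ~18 Z-planes at 10 µm. Axial extent is
2–4 planes with a triangular intensity profile peaking at 1, so a
maximum-intensity projection recovers the full live level. Noise is Poisson
shot noise on the signal plus additive Gaussian read noise (defaults:
background 10, live 100, read σ = 2, giving SNR ≈ 10 at the live level).
The pixel size is not calibrated in the source experiments, so a single
configurable value (2.5 µm/px; a 512-px tile spans 1.28 mm, 2000 µm² ≈ 320
px) is used for both culture arms, and all thresholds are specified in µm².

Determinism: one master seed; every tile × plane (and every experiment
stage) derives its own stream from it, so outputs are bitwise reproducible
and independent of tile visit order. The ground-truth ledger records both
the analytic ellipse area πab and the rasterized pixel area — the latter is
the exact oracle for segmentation (recovered areas match it to within a
one-pixel boundary ring per object).

Dose-response experiments thin and shrink the control scene so the planted
viable area is exactly `fraction × control area` (times replicate-level
log-normal noise, CV 0.10 by default, matching the spread of the reference
normalized areas). Default fractions follow the static carboplatin series
(1, 0.93, 0.82, 0.83, 0.70, 0.55, 0.18 for 0–500 µM); the 100 µM value is
not reported in the source data and is set once to 0.70, between its
neighbours. Recovery tests compare against the *planted* truth table, not
the nominal fractions, so replicate noise does not inflate the tolerance.

What the generator does **not** emulate: optical point-spread functions,
spectral bleed-through, photobleaching, illumination gradients across
tiles, stage-registration error (tiles are pre-registered, as real stage
mosaics effectively are), or biologically realistic nodule morphology. A
green pipeline test therefore establishes correctness of the *computation*
— segmentation, stitching, projection, labeling, merging, normalization —
not robustness to every optical artefact of a real microscope.

## 3. Quantification pipeline

Calibration mirrors the live/formalin-fixed bracketing of the calcein
dynamic range: the global floor is the midpoint of the robust means
(medians) of the two image sets. Segmentation is local-mean adaptive
thresholding (window 101 px — much larger than any nodule, so the local
mean stays near background even inside objects) with an offset of
0.5 × (live − background), AND-gated with the global floor; the exact
internals of the commercial adaptive-threshold routine used originally are
not replicated — the behavioural contract (blank → empty; noiseless disk
recovered to a one-pixel ring; bright-object polarity; idempotence on
binary images) defines the operation instead.

Stitching fuses overlap strips by pixelwise maximum (exact for identical
signal, robust to illumination mismatch); overlap pixels =
round(0.10 × 512) = 51. Composite masks are the OR of per-plane masks.
The reference description multiplies the composite mask by the MIP before
thresholding for size; since the product's nonzero support *is* the
composite mask, areas are computed from the mask directly and the product
is treated as a visualization step. Connected components use
8-connectivity (the source is silent; 8 is the conservative choice for
merging). Areas are always converted to µm² through pixel_size².

The streaming mode reproduces the memory-aware processing of the original
large mosaics: the mosaic is processed in vertical bands split at overlap
midpoints, each segmented with a halo of half the adaptive window so every
retained pixel sees its complete window — making per-pixel results
*bitwise identical* to the whole-mosaic path — and objects touching band
seams are merged by union-find before size filtering. At most two tile
columns (far less than two grid rows) are resident at once. Identity of
streaming and whole-mosaic results is asserted, not approximated.

## 4. Statistics

Summaries are mean ± SEM (sample s.d., n − 1). Two-group comparisons:
Welch t (two-tailed) and Mann–Whitney U (exact for tie-free groups of
n ≤ 8, normal approximation with tie correction otherwise). Dose series:
one-way ANOVA plus Dunnett-style treated-vs-control contrasts. Exact
Dunnett critical values (as in commercial software) are replaced by a
seeded Monte-Carlo reference: the joint null distribution of the contrast
t statistics is simulated (≥ 10⁵ draws; group means and a pooled χ²
variance), and single-step adjusted p values are tail probabilities of
max|T|. This is cached per design, which also makes the 2000-replicate
type-I calibration tests cheap. A rank-based variant (Kruskal–Wallis +
Dunn with Bonferroni adjustment) is available via `rank = TRUE`.

The cut-off sensitivity analysis treats the size cut-off as a
within-replicate factor (each well is re-quantified at every cut-off) and
runs a repeated-measures one-way ANOVA per treatment group — the chosen
interpretation of the original "multivariate ANOVA across thresholds",
which was not further specified. The analysis is "threshold-stable" when
no group shows a cut-off effect at α = 0.05. Degenerate inputs (zero
between- or within-variance) return p = 1 or p = 0 explicitly rather than
NaN. How the 9 wells (three experiments in triplicate) nest is not fully
specified in the source; replicates are treated as exchangeable, and the
replicate column is the unit the user declares.

## 5. Orchestration and reproducibility

`run_pipeline()` runs synthesize → quantify → summarize → fluids from one
validated configuration; every CSV embeds the configuration hash and seed
in its first line, a JSON manifest records seed, configuration, outputs and
stage timings, and a failure in any stage aborts with a stage-tagged error.
Reruns with the same configuration are byte-identical. The package's
command-line surface is this function plus `scripts/acceptance.R`; no
separate shell binary is shipped.

## 6. Numerical choices and limitations

* Direct sparse LU limits practical grids to ~10⁵–10⁶ unknowns; the default
  4 µm grid over a 2.2 mm section (~10⁵ unknowns) solves in seconds.
* Convergence is declared by the post-hoc relative residual (< 10⁻⁸);
  non-convergence raises an error carrying the residual.
* The 2D XZ model ignores side-wall effects and spanwise variation; no 3D
  ellipsoid solves, deformable nodules, or non-Newtonian rheology.
* Shear/flux extraction is first-order accurate near the penalized
  boundary; quantitative peak values carry a few percent of discretization
  error (orderings and symmetry are robust; the twin-peak apex artefact is
  described above).
* Reduced-scale synthetic experiments (smaller tile grids, 3 replicates)
  are used in time-budgeted tests; the full 13 × 3 × 18-plane channel is
  exercised once per test run. Scaling down the grid changes runtime, not
  the contract being tested.
* Acceptance never targets values that depend on unpublished parameters
  (the porous scale velocity, absolute permeability effects); only
  recomputable anchors, printed arithmetic relations and property-based
  invariants are asserted.
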