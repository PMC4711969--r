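---
title: "Toroidal modeling of diffusion tensors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Toroidal modeling of diffusion tensors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supertoroid)
```

This vignette documents the models implemented by **supertoroid**, the
numerical choices behind them, what the synthetic phantom does and does not
emulate, and the design decisions taken where the construction was genuinely
open.

## The diffusion tensor and its estimation

Per voxel, diffusion-weighted MRI under the monoexponential model gives
$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i)$ for gradient direction $g_i$ and
b-value $b_i$ (s/mm²), with $D$ the symmetric diffusion tensor (mm²/s).
`fit_tensor()` solves the log-linearized system by ordinary least squares
with $S_0$ taken as the mean of the $b = 0$ volumes. This is the standard
baseline estimator; a one-step weighted refit (`method = "wlls"`, weights
equal to the squared predicted signal) is available to counter the
heteroscedasticity that the log transform induces, but is not the default
because the package makes no claim of matching any particular production
fitter. Non-positive signals are clipped to $10^{-6} S_0$ before the log
and counted; voxels with no signal are masked out, never propagated.

Eigendecomposition (`tensor_eigen()`) sorts eigenvalues descending and
clamps negative eigenvalues — a finite-noise artifact — to zero before any
invariant is computed, because every formula below assumes
$\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$. Eigenvector signs are fixed
by making the largest-magnitude component positive so orientation colors
are reproducible. Voxel indices are 0-based in the voxel-to-world (RAS)
affine convention; eigenvectors are reported in the world frame.

## Toroidal surface and invariants

The toroidal surface is
$$T(\theta,\phi) = \big(\cos\theta\,(\alpha+\beta\cos\phi),\;
\sin\theta\,(\alpha+\beta\cos\phi),\; \gamma\sin\phi\big),$$
with $\alpha = (2\lambda_2+\lambda_3)/4$, $\beta = \lambda_3/4$,
$\gamma = \lambda_1/2$: the z-extent equals $\lambda_1$, the
central-opening diameter $2(\alpha-\beta)$ equals $\lambda_2$, and the
cross-section thickness is $\lambda_3/2$. The shape runs from a tube (high
anisotropy) to an ordinary torus (isotropy).

**TV.** The toroidal volume is implemented exactly as
$TV = (\lambda_1\pi/3)(\lambda_2\lambda_3 + \lambda_3^2/2)$ (mm⁶/s³). Note
that the *geometric* volume enclosed by the surface above is
$2\pi^2\alpha\beta\gamma = (\pi^2/8)\lambda_1(\lambda_2\lambda_3 +
\lambda_3^2/2)$ — the same eigenvalue polynomial with prefactor $\pi^2/8$
rather than $\pi/3$, a constant ratio of $3\pi/8 \approx 1.178$. The tests
verify both facts separately (divergence-theorem quadrature on a
$128\times128$ mesh agrees with $2\pi^2\alpha\beta\gamma$ to 0.1%); the
invariant follows the $\pi/3$ form, and since the two differ by a constant
the choice does not affect any rank-based statistic.

**TC.** The toroidal curvature is the maximum Gaussian curvature of the
$\lambda_1$-normalized surface ($\alpha' = \alpha/\lambda_1$,
$\beta' = \beta/\lambda_1$, $\gamma' = 1/2$):
$$tc(\phi) = \frac{4\beta'\gamma'^2\cos\phi}
{(\alpha'+\beta'\cos\phi)\left[\beta'^2+\gamma'^2+
(\gamma'^2-\beta'^2)\cos 2\phi\right]^2},$$
which algebraically equals the curvature
$\beta'\gamma'^2\cos\phi\,/\,\big((\alpha'+\beta'\cos\phi)
(\beta'^2\sin^2\phi+\gamma'^2\cos^2\phi)^2\big)$ obtained from the first
and second fundamental forms (the double-angle identity absorbs the leading
4), and reduces to the classical circular-torus curvature when
$\beta' = \gamma'$. The test suite checks the closed form against an
independent numerical fundamental-forms oracle (central differences,
$h = 10^{-4}$ — the step is chosen near the float64 optimum for second
derivatives, where truncation $O(h^2)$ and roundoff $\varepsilon/h^2$
balance) to within $10^{-5}$ relative.

Because only normalized parameters enter, TC is dimensionless and scale
invariant; its range is unbounded *across* eigenvalue configurations (the
supremum grows without bound as $\lambda_3/\lambda_1 \to 0$), which gives
it a larger dynamic range than FA in highly linear tissue. Whenever
$\gamma' > \beta'$ — always, except in the degenerate limit — the maximum
of $tc$ can sit strictly inside $(0, \pi/2)$, so no closed-form argmax is
attempted: the maximizer is located on a dense grid over $[0,\pi]$ (2048
points by default) and refined with bounded golden-section search
(`stats::optimize`, tolerance $10^{-10}$). At isotropy the interior maximum
is genuine: $TC(1,1,1) \approx 3.612 > tc(0) = 1$. For $\lambda_1 = 0$ TC
is undefined and stored as 0 under a mask flag; for $\lambda_3 = 0$ the
profile is identically zero and TC is 0.

Degenerate conventions, all chosen as continuum limits rather than NaNs:
FA of the zero tensor is 0; shape metrics of the zero tensor are
$(C_L, C_P, C_S) = (0, 0, 1)$ with a warning; min–max normalization of a
constant map returns all zeros (so constant backgrounds render dark instead
of dividing by zero).

## Supertoroidal glyphs

The glyph surface blends genus-1 shapes driven by the shape metrics: with
branch amplitudes $(A, B) = (C_L+C_P,\, C_S)$ when $C_S \ge C_P$ and
swapped otherwise,
$$\big(\cos^{\eta_1}\theta\,\{A + B\cos^{\eta_2}\phi\},\;
\sin^{\eta_1}\theta\,\{A + B\cos^{\eta_2}\phi\},\; \sin^{\eta_2}\phi\big),$$
with $\eta_1 = (1-C_P)^{\gamma_1}$ and $\eta_2 = (1-C_P)^{\gamma_2}$,
defaults $\gamma_1 = 4$ (sharpness across the medium/minor directions) and
$\gamma_2 = 0.5$ (shape along the rotational axis). Choices made here,
where the formulas admit more than one reading:

- $\cos^\eta$/$\sin^\eta$ are **sign-preserving powers**
  ($\mathrm{sign}(x)|x|^\eta$), the superquadric convention — plain powers
  of negative bases are undefined for fractional exponents and the
  symmetric closed shapes require the odd extension.
- $\eta = (1-C_P)^\gamma$ is read as **exponentiation** (matching the
  superquadric-literature construction); the multiplicative alternative
  $(1-C_P)\cdot\gamma$ is noted but not implemented.
- $\eta$ is floored at 0.05 to avoid numerically flat powers as
  $C_P \to 1$.
- The z-amplitude is unity as printed, with no $C_S$/$C_L$ scaling.
- The two branch parameterizations coincide at $C_S = C_P$ only when
  $C_L = 0$; for $C_L > 0$ the printed equations are genuinely
  discontinuous across the branch switch (the amplitudes differ by
  $C_L$). The continuity property is therefore asserted along the
  $C_L = 0$ edge of the barycentric triangle, where it holds.

Tessellation samples a closed $(\theta,\phi)$ grid without duplicated seam
rows and splits each wrapping quad along its geometrically shorter diagonal
(ties broken by welded vertex indices). This rule matters for topology
checks: the isotropic glyph's parameterization traverses the sphere twice,
and because the diagonal choice depends only on vertex geometry, the two
covers produce identical triangles which are then deduplicated — the welded
isotropic blob has Euler characteristic 2 and the non-degenerate toroid 0,
turning the genus switch into a computable assertion. Fully collapsed
glyphs become flagged placeholder meshes rather than errors so slice-wide
exports never abort. Placement maps the local z-axis (the opening
direction) onto $e_1$, local x onto $e_2$, local y onto $e_3$, forcing a
proper rotation; the default display scale is 0.45 voxel so neighboring
glyphs do not overlap.

Color encodings: orientation RGB $=(|e_{1x}|,|e_{1y}|,|e_{1z}|)$ optionally
FA-weighted; normalized TV on a blue→cyan→green→yellow→red ramp; and the
four-class eigenvalue-configuration scheme — orthotropic
$\lambda_1>\lambda_2>\lambda_3$ purple (0.5, 0, 0.5), prolate
$\lambda_1>\lambda_2=\lambda_3$ orange (1, 0.55, 0), oblate
$\lambda_1=\lambda_2>\lambda_3$ green (0, 0.6, 0), isotropic gray
(0.5, 0.5, 0.5) — with the HSV value channel scaled by
$0.2 + 0.8\,\widetilde{TV}$. The exact RGB anchors and the 0.2 brightness
floor are package choices (only the color names are canonical). Eigenvalue
equality for classification uses a relative threshold
$(\lambda_i-\lambda_j)/\lambda_1 \le 0.05$ — no canonical value exists;
0.05 keeps the classes stable under realistic fit noise while separating
the phantom's prolate white matter from its orthotropic tensors, and makes
the classification scale invariant by construction.

## The synthetic phantom

`generate_phantom()` paints four compartments on a default
$32\times32\times16$ grid of 2.5 mm voxels: a spherical high-diffusivity,
near-isotropic *tumor core*; a surrounding *edema* shell; two anisotropic
*white-matter* bundles (one straight, one a 90° arc, so orientation
encoding is exercised); and near-isotropic *gray matter* everywhere else.
Overlaps resolve by precedence core > edema > WM > GM (logged). Default
eigenvalue triples (mm²/s) are literature-typical brain values: tumor
(1.8, 1.7, 1.6)·10⁻³, edema (1.3, 1.1, 1.0)·10⁻³, GM
(0.9, 0.8, 0.75)·10⁻³, WM (1.7, 0.4, 0.3)·10⁻³. They are synthetic
defaults chosen once to produce the qualitative regional orderings a
glioblastoma cohort shows — MD/TV: tumor > edema > parenchyma; FA/TC:
WM ≫ GM; TV (but not MD) separating GM from WM — and are **not** measured
values from any study. ROI labels are trimmed to equal voxel counts by
default (nearest-to-reference-point rule), mirroring an equal-volume ROI
sampling design.

DWI synthesis uses a deterministic 32-direction spherical-Fibonacci
gradient scheme at $b \in \{0, 800\}$ s/mm² and Rician noise (Gaussian on
two quadrature channels, then magnitude; scale $\sigma S_0$), the
magnitude-MRI standard; plain Gaussian noise is available for debugging.
Cohorts apply one lognormal scale factor (log-sd 0.05 by default) per
subject and region to the whole eigenvalue triple, so the cross-subject CV
of each region's MD is about 5%; per-subject seeds derive from the master
seed by fixed increments. What the phantom does *not* emulate: partial
volume, susceptibility and eddy-current artifacts, spatially varying noise,
anatomically realistic geometry, or infiltrative tumor margins. Passing
tests therefore demonstrate correctness of the estimators and statistics
under the stated generative model, not clinical performance on scanner
data.

## Cohort statistics

For each invariant the subjects × regions matrix of ROI means is tested
with the Friedman rank test (within-subject mid-ranks, tie-corrected
χ² statistic, $k-1$ degrees of freedom); the χ² approximation is the
primary p-value — standard practice at n = 18 — with an exact permutation
p-value (dynamic programming over all $k!^n$ tie-free orderings) available
for $n \le 8$. Post-hoc paired sign tests (exact two-sided binomial on the
signs, zeros dropped) run on all six region pairs only when the omnibus
p-value is below α = 0.05 — gatekeeping by the omnibus test, with *no*
multiplicity correction by default to mirror the per-pair reporting
convention; a Bonferroni option exists. `stats::friedman.test` and
`stats::binom.test` serve as independent cross-checks in the test suite,
not as the implementation, since the package's version adds the tie
correction and the exact permutation path.

## Problem sizes and reproducibility

The test suite and the acceptance script use a $32\times32\times16$ phantom
for the 18-subject cohort and a $64\times64\times16$ grid for the
noiseless fit-recovery check, sizes at which the designed effects are
comfortably detectable and a full run of everything completes in a few
minutes on one CPU. Every stochastic step takes an explicit seed; identical
seeds give bit-identical phantoms, signals, and serialized reports.

## Known limitations

- The tensor fit is log-linear (optionally one-step weighted); no
  nonlinear, robust, or constrained (positive-definite) fitting.
- Single-shell, Gaussian diffusion only; no multi-compartment or kurtosis
  models.
- TC is reported as a dimensionless curvature of the normalized surface,
  not in physical units; only its ordering is meaningful across voxels.
- Inputs are assumed motion- and distortion-corrected; no registration is
  performed.
- Voxelwise statistics, skeletonized analyses, and tractography are out of
  scope.
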