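# supertoroid

Toroid-based modeling and analysis of diffusion tensor MRI (DTI) in R.

DTI reduces water diffusion in each voxel to a symmetric positive 3×3 tensor
with eigenvalues λ₁ ≥ λ₂ ≥ λ₃ (mm²/s) and eigenvectors giving the principal
diffusion directions. The classical scalar summaries — mean diffusivity
MD = (λ₁+λ₂+λ₃)/3 and fractional anisotropy FA — and the classical glyphs
(ellipsoids, superquadrics) struggle to disambiguate eigenvalue
configurations and to separate tumor-infiltrated tissue from peritumoral
edema. This package implements a toroid-based alternative aimed at exactly
that problem, for neuroimaging researchers working with brain-tumor (e.g.
glioblastoma) DTI:

- **Supertoroidal glyphs.** A genus-1 generalization of superquadric glyphs
  driven by the Westin shape metrics C_L = (λ₁−λ₂)/Σλ, C_P = 2(λ₂−λ₃)/Σλ,
  C_S = 3λ₃/Σλ, with sharpness exponents η₁ = (1−C_P)^γ₁, η₂ = (1−C_P)^γ₂
  (defaults γ₁ = 4, γ₂ = 0.5). The central opening is aligned with the
  principal eigenvector from any viewing angle; in isotropic voxels the
  glyph closes into a genus-0 blob.
- **Toroidal invariants.** From the toroidal surface
  T(θ,φ) = (cosθ(α+βcosφ), sinθ(α+βcosφ), γ sinφ) with
  α = (2λ₂+λ₃)/4, β = λ₃/4, γ = λ₁/2:
  - **TV** (toroidal volume) = (λ₁π/3)(λ₂λ₃ + λ₃²/2), a *nonlinear*
    diffusivity index in mm⁶/s³ complementing the affine MD;
  - **TC** (toroidal curvature) = max over φ of the Gaussian curvature of
    the λ₁-normalized surface, an unbounded anisotropy index complementing
    FA ∈ [0,1].
- **Tensor estimation** by log-linear least squares (optional weighted
  refit) from 4D DWI volumes with FSL-style `.bval`/`.bvec` tables.
- **Synthetic brain phantoms** (tumor core / edema / white matter / gray
  matter, Rician noise, multi-subject jitter) so the whole pipeline is
  testable without scanner data.
- **Cohort ROI statistics**: Friedman omnibus test across regions with
  post-hoc exact sign tests.

## Worked example

```r
library(supertoroid)

# a 32x32x16 brain-like phantom: tumor core, edema shell, two WM bundles
ph <- generate_phantom(phantom_spec(seed = 3))
eigs <- tensor_eigen(ph$field)

md <- roi_means(compute_map(eigs, "MD"), ph$rois)
tv <- roi_means(compute_map(eigs, "TV"), ph$rois)
fa <- roi_means(compute_map(eigs, "FA"), ph$rois)
tc <- roi_means(compute_map(eigs, "TC"), ph$rois)
round(rbind(MD = md * 1e3, TV = tv * 1e9, FA = fa, TC = tc), 3)
#>        tumor   edema    GM      WM
#> MD     1.700   1.133  0.817   0.800
#> TV     7.540   2.178  0.831   0.294
#> FA     0.059   0.134  0.093   0.763
#> TC     4.853   7.201  5.825 510.660
```

(MD row in 10⁻³ mm²/s, TV row in 10⁻⁹ mm⁶/s³.) The diffusivity indices rank
tumor > edema > parenchyma, but TV spreads the regions far more than MD —
its nonlinearity is what separates gray from white matter where MD cannot
(GM ≈ WM in the MD row). TC explodes in the anisotropic white-matter bundle
(≈511 vs FA's bounded 0.76), its greater dynamic range for highly linear
structures.

Glyph meshes for a slice, colored by eigenvalue configuration with
TV-modulated brightness:

```r
mesh <- glyph_slice(ph$field, z = 8, mode = "supertoroid", color = "config")
write_mesh(mesh, "slice8.ply")   # binary PLY with per-vertex RGB
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "supertoroid.R", package = "supertoroid")` with
subcommands `phantom`, `fit`, `maps`, `glyphs`, `stats`; see `--help`.

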