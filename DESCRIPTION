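Package: supertoroid
Title: Supertoroidal Glyphs and Toroidal Invariants for Diffusion Tensor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diffusion tensor estimation and toroid-based analysis of diffusion
    MRI. Fits the diffusion tensor to diffusion-weighted volumes by log-linear
    least squares, eigendecomposes the tensor field, and computes the classical
    scalar invariants (mean diffusivity, fractional anisotropy) together with
    the toroidal invariants: the toroidal volume (TV), a nonlinear diffusivity
    index, and the toroidal curvature (TC), the maximum Gaussian curvature of an
    eigenvalue-parameterized toroidal surface. Generates supertoroidal and
    toroidal glyph meshes with orientation, eigenvalue-configuration and TV
    color encodings, synthesizes brain-like tensor phantoms with tumor-core,
    edema, white-matter and gray-matter compartments under Rician noise, and
    runs region-of-interest cohort statistics (Friedman omnibus test with
    post-hoc sign tests). Reads and writes NIfTI volumes, FSL-style
    bval/bvec tables, and PLY/OBJ meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
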