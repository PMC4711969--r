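# MD, FA, TV, TC and the curvature profile, checked against closed forms and
# the fundamental-forms oracle.

test_that("mean diffusivity is the eigenvalue mean", {
  expect_equal(mean_diffusivity(c(3, 2, 1) * 1e-3), 2e-3)
  expect_equal(mean_diffusivity(c(1.1e-3, 1.1e-3, 1.1e-3)), 1.1e-3)
  expect_equal(mean_diffusivity(c(1.7e-3, 4e-4, 4e-4)), 8.333333333e-4,
               tolerance = 1e-9)
})

test_that("fractional anisotropy matches closed forms and stays in [0, 1]", {
  expect_equal(fractional_anisotropy(c(1, 1, 1)), 0)
  expect_equal(fractional_anisotropy(c(1, 0, 0)), 1)
  expect_equal(fractional_anisotropy(c(3, 2, 1)), sqrt(3 / 14),
               tolerance = 1e-12)
  expect_warning(z <- fractional_anisotropy(c(0, 0, 0)), "zero")
  expect_equal(z, 0)
  set.seed(3)
  fa <- fractional_anisotropy(random_evals(1e5))
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("toroid parameters follow their defining relations", {
  p <- toroid_params(c(1, 1, 1))
  expect_equal(c(p$alpha, p$beta, p$gamma), c(3 / 4, 1 / 4, 1 / 2))
  p2 <- toroid_params(c(1, 0, 0))
  expect_equal(c(p2$alpha, p2$beta, p2$gamma), c(0, 0, 1 / 2))
  p3 <- toroid_params(c(2, 1, 1) * 1e-3)
  expect_equal(c(p3$alpha, p3$beta, p3$gamma), c(7.5e-4, 2.5e-4, 1e-3))
  # normalized primes: gamma_p is always 1/2, beta_p in [0, 1/4], <= alpha_p
  set.seed(21)
  pr <- toroid_params(random_evals(1000, min = 1e-5))
  expect_true(all(pr$gamma_p == 0.5))
  expect_true(all(pr$beta_p >= 0 & pr$beta_p <= 0.25 + 1e-15))
  expect_true(all(pr$beta_p <= pr$alpha_p + 1e-15))
  # degenerate flag for a zero tensor
  expect_true(toroid_params(c(0, 0, 0))$degenerate)
})

test_that("toroidal volume matches its closed form and vanishes with lambda3", {
  expect_equal(toroidal_volume(c(1, 1, 1)), pi / 2, tolerance = 1e-12)
  expect_equal(toroidal_volume(c(2e-3, 1e-3, 5e-4)),
               (2e-3 * pi / 3) * (5e-7 + 1.25e-7), tolerance = 1e-12)
  expect_equal(toroidal_volume(c(1, 0.5, 0)), 0)
  set.seed(4)
  expect_true(all(toroidal_volume(random_evals(1e5)) >= 0))
})

test_that("the curvature profile reduces to the circular-torus closed form", {
  phi <- seq(0, 2 * pi, length.out = 64)
  got <- tc_profile(phi, alpha_p = 3, beta_p = 1, gamma_p = 1)
  classic <- cos(phi) / (1 * (3 + cos(phi)))
  expect_equal(got, classic, tolerance = 1e-12)
})

test_that("the curvature profile matches the fundamental-forms oracle", {
  set.seed(31)
  ev <- random_evals(50, min = 5e-5)
  phi <- seq(0.02, pi - 0.02, length.out = 64)
  for (i in seq_len(nrow(ev))) {
    pr <- toroid_params(ev[i, , drop = FALSE])
    got <- tc_profile(phi, pr$alpha_p, pr$beta_p)
    want <- numeric_gaussian_curvature(pr$alpha_p, pr$beta_p, 0.5, phi)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-4)), 1e-5)
  }
})

test_that("profile values at special angles are as derived", {
  expect_equal(tc_profile(0, 3 / 4, 1 / 4), 1, tolerance = 1e-12)
  expect_equal(tc_profile(pi / 2, 3 / 4, 1 / 4), 0, tolerance = 1e-12)
  expect_equal(tc_profile(pi / 2, 0.9, 0.2), 0, tolerance = 1e-12)
})

test_that("TC is continuous at isotropy, scale invariant, with interior maximum", {
  tc_iso <- toroidal_curvature(c(1, 1, 1))
  tc_near <- toroidal_curvature(c(1, 0.999999, 0.999999))
  expect_lt(abs(tc_near - tc_iso) / tc_iso, 1e-4)
  # the maximum exceeds the rim value tc(0) = 1: interior maximum
  expect_gt(tc_iso, tc_profile(0, 3 / 4, 1 / 4))
  set.seed(17)
  ev <- random_evals(30, min = 1e-5)
  for (c_ in c(0.37, 5)) {
    expect_equal(toroidal_curvature(ev * c_), toroidal_curvature(ev),
                 tolerance = 1e-9)
  }
  # degenerate eigenvalues
  expect_equal(toroidal_curvature(c(0, 0, 0)), 0)
  expect_equal(toroidal_curvature(c(1, 0.5, 0)), 0)  # flat profile, beta = 0
})

test_that("TC increases strictly from isotropy toward anisotropy", {
  t_path <- seq(1, 0.05, by = -0.05)
  tc <- toroidal_curvature(cbind(1, t_path, t_path))
  expect_true(all(diff(tc) > 0))
})

test_that("TC grid+refine maximization agrees with a dense-grid oracle", {
  set.seed(55)
  ev <- random_evals(20, min = 1e-4)
  phi <- seq(0, pi, length.out = 2e5)
  for (i in seq_len(nrow(ev))) {
    pr <- toroid_params(ev[i, , drop = FALSE])
    dense <- max(tc_profile(phi, pr$alpha_p, pr$beta_p))
    expect_equal(toroidal_curvature(ev[i, ]), dense, tolerance = 1e-6)
  }
})

test_that("MD is affine along a linear eigenvalue path while TV is not", {
  t_ <- seq(0, 1, length.out = 21)
  ev <- cbind(1 + t_, 1 + t_, 1 + t_) * 1e-3
  md <- mean_diffusivity(ev)
  tv <- toroidal_volume(ev)
  expect_lt(max(abs(diff(diff(md)))), 1e-12 * max(md))
  expect_gt(max(abs(diff(diff(tv)))), 1e-6 * max(tv))
})

test_that("compute_map vectorizes the per-voxel invariants over a field", {
  d <- 1e-3
  dims <- c(4, 4, 2)
  field <- evals_to_field(matrix(d, prod(dims), 3), dims)
  expect_equal(unique(as.vector(compute_map(field, "MD")$values)), d)
  expect_equal(unique(as.vector(compute_map(field, "FA")$values)), 0)
  # two-region field agrees with direct per-voxel invariant calls
  ev_wm <- c(1.7e-3, 4e-4, 3e-4); ev_csf <- c(3e-3, 2.9e-3, 2.9e-3)
  ev <- rbind(matrix(ev_wm, 16, 3, byrow = TRUE),
              matrix(ev_csf, 16, 3, byrow = TRUE))
  field2 <- evals_to_field(ev, dims)
  eigs2 <- tensor_eigen(field2)
  for (w in c("MD", "FA", "TV", "TC")) {
    m <- compute_map(eigs2, w)
    f <- switch(w, MD = mean_diffusivity, FA = fractional_anisotropy,
                TV = toroidal_volume, TC = toroidal_curvature)
    expect_equal(as.vector(m$values), as.vector(f(ev)), tolerance = 1e-9)
    expect_false(any(is.na(m$values)))
  }
  # masked voxels are excluded and zero-filled
  mask <- array(TRUE, dims); mask[1, 1, 1] <- FALSE
  field3 <- tensor_field(field2$D, mask = mask)
  m3 <- compute_map(field3, "MD")
  expect_equal(m3$values[1, 1, 1], 0)
  expect_false(m3$mask[1, 1, 1])
})

test_that("map normalization is min-max over the mask with constant maps at 0", {
  m <- scalar_map(array(c(2, 4, 6, 0), c(4, 1, 1)),
                  mask = array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)))
  nm <- normalize_map(m)
  expect_equal(as.vector(nm$values), c(0, 0.5, 1, 0))
  const <- scalar_map(array(5, c(3, 1, 1)))
  expect_equal(unique(as.vector(normalize_map(const)$values)), 0)
  empty <- scalar_map(array(1, c(2, 1, 1)), mask = array(FALSE, c(2, 1, 1)))
  expect_error(normalize_map(empty), "empty mask")
  # the argmax voxel of a phantom TV map lands exactly at 1
  ph <- generate_phantom(phantom_spec(seed = 2))
  suppressMessages(tv <- compute_map(ph$field, "TV"))
  expect_equal(max(normalize_map(tv)$values), 1)
})

test_that("the tessellated toroid encloses the analytic 2 pi^2 alpha beta gamma volume", {
  ev <- c(1.6e-3, 9e-4, 5e-4)
  mesh <- tessellate(toroid_surface(ev, n_theta = 128, n_phi = 128))
  pr <- toroid_params(ev)
  v_analytic <- 2 * pi^2 * pr$alpha * pr$beta * pr$gamma
  expect_lt(abs(mesh_volume(mesh) - v_analytic) / v_analytic, 1e-3)
  # ratio of the geometric volume to the printed TV form is the constant 3 pi/8
  expect_equal(v_analytic / toroidal_volume(ev), 3 * pi / 8, tolerance = 1e-12)
})
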