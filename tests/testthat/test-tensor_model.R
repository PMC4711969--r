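# Tensor estimation, eigendecomposition, shape metrics, configuration classes.

make_single_voxel_dwi <- function(D6, gt = gradient_table(), S0 = 1000) {
  f <- tensor_field(array(D6, c(1, 1, 1, 6)))
  synthesize_dwi(f, gt$bvals, gt$bvecs, S0 = S0)
}

test_that("dwi_volume validates its gradient table", {
  sig <- array(1, c(2, 2, 2, 8))
  bv <- rbind(c(0, 0, 0), diag(3), matrix(rnorm(12), 4, 3))
  expect_s3_class(dwi_volume(sig, c(0, rep(800, 7)), bv), "dwi_volume")
  expect_error(dwi_volume(sig, rep(800, 8), bv), "b=0")
  expect_error(dwi_volume(sig, c(0, rep(800, 6), 0), bv[1:7, ]), "mismatch")
  expect_error(dwi_volume(array(1, c(2, 2, 2)), 0, matrix(0, 1, 3)), "4D")
  # nonzero-b directions come back unit-normalized
  d <- dwi_volume(sig, c(0, rep(800, 7)), bv * 3)
  expect_equal(sqrt(rowSums(d$bvecs[-1, ]^2)), rep(1, 7), tolerance = 1e-12)
})

test_that("noiseless log-linear fit recovers the tensor essentially exactly", {
  D6 <- c(1.7e-3, 0, 0, 4e-4, 0, 4e-4)
  dwi <- make_single_voxel_dwi(D6)
  fit <- fit_tensor(dwi)
  expect_lt(max(abs(fit$D[1, 1, 1, ] - D6)) / max(abs(D6)), 1e-10)
  # and re-synthesized signals match the input
  resig <- predict_signal(fit, dwi$bvals, dwi$bvecs, S0 = 1000)
  expect_lt(max(abs(resig - dwi$signal) / dwi$signal), 1e-9)
})

test_that("isotropic signals fit to an isotropic tensor", {
  d <- 1.1e-3
  dwi <- make_single_voxel_dwi(c(d, 0, 0, d, 0, d))
  # all equal-b signals identical by construction
  expect_equal(diff(range(dwi$signal[1, 1, 1, -1])), 0, tolerance = 1e-12)
  fit <- fit_tensor(dwi)
  expect_equal(fit$D[1, 1, 1, ], c(d, 0, 0, d, 0, d), tolerance = 1e-10 * d)
})

test_that("an unfittable gradient design and zero voxels are rejected/handled", {
  sig <- array(1000, c(1, 1, 1, 7))
  # 6 copies of the same direction: rank 1
  bv <- rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 6), 6, 3, byrow = TRUE))
  dwi <- dwi_volume(sig, c(0, rep(800, 6)), bv)
  expect_error(fit_tensor(dwi), "rank-deficient")
  # an all-zero voxel is masked out, not propagated
  gt <- gradient_table()
  sig2 <- array(1000, c(2, 1, 1, length(gt$bvals)))
  sig2[2, 1, 1, ] <- 0
  dwi2 <- dwi_volume(sig2, gt$bvals, gt$bvecs)
  expect_message(fit2 <- fit_tensor(dwi2), "masked out")
  expect_false(fit2$mask[2, 1, 1])
  expect_true(fit2$mask[1, 1, 1])
})

test_that("fit error under Rician noise scales as the Monte-Carlo oracle predicts", {
  gt <- gradient_table()
  nvox <- 100L
  ev <- matrix(rep(c(1.7e-3, 4e-4, 4e-4), each = nvox), nvox, 3)
  field <- evals_to_field(ev, c(nvox, 1, 1))
  sigma <- 0.02
  dwi1 <- synthesize_dwi(field, gt$bvals, gt$bvecs, sigma = sigma, seed = 11)
  err1 <- median(abs(fit_tensor(dwi1)$D - field$D))
  # oracle: average 10 independent noisy acquisitions -> noise ~ sigma/sqrt(10),
  # so the error should shrink by about sqrt(10)
  sig_avg <- Reduce(`+`, lapply(1:10, function(r) {
    synthesize_dwi(field, gt$bvals, gt$bvecs, sigma = sigma, seed = 100 + r)$signal
  })) / 10
  dwi10 <- dwi_volume(sig_avg, gt$bvals, gt$bvecs)
  err10 <- median(abs(fit_tensor(dwi10)$D - field$D))
  expect_gt(err1, err10)                      # averaging must help
  expect_lt(err1, 3 * sqrt(10) * err10)       # and by roughly sqrt(10)
})

test_that("weighted LLS matches LLS on noiseless data", {
  D6 <- c(1.5e-3, 1e-4, -5e-5, 8e-4, 2e-5, 6e-4)
  dwi <- make_single_voxel_dwi(D6)
  f_lls <- fit_tensor(dwi, method = "lls")
  f_wlls <- fit_tensor(dwi, method = "wlls")
  expect_equal(f_wlls$D, f_lls$D, tolerance = 1e-9)
})

test_that("eigendecomposition handles diagonal, rotated and zero tensors", {
  dims <- c(3, 1, 1)
  lam <- c(3, 2, 1) * 1e-3
  set.seed(5)
  R <- random_rotation_oracle()
  Dr <- R %*% diag(lam) %*% t(R)
  D <- matrix(0, 3, 6)
  D[1, ] <- c(lam[1], 0, 0, lam[2], 0, lam[3])
  D[2, ] <- Dr[c(1, 4, 7, 5, 8, 9)]
  D[3, ] <- 0
  eigs <- tensor_eigen(tensor_field(array(D, c(dims, 6))))
  expect_equal(eigs$values[1, 1, 1, ], lam, tolerance = 1e-12)
  expect_equal(abs(diag(crossprod(matrix(eigs$vectors[1, 1, 1, , ], 3, 3), diag(3)))),
               rep(1, 3), tolerance = 1e-8)
  expect_equal(eigs$values[2, 1, 1, ], lam, tolerance = 1e-12)
  V2 <- matrix(eigs$vectors[2, 1, 1, , ], 3, 3)
  # eigenvectors match the columns of R up to sign
  expect_equal(abs(colSums(V2 * R)), rep(1, 3), tolerance = 1e-8)
  expect_equal(eigs$values[3, 1, 1, ], c(0, 0, 0))
  expect_equal(as.character(classify_configuration(eigs$values[3, 1, 1, ])),
               "ISOTROPIC")
})

test_that("eigendecomposition reconstructs random SPD tensors and sorts descending", {
  set.seed(101)
  n <- 200L
  D <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    A <- matrix(rnorm(9), 3, 3)
    S <- crossprod(A) * 1e-3 + diag(3) * 1e-5
    D[i, ] <- S[c(1, 4, 7, 5, 8, 9)]
  }
  eigs <- tensor_eigen(tensor_field(array(D, c(n, 1, 1, 6))))
  vals <- matrix(eigs$values, n, 3)
  expect_true(all(vals[, 1] >= vals[, 2] & vals[, 2] >= vals[, 3]))
  expect_true(all(vals >= 0))
  for (i in seq_len(n)) {
    V <- matrix(eigs$vectors[i, 1, 1, , ], 3, 3)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-8)
    S <- matrix(D[i, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
    rec <- V %*% diag(vals[i, ]) %*% t(V)
    expect_lt(max(abs(rec - S)) / max(abs(S)), 1e-8)
  }
})

test_that("non-finite tensor voxels are masked, never propagated", {
  D <- array(1e-3, c(2, 1, 1, 6))
  D[2, 1, 1, 3] <- NaN
  expect_message(f <- tensor_field(D), "non-finite")
  expect_false(f$mask[2, 1, 1])
  expect_true(all(is.finite(f$D)))
})

test_that("shape metrics match the closed-form cases and sum to one", {
  expect_equal(shape_metrics(c(1, 1, 1))[1, ], c(CL = 0, CP = 0, CS = 1))
  expect_equal(shape_metrics(c(1, 0, 0))[1, ], c(CL = 1, CP = 0, CS = 0))
  expect_equal(shape_metrics(c(3, 2, 1))[1, ],
               c(CL = 1 / 6, CP = 1 / 3, CS = 1 / 2), tolerance = 1e-15)
  set.seed(7)
  sm <- shape_metrics(random_evals(1e4))
  expect_true(all(sm >= 0 & sm <= 1))
  expect_lt(max(abs(rowSums(sm) - 1)), 1e-12)
  expect_warning(z <- shape_metrics(c(0, 0, 0)), "zero-trace")
  expect_equal(z[1, ], c(CL = 0, CP = 0, CS = 1))
})

test_that("configuration classes follow the tolerance rule and scale invariance", {
  expect_equal(as.character(classify_configuration(c(1, 1, 1))), "ISOTROPIC")
  expect_equal(as.character(classify_configuration(c(1, 0.5, 0.5))), "PROLATE")
  expect_equal(as.character(classify_configuration(c(1, 0.98, 0.5))), "OBLATE")
  expect_equal(as.character(classify_configuration(c(3, 2, 1))), "ORTHOTROPIC")
  expect_equal(as.character(classify_configuration(c(0, 0, 0))), "ISOTROPIC")
  set.seed(12)
  ev <- random_evals(500)
  for (c_ in c(1e-3, 1, 42)) {
    expect_identical(classify_configuration(ev * c_), classify_configuration(ev))
  }
})
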