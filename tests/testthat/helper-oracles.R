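# Independent numerical oracles used to cross-check the implementation.
# Each oracle is implemented from first principles, never via the code path
# it validates.

# Gaussian curvature of the toroidal surface
#   T(theta, phi) = (cos(theta)(a + b cos(phi)), sin(theta)(a + b cos(phi)),
#                    g sin(phi))
# computed numerically from the first and second fundamental forms with
# central differences: K = (LN - M^2) / (EG - F^2). The step h = 1e-4 sits
# near the float64 optimum for second-derivative central differences
# (truncation O(h^2) ~ roundoff eps/h^2); much smaller steps amplify
# roundoff past the comparison tolerance.
numeric_gaussian_curvature <- function(a, b, g, phi, theta = 0.3, h = 1e-4) {
  surf <- function(th, ph) {
    c(cos(th) * (a + b * cos(ph)), sin(th) * (a + b * cos(ph)), g * sin(ph))
  }
  vapply(phi, function(ph) {
    r_t <- (surf(theta + h, ph) - surf(theta - h, ph)) / (2 * h)
    r_p <- (surf(theta, ph + h) - surf(theta, ph - h)) / (2 * h)
    r_tt <- (surf(theta + h, ph) - 2 * surf(theta, ph) + surf(theta - h, ph)) / h^2
    r_pp <- (surf(theta, ph + h) - 2 * surf(theta, ph) + surf(theta, ph - h)) / h^2
    r_tp <- (surf(theta + h, ph + h) - surf(theta + h, ph - h) -
             surf(theta - h, ph + h) + surf(theta - h, ph - h)) / (4 * h^2)
    E <- sum(r_t^2); Ff <- sum(r_t * r_p); G <- sum(r_p^2)
    n <- c(r_t[2] * r_p[3] - r_t[3] * r_p[2],
           r_t[3] * r_p[1] - r_t[1] * r_p[3],
           r_t[1] * r_p[2] - r_t[2] * r_p[1])
    n <- n / sqrt(sum(n^2))
    L <- sum(r_tt * n); M <- sum(r_tp * n); N <- sum(r_pp * n)
    (L * N - M^2) / (E * G - Ff^2)
  }, numeric(1))
}

# Exhaustive-permutation null for the (tie-free) Friedman statistic at k = 3:
# enumerate all 6^n within-subject rank orderings, return P(stat >= observed).
friedman_bruteforce_p <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(k == 3L, n <= 4L)
  stat_of <- function(ranks) {
    Rj <- colSums(ranks)
    12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  }
  obs <- stat_of(t(apply(mat, 1L, rank)))
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  combos <- expand.grid(rep(list(1:6), n))
  stats <- apply(combos, 1L, function(sel) {
    stat_of(perms[as.integer(sel), , drop = FALSE])
  })
  mean(stats >= obs - 1e-12)
}

# Two-sided exact sign-test p by direct binomial enumeration.
sign_test_enum_p <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  lower <- sum(probs[seq_len(k + 1)])          # P(X <= k)
  upper <- sum(probs[seq(k + 1, n + 1)])       # P(X >= k)
  min(1, 2 * min(lower, upper))
}

# Random sorted nonnegative eigenvalue triples in a diffusivity-like range.
random_evals <- function(n, min = 0, max = 2.5e-3) {
  ev <- matrix(stats::runif(3 * n, min, max), n, 3)
  t(apply(ev, 1L, sort, decreasing = TRUE))
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation_oracle <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Pack an n x 3 eigenvalue matrix into an axis-aligned tensor_field.
evals_to_field <- function(ev, dims) {
  stopifnot(nrow(ev) == prod(dims))
  D <- matrix(0, nrow(ev), 6L)
  D[, 1] <- ev[, 1]; D[, 4] <- ev[, 2]; D[, 6] <- ev[, 3]
  tensor_field(array(D, c(dims, 6L)))
}
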