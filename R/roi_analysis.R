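# ROI means and nonparametric cohort statistics: Friedman omnibus test across
# regions (repeated measures over subjects), post-hoc paired sign tests.

#' Per-region means of a scalar map
#'
#' Arithmetic mean of unmasked voxel values for each nonzero ROI label.
#'
#' @param map a \code{\link{scalar_map}}.
#' @param rois a \code{\link{roi_set}} on the same grid.
#' @return named numeric vector (tumor, edema, GM, WM).
#' @export
roi_means <- function(map, rois) {
  stopifnot(inherits(map, "scalar_map"), inherits(rois, "roi_set"))
  if (!identical(dim(map$values), dim(rois$labels)))
    stop("map and ROI grids differ")
  out <- vapply(1:4, function(l) {
    sel <- rois$labels == l & map$mask
    if (!any(sel)) stop("ROI '", rois$region_names[l],
                        "' is empty within the map mask")
    mean(map$values[sel])
  }, numeric(1))
  names(out) <- rois$region_names
  out
}

# Tie-corrected Friedman statistic from a subjects x regions matrix of
# within-subject mid-ranks. General rank-ANOVA form, reducing to the classic
# 12/(n k (k+1)) sum R_j^2 - 3 n (k+1) without ties.
friedman_statistic <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  Rj <- colSums(ranks)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)
  num / den
}

# Exact permutation p-value by dynamic programming over column rank-sum
# vectors, assuming no within-subject ties (all k!^n orderings equally
# likely under the null).
friedman_exact_p <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == k), , drop = FALSE]
  obs <- friedman_statistic(t(apply(mat, 1L, rank)))
  # distribution over rank-sum vectors
  states <- new.env(hash = TRUE)
  assign(paste(rep(0L, k), collapse = ","), 1, envir = states)
  for (s in seq_len(n)) {
    nxt <- new.env(hash = TRUE)
    for (key in ls(states)) {
      cnt <- get(key, envir = states)
      base <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      for (r in seq_len(nrow(perms))) {
        nk <- paste(base + perms[r, ], collapse = ",")
        prev <- if (exists(nk, envir = nxt, inherits = FALSE))
          get(nk, envir = nxt) else 0
        assign(nk, prev + cnt, envir = nxt)
      }
    }
    states <- nxt
  }
  total <- 0; hit <- 0
  denom_rank <- matrix(rep(seq_len(k), n), n, k, byrow = TRUE)
  den <- sum(denom_rank^2) - n * k * (k + 1)^2 / 4
  for (key in ls(states)) {
    cnt <- get(key, envir = states)
    Rj <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / den
    total <- total + cnt
    if (stat >= obs - 1e-12) hit <- hit + cnt
  }
  hit / total
}

#' Friedman rank test across regions
#'
#' Nonparametric repeated-measures omnibus test on a subjects x regions
#' matrix: within-subject mid-ranks, tie-corrected chi-squared statistic,
#' p-value from the upper tail of chi-squared with k-1 degrees of freedom.
#' For small tie-free designs (\code{exact = TRUE}, n <= 8) an exact
#' permutation p-value over all k!^n orderings is also computed.
#'
#' @param mat numeric matrix, subjects in rows, k >= 3 regions in columns,
#'   no missing cells.
#' @param exact also compute the exact permutation p (n <= 8, no ties).
#' @return list with \code{statistic}, \code{df}, \code{p.value}, and
#'   optionally \code{p.exact}.
#' @export
friedman_test <- function(mat, exact = FALSE) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("matrix has missing cells")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L) stop("need at least 2 subjects")
  if (k < 3L) stop("need at least 3 regions; use sign_test() for paired data")
  ranks <- t(apply(mat, 1L, rank))
  stat <- friedman_statistic(ranks)
  out <- list(statistic = stat, df = k - 1L,
              p.value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
              method = "Friedman rank test (tie-corrected chi-squared)")
  if (exact) {
    if (n > 8L) stop("exact permutation p-value supported for n <= 8 only")
    if (any(apply(mat, 1L, function(r) anyDuplicated(r) > 0)))
      stop("exact permutation p-value requires tie-free rows")
    out$p.exact <- friedman_exact_p(mat)
  }
  out
}

#' Exact paired sign test
#'
#' Two-sided exact binomial test with success probability 1/2 on the number
#' of positive differences among the informative (nonzero) pairs; zero
#' differences are dropped (the standard exact sign-test convention). If all
#' differences are zero, p = 1 with a warning.
#'
#' @param x paired differences, or first sample if \code{y} given.
#' @param y optional second sample (\code{x - y} is tested).
#' @return list with \code{n_informative}, \code{n_positive},
#'   \code{p.value}.
#' @export
sign_test <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(n_informative = 0L, n_positive = 0L, p.value = 1))
  }
  k <- sum(d > 0)
  p <- 2 * min(stats::pbinom(k, n, 0.5),
               stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
  list(n_informative = n, n_positive = k, p.value = min(p, 1))
}

#' Extract the subjects x regions x invariants ROI-mean array of a cohort
#'
#' Runs the full per-subject pipeline (eigendecomposition, invariant maps,
#' ROI averaging) over a cohort of tensor fields.
#'
#' @param cohort list of per-subject lists with \code{field} and \code{rois}
#'   (as returned by \code{\link{generate_cohort}}).
#' @param invariants character vector among MD, FA, TV, TC.
#' @return 3D array subjects x 4 regions x invariants.
#' @export
cohort_roi_means <- function(cohort, invariants = c("MD", "FA", "TV", "TC")) {
  stopifnot(length(cohort) >= 1L)
  invariants <- match.arg(invariants, several.ok = TRUE)
  out <- array(NA_real_, c(length(cohort), 4L, length(invariants)),
               dimnames = list(NULL, REGION_LEVELS, invariants))
  for (s in seq_along(cohort)) {
    eigs <- tensor_eigen(cohort[[s]]$field)
    for (inv in invariants) {
      m <- compute_map(eigs, inv)
      out[s, , inv] <- roi_means(m, cohort[[s]]$rois)
    }
  }
  out
}

#' Cohort ROI statistics: Friedman omnibus plus post-hoc sign tests
#'
#' For each invariant, tests for variation across the four regions with the
#' Friedman test; when the omnibus p-value falls below \code{alpha}, paired
#' sign tests are run on all six region pairs (gatekeeping by the omnibus
#' test, uncorrected pairwise p-values by default -- a Bonferroni option is
#' available).
#'
#' @param means subjects x regions x invariants array (see
#'   \code{\link{cohort_roi_means}}), or a subjects x regions matrix for a
#'   single invariant.
#' @param alpha significance level (default 0.05).
#' @param bonferroni correct post-hoc p-values for the 6 pairs
#'   (default FALSE).
#' @return An object of class \code{cohort_stats}: per-invariant omnibus
#'   results and a data.frame of pairwise tests.
#' @export
cohort_analysis <- function(means, alpha = 0.05, bonferroni = FALSE) {
  if (is.matrix(means)) {
    means <- array(means, c(dim(means), 1L),
                   dimnames = c(dimnames(means) %||% list(NULL, REGION_LEVELS),
                                list("value")))
  }
  stopifnot(length(dim(means)) == 3L)
  if (any(!is.finite(means))) {
    bad <- which(!is.finite(means), arr.ind = TRUE)
    stop("missing ROI means for subject(s) ",
         paste(unique(bad[, 1]), collapse = ", "))
  }
  regions <- dimnames(means)[[2]] %||% paste0("R", seq_len(dim(means)[2]))
  invs <- dimnames(means)[[3]] %||% paste0("inv", seq_len(dim(means)[3]))
  pairs <- utils::combn(seq_along(regions), 2L)
  omnibus <- list()
  ph <- list()
  for (inv in invs) {
    m <- means[, , inv, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(regions))
    fr <- friedman_test(m)
    omnibus[[inv]] <- fr
    if (fr$p.value < alpha) {
      for (c_ in seq_len(ncol(pairs))) {
        i <- pairs[1, c_]; j <- pairs[2, c_]
        st <- suppressWarnings(sign_test(m[, i], m[, j]))
        p <- st$p.value
        if (bonferroni) p <- min(1, p * ncol(pairs))
        ph[[length(ph) + 1L]] <- data.frame(
          invariant = inv, region1 = regions[i], region2 = regions[j],
          n_informative = st$n_informative, n_positive = st$n_positive,
          p.value = p, significant = p < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  posthoc <- if (length(ph)) do.call(rbind, ph) else
    data.frame(invariant = character(0), region1 = character(0),
               region2 = character(0), n_informative = integer(0),
               n_positive = integer(0), p.value = numeric(0),
               significant = logical(0))
  structure(list(means = means, omnibus = omnibus, posthoc = posthoc,
                 alpha = alpha, bonferroni = bonferroni),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats> %d subjects x %d regions, alpha = %g\n",
              dim(x$means)[1], dim(x$means)[2], x$alpha))
  for (inv in names(x$omnibus)) {
    o <- x$omnibus[[inv]]
    cat(sprintf("  %-3s Friedman chi2(%d) = %.3f, p = %.4g\n",
                inv, o$df, o$statistic, o$p.value))
  }
  sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant pairs (sign test):\n")
    for (r in seq_len(nrow(sig)))
      cat(sprintf("    %-3s %s vs %s: p = %.4g\n", sig$invariant[r],
                  sig$region1[r], sig$region2[r], sig$p.value[r]))
  }
  invisible(x)
}
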