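#' Mutual information between two expression profiles
#'
#' Estimates mutual information (in nats) between two sample-matched
#' expression vectors with a bivariate Gaussian kernel density estimator on
#' copula-transformed margins. Each vector is rank-transformed to the grid
#' \eqn{r/(n+1)}, so the estimate depends only on the joint ranking of the
#' two profiles: it is symmetric in its arguments and exactly invariant to
#' strictly monotone transforms of either one. Bandwidth follows the
#' bivariate rule of thumb \eqn{h = \sigma n^{-1/6}}. Negative estimates
#' (possible for near-independent pairs because of estimator bias) are
#' clipped at zero.
#'
#' @param x,y Numeric vectors of equal length (one value per sample).
#' @return Mutual information estimate in nats, a single non-negative number.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' estimate_mi(x, x + rnorm(100, sd = 0.2)) # strong dependence
#' estimate_mi(x, rnorm(100))               # near zero
#' @export
estimate_mi <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 samples are required for MI estimation")
  check_nonconstant(x, "x")
  check_nonconstant(y, "y")
  prep <- mi_prep(length(x))
  mi_from_ranks(mi_ranks(x), mi_ranks(y), prep)
}

check_nonconstant <- function(v, label) {
  if (anyNA(v)) stop("missing values in ", label)
  if (max(v) == min(v)) {
    stop("MI undefined for constant expression profile: ", label)
  }
  invisible(TRUE)
}

# Integer copula ranks; ties broken by position so the transform is a
# permutation of 1..n (required for the shared-grid kernel lookup).
mi_ranks <- function(v) rank(v, ties.method = "first")

# Precompute everything that depends only on the sample count: the kernel
# matrix over the rank grid and the (identical for every gene) log marginal
# density at the grid points.
mi_prep <- function(n) {
  grid <- seq_len(n) / (n + 1)
  h <- stats::sd(grid) * n^(-1 / 6)
  K0 <- stats::dnorm(outer(grid, grid, "-") / h)
  log_marg <- log(rowMeans(K0)) - log(h)
  list(n = n, h = h, K0 = K0,
       mean_log_marg = mean(log_marg),
       log_joint_norm = log(n * h * h))
}

# MI = mean_i log f(u_i, v_i) - mean_i log f(u_i) - mean_i log f(v_i); the
# marginal terms reduce to a constant because the copula ranks are a
# permutation of the grid.
mi_from_ranks <- function(rx, ry, prep) {
  A <- prep$K0[rx, rx]
  B <- prep$K0[ry, ry]
  m <- mean(log(.rowSums(A * B, prep$n, prep$n))) - prep$log_joint_norm -
    2 * prep$mean_log_marg
  max(m, 0)
}

#' Fit a permutation null model for mutual information
#'
#' Builds the null distribution of MI under the hypothesis of statistical
#' independence by estimating MI between randomly chosen gene pairs after
#' permuting the sample order of one member. Because the estimator is
#' rank-based, this null depends only on the number of samples. To reach
#' p-values far beyond the empirical resolution \eqn{1/n_{perm}} (the
#' network threshold is typically 1e-8), an exponential tail is fitted to
#' the exceedances over the empirical 95th percentile (widened just enough
#' to keep at least 20 exceedances at small `n_perm`) and survival
#' probabilities beyond it are obtained by extrapolation.
#'
#' @param expr Numeric gene-by-sample matrix (log scale) with row names.
#' @param n_perm Number of permuted pairs to draw (>= 100).
#' @param n_pairs_tested Number of hypotheses the Bonferroni correction
#'   should account for; defaults via [build_edge_list()] to
#'   `length(regulators) * (nrow(expr) - 1)`.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `mi_null` with the sorted null MI sample, the
#'   tail threshold and fitted rate, and `n_pairs_tested`.
#' @seealso [mi_pvalue()], [build_edge_list()]
#' @export
fit_mi_null <- function(expr, n_perm = 1000L, n_pairs_tested, seed = 1L) {
  expr <- as_expression_matrix(expr)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  n <- ncol(expr)
  prep <- mi_prep(n)
  rk <- apply(expr, 1L, mi_ranks)           # samples x genes
  withr_seed(seed, {
    null_mi <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      gp <- sample.int(nrow(expr), 2L)
      null_mi[b] <- mi_from_ranks(rk[, gp[1L]], rk[sample.int(n), gp[2L]],
                                  prep)
    }
  })
  null_mi <- sort(null_mi)
  # upper 5% of the null, widened when needed so the fit always sees at
  # least 20 exceedances
  tail_frac <- max(0.05, 20 / n_perm)
  thr <- stats::quantile(null_mi, 1 - tail_frac, names = FALSE)
  exceed <- null_mi[null_mi > thr] - thr
  if (length(exceed) < 20L) {
    stop("too few permutations for the exponential tail fit ",
         "(need >= 20 distinct points above the tail threshold)")
  }
  structure(list(null_mi = null_mi,
                 tail_threshold = thr,
                 tail_surv = (1 + sum(null_mi >= thr)) / (n_perm + 1),
                 rate = 1 / mean(exceed),
                 n_perm = n_perm,
                 n_samples = n,
                 n_pairs_tested = if (missing(n_pairs_tested)) NA_real_
                                  else n_pairs_tested,
                 seed = seed),
            class = "mi_null")
}

#' P-values from a fitted MI null model
#'
#' Maps MI values to independence-test p-values: the empirical survival
#' function (with a +1 pseudocount) below the tail threshold and the fitted
#' exponential tail above it. The map is monotone non-increasing in MI.
#' With `corrected = TRUE` the p-value is Bonferroni-corrected as
#' `min(1, p * n_pairs_tested)`.
#'
#' @param null An `mi_null` object from [fit_mi_null()].
#' @param mi Numeric vector of MI values.
#' @param corrected Apply the Bonferroni correction recorded in the null?
#' @return Numeric vector of p-values in (0, 1].
#' @export
mi_pvalue <- function(null, mi, corrected = TRUE) {
  stopifnot(inherits(null, "mi_null"))
  nm <- null$null_mi
  np <- null$n_perm
  # count of null values >= mi via the sorted sample
  n_ge <- np - findInterval(mi, nm, left.open = TRUE)
  p <- (1 + n_ge) / (np + 1)
  hi <- mi > null$tail_threshold
  p[hi] <- null$tail_surv * exp(-null$rate * (mi[hi] - null$tail_threshold))
  if (corrected) {
    if (is.na(null$n_pairs_tested)) {
      stop("null model carries no n_pairs_tested; fit it with one or use ",
           "corrected = FALSE")
    }
    p <- p * null$n_pairs_tested
  }
  pmin(p, 1)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' @export
print.mi_null <- function(x, ...) {
  cat("MI permutation null model\n")
  cat(sprintf("  permutations: %d  (samples per profile: %d)\n",
              x$n_perm, x$n_samples))
  cat(sprintf("  95%% tail threshold: %.4g nats, tail rate: %.4g\n",
              x$tail_threshold, x$rate))
  cat(sprintf("  Bonferroni pairs: %s\n",
              ifelse(is.na(x$n_pairs_tested), "not set",
                     format(x$n_pairs_tested))))
  invisible(x)
}
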