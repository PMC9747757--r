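#' Active-node density series
#'
#' \eqn{\rho_1(t)}: the fraction of nodes/channels active in each time bin.
#' Accepts a binary raster matrix (rows = nodes, columns = bins), a
#' \code{cbm_sim}, or a per-bin active-count vector together with
#' \code{n_nodes}.
#'
#' @param x raster matrix, \code{cbm_sim} object, or integer count vector.
#' @param n_nodes node count (required when \code{x} is a count vector).
#' @return Object of class \code{activity_series}: list with \code{rho}
#'   (density per bin, in [0, 1]) and \code{n_nodes}.
#' @export
activity_series <- function(x, n_nodes = NULL) {
  if (inherits(x, "cbm_sim")) {
    counts <- x$counts
    n_nodes <- x$config$n_nodes
  } else if (is.matrix(x)) {
    counts <- colSums(x != 0)
    n_nodes <- nrow(x)
  } else {
    if (is.null(n_nodes))
      stop("n_nodes is required for a count vector", call. = FALSE)
    counts <- x
  }
  if (any(counts < 0) || any(counts > n_nodes))
    stop("counts outside [0, n_nodes]", call. = FALSE)
  structure(list(rho = as.numeric(counts) / n_nodes,
                 n_nodes = as.integer(n_nodes)),
            class = "activity_series")
}

#' @rdname activity_series
#' @export
activity_density <- function(x, n_nodes = NULL) activity_series(x, n_nodes)

as_activity_series <- function(x, n_nodes = NULL) {
  if (inherits(x, "activity_series")) x else activity_series(x, n_nodes)
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("activity series: %d bins, N = %d, mean density %.4g\n",
              length(x$rho), x$n_nodes, mean(x$rho)))
  invisible(x)
}

#' Dynamical susceptibility
#'
#' \eqn{\chi = N[\langle\rho_1^2\rangle_T - \langle\rho_1\rangle_T^2]}: the
#' node count times the population (not sample) temporal variance of the
#' active-node density.  \eqn{\chi} peaks in the quasicritical region and its
#' maximum over \eqn{\kappa} traces the Widom line as \eqn{p_s} varies.
#'
#' @param series an \code{\link{activity_series}} (or anything it accepts).
#' @param n_nodes passed through when \code{series} is a count vector.
#' @return Non-negative scalar.
#' @examples
#' susceptibility(activity_series(c(0L, 2L, 0L, 2L), n_nodes = 2))  # 0.5
#' @export
susceptibility <- function(series, n_nodes = NULL) {
  s <- as_activity_series(series, n_nodes)
  if (length(s$rho) < 2)
    stop("need at least 2 time bins", call. = FALSE)
  rho <- s$rho
  s$n_nodes * (mean(rho^2) - mean(rho)^2)
}

#' Local time fluctuation
#'
#' \eqn{\mathrm{LTF} = \sqrt{\chi/N}\,/\,\langle\rho_1\rangle_T}, a
#' coefficient-of-variation-like measure of firing-rate variability.
#' Values above 1 indicate bursting activity, below 1 regular activity.
#'
#' @inheritParams susceptibility
#' @return Non-negative scalar.
#' @export
ltf <- function(series, n_nodes = NULL) {
  s <- as_activity_series(series, n_nodes)
  m <- mean(s$rho)
  if (m <= 0)
    stop("undefined metric: mean activity density is zero", call. = FALSE)
  sqrt(susceptibility(s) / s$n_nodes) / m
}

#' Variance of avalanche sizes
#'
#' Population variance \eqn{\mathrm{var}(S) = \langle S^2\rangle - \langle
#' S\rangle^2} over an avalanche catalog; tracks the susceptibility across
#' subjects.
#'
#' @param catalog an \code{\link{extract_avalanches}} catalog, or a numeric
#'   vector of sizes.
#' @return Non-negative scalar.
#' @export
avalanche_size_variance <- function(catalog) {
  sizes <- if (is.data.frame(catalog)) catalog$size else as.numeric(catalog)
  if (length(sizes) < 2)
    stop("undefined metric: need at least 2 avalanches", call. = FALSE)
  mean(sizes^2) - mean(sizes)^2
}

#' Naive branching ratio
#'
#' The classical estimator: the mean over avalanches of the ratio of events
#' in the avalanche's second bin to events in its first bin, with the second
#' bin counted as zero for avalanches of duration 1.  Including the
#' single-bin avalanches keeps the estimator unbiased for a branching
#' process (mean offspring \eqn{\kappa}); conditioning on survival would
#' inflate it.  Known to be biased downward under spatial subsampling, which
#' motivates the multistep-regression estimator \code{\link{branching_mr}}.
#'
#' @param x binary raster matrix, \code{cbm_sim}, or per-bin count vector.
#' @return Scalar estimate of the branching ratio \eqn{\sigma}.
#' @export
branching_naive <- function(x) {
  counts <- bin_counts_of(x)
  runs <- activity_runs(counts, drop_edges = TRUE)
  if (nrow(runs) < 1)
    stop("undefined metric: no complete avalanches", call. = FALSE)
  first <- counts[runs$start]
  second <- ifelse(runs$duration >= 2, counts[runs$start + 1L], 0L)
  mean(second / first)
}

#' Multistep-regression branching ratio
#'
#' For each lag \eqn{k = 1..k_{max}} the linear-regression slope \eqn{r_k}
#' of activity \eqn{a(t+k)} on \eqn{a(t)} is computed; under a stationary
#' branching process with drive, \eqn{r_k = A\,m^k}, so \eqn{m} is
#' recovered by an ordinary least-squares fit of \eqn{\log r_k} against
#' \eqn{k} over the lags with positive slope.  Unlike the naive estimator,
#' the multistep regression is robust to spatial subsampling (the
#' subsampling bias is absorbed by the amplitude \eqn{A}).
#'
#' @param series per-bin activity: an \code{\link{activity_series}}, count
#'   vector, raster matrix or \code{cbm_sim}.  Per-bin totals (counts) and
#'   densities give identical results — the estimator is invariant under
#'   positive scaling.
#' @param k_max maximum regression lag (default 40 bins).
#' @return List of class \code{branching_mr_fit}: \code{m} (the branching
#'   ratio), \code{stderr}, \code{slopes} (the \eqn{r_k}), \code{k_used}.
#' @export
branching_mr <- function(series, k_max = 40L) {
  a <- if (inherits(series, "activity_series")) series$rho
       else if (inherits(series, "cbm_sim")) as.numeric(series$counts)
       else if (is.matrix(series)) as.numeric(colSums(series != 0))
       else as.numeric(series)
  n <- length(a)
  k_max <- as.integer(k_max)
  if (n <= k_max + 1L)
    stop("series too short for k_max = ", k_max, call. = FALSE)
  r_k <- vapply(seq_len(k_max), function(k) {
    x <- a[seq_len(n - k)]
    y <- a[seq_len(n - k) + k]
    vx <- stats::var(x)
    if (vx == 0) return(NA_real_)
    stats::cov(x, y) / vx
  }, numeric(1))
  use <- which(is.finite(r_k) & r_k > 0)
  if (length(use) < 2 || !is.finite(r_k[1]) || r_k[1] <= 0)
    stop("fit failure: no positive multistep slopes", call. = FALSE)
  # initialize from log-space OLS, then refit r_k = A m^k by least squares
  # in linear space (the log fit is biased low where r_k is small and noisy)
  init <- stats::coef(stats::lm(log(r_k[use]) ~ use))
  kk <- which(is.finite(r_k))
  obj <- function(p) sum((r_k[kk] - exp(p[1]) * exp(p[2])^kk)^2)
  opt <- stats::optim(c(init[1], init[2]), obj)
  m <- exp(opt$par[2])
  # stderr of m from the curvature of the residual surface
  resid_var <- opt$value / max(length(kk) - 2L, 1L)
  h <- 1e-4
  d2 <- (obj(opt$par + c(0, h)) - 2 * opt$value +
         obj(opt$par - c(0, h))) / h^2
  se_log_m <- if (is.finite(d2) && d2 > 0) sqrt(2 * resid_var / d2)
              else NA_real_
  structure(list(m = unname(m), stderr = unname(m * se_log_m),
                 slopes = r_k, k_used = kk),
            class = "branching_mr_fit")
}

#' @export
print.branching_mr_fit <- function(x, ...) {
  cat(sprintf("multistep-regression branching ratio: m = %.4f (SE %.4f), %d lags\n",
              x$m, x$stderr, length(x$k_used)))
  invisible(x)
}

# per-bin total event counts from the accepted raster-like inputs
bin_counts_of <- function(x) {
  if (inherits(x, "cbm_sim")) return(as.integer(x$counts))
  if (is.matrix(x)) return(as.integer(colSums(x != 0)))
  as.integer(x)
}
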