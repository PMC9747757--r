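#' Fit the gamma-scaling line over a cohort
#'
#' Ordinary least squares of the effective duration exponent
#' \eqn{\tilde\tau_T} on the size exponent \eqn{\tilde\tau_S} over a cohort
#' of exponent pairs.  Quasicritical systems organize along the line
#' \eqn{\tilde\tau_T - 1 = \gamma(\tilde\tau_S - 1)}; the fitted slope is
#' the cohort-level \eqn{\gamma_{lsf}}.
#'
#' @param pairs data frame with columns \code{tau_S} and \code{tau_T} (one
#'   row per subject), or a two-column matrix.
#' @return Object of class \code{scaling_line}: \code{slope},
#'   \code{intercept}, \code{slope_err}, \code{n}.
#' @examples
#' p <- data.frame(tau_S = c(1.4, 1.6, 1.8), tau_T = c(1.6, 1.9, 2.2))
#' fit_scaling_line(p)
#' @export
fit_scaling_line <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("tau_S", "tau_T") %in% names(pairs)))
    names(pairs)[1:2] <- c("tau_S", "tau_T")
  if (nrow(pairs) < 3)
    stop("fit failure: need at least 3 exponent pairs", call. = FALSE)
  if (stats::sd(pairs$tau_S) == 0)
    stop("fit failure: degenerate abscissa (all tau_S equal)", call. = FALSE)
  fit <- stats::lm(tau_T ~ tau_S, data = pairs)
  sl <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = sl["tau_S", "Estimate"],
                 intercept = sl["(Intercept)", "Estimate"],
                 slope_err = sl["tau_S", "Std. Error"],
                 n = nrow(pairs)),
            class = "scaling_line")
}

#' @export
print.scaling_line <- function(x, ...) {
  cat(sprintf("gamma-scaling line: slope %.3f +/- %.3f, intercept %.3f (n = %d)\n",
              x$slope, x$slope_err, x$intercept, x$n))
  invisible(x)
}

#' Normalized position on the gamma-scaling line
#'
#' The cohort biomarker: (1) all points are shifted vertically by the line's
#' intercept so the line passes through the origin; (2) each shifted vector
#' \eqn{(\tilde\tau_S, \tilde\tau_T - c)} is scalar-projected onto the unit
#' vector along the shifted line; (3) projections are divided by the cohort
#' maximum, so values lie in [0, 1] with the maximum exactly 1.
#'
#' Because the normalization is cohort-relative, positions are comparable
#' only within one jointly normalized cohort — never across separately
#' processed cohorts.
#'
#' @param pairs data frame with \code{tau_S}, \code{tau_T} (or two-column
#'   matrix), one row per subject.
#' @param line a \code{\link{fit_scaling_line}} result (or any list with
#'   \code{slope} and \code{intercept}).
#' @return Numeric vector of positions in [0, 1], one per row of
#'   \code{pairs}.
#' @export
position_on_line <- function(pairs, line) {
  pairs <- as.data.frame(pairs)
  if (!all(c("tau_S", "tau_T") %in% names(pairs)))
    names(pairs)[1:2] <- c("tau_S", "tau_T")
  u <- c(1, line$slope) / sqrt(1 + line$slope^2)
  proj <- pairs$tau_S * u[1] + (pairs$tau_T - line$intercept) * u[2]
  m <- max(proj)
  if (!is.finite(m) || m <= 0)
    stop("degenerate cohort: non-positive maximum projection", call. = FALSE)
  proj / m
}
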