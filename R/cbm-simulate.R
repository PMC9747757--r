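#' Simulate the cortical branching model
#'
#' Runs the CBM automaton from an all-quiescent start, discards
#' \code{config$burn_in} steps, and records \code{config$n_steps} steps.  At
#' each step a quiescent node becomes active if any active in-neighbour's
#' edge transmits (uniform draw \eqn{\le P_{ij}}) or it activates
#' spontaneously (draw \eqn{\le p_s}); an active node is refractory for
#' \eqn{\tau_r} steps afterwards, during which it cannot activate at all.
#'
#' The per-step active counts are always returned; the full binary raster is
#' kept only when \code{keep_raster = TRUE} (memory is
#' \code{n_nodes * n_steps} entries, so leave it off for long runs — all
#' avalanche and activity statistics in this package work on the count
#' series).
#'
#' @param config a \code{\link{cbm_config}}.
#' @param network optional pre-built \code{\link{build_network}} result; by
#'   default a network is built (reproducibly) from the config seed.
#' @param keep_raster keep the full node-by-time binary raster?
#' @return An object of class \code{cbm_sim}: list with \code{counts}
#'   (integer vector of active nodes per step), \code{raster}
#'   (\code{n_nodes x n_steps} logical matrix or \code{NULL}),
#'   \code{network} and \code{config}.
#' @examples
#' sim <- simulate_cbm(cbm_config(n_nodes = 64, kappa = 1.05, bias = 1.8,
#'                                n_steps = 2000, seed = 42))
#' mean(sim$counts) / 64  # mean active-node density
#' @export
simulate_cbm <- function(config, network = NULL, keep_raster = FALSE) {
  validate_cbm_config(config)
  set.seed(config$seed)
  if (is.null(network)) network <- build_network(config)
  out <- .cbm_run_cpp(network$in_src, network$p_edge, config$p_s,
                      config$refractory, config$n_steps, config$burn_in,
                      keep_raster)
  res <- list(counts = out$counts,
              raster = if (keep_raster) out$raster else NULL,
              network = network, config = config)
  class(res) <- "cbm_sim"
  res
}

#' @export
print.cbm_sim <- function(x, ...) {
  cat(sprintf("CBM simulation: %d nodes, %d steps, kappa %.4g, bias %.3g\n",
              x$config$n_nodes, length(x$counts), x$config$kappa,
              x$config$bias))
  cat(sprintf("  mean density %.4g, raster %s\n",
              mean(x$counts) / x$config$n_nodes,
              if (is.null(x$raster)) "not kept" else "kept"))
  invisible(x)
}

#' Seeded avalanches of the noise-free CBM
#'
#' With \eqn{p_s = 0} the quiescent state is absorbing, so avalanches are
#' produced by repeatedly activating one random node and running the
#' automaton to extinction.  In the subcritical regime (\eqn{\kappa < 1},
#' large network, rare refractory collisions) this is a Galton-Watson
#' branching process with mean offspring \eqn{\kappa}, whose expected total
#' size is \eqn{1/(1-\kappa)} — the closed form used to validate the
#' automaton.
#'
#' @param config a \code{\link{cbm_config}} (its \code{p_s} is ignored;
#'   dynamics run noise-free).
#' @param n_avalanches number of seeded avalanches to run.
#' @param max_steps per-avalanche step cap (guards supercritical runs).
#' @return List with integer vectors \code{sizes} and \code{durations}, and
#'   \code{counts}: the concatenated per-step active counts of all
#'   avalanches, separated by single empty steps (usable with
#'   \code{\link{extract_avalanches}} and \code{\link{branching_naive}}).
#' @examples
#' av <- seeded_avalanches(cbm_config(kappa = 0.8, seed = 7), 2000)
#' mean(av$sizes)  # ~ 1 / (1 - 0.8) = 5
#' @export
seeded_avalanches <- function(config, n_avalanches, max_steps = 1e5L) {
  validate_cbm_config(config)
  stopifnot(n_avalanches >= 1)
  set.seed(config$seed)
  network <- build_network(config)
  .cbm_avalanches_cpp(network$in_src, network$p_edge, config$refractory,
                      as.integer(n_avalanches), as.integer(max_steps))
}

#' Susceptibility sweep over the branching parameter
#'
#' Repeats CBM simulations on a grid of \eqn{\kappa} values and computes the
#' dynamical susceptibility \eqn{\chi = N[\langle\rho_1^2\rangle -
#' \langle\rho_1\rangle^2]} of each run, locating the susceptibility peak
#' that marks the quasicritical region (the Widom line point for the given
#' \eqn{p_s}).
#'
#' @param config a \code{\link{cbm_config}} template; its \code{kappa} is
#'   overridden by the grid and its seed is the master seed for the sweep.
#' @param kappa_grid numeric vector of branching-parameter values.
#' @param reps independent runs per grid point (different seeds).
#' @return A data frame of class \code{kappa_sweep} with columns
#'   \code{kappa}, \code{chi_mean}, \code{chi_sd}; attribute
#'   \code{peak_kappa} holds the grid value maximizing \code{chi_mean}.
#' @export
kappa_sweep <- function(config, kappa_grid, reps = 3L) {
  if (length(kappa_grid) == 0)
    stop("invalid argument: kappa_grid must be non-empty", call. = FALSE)
  stopifnot(reps >= 1)
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max,
                          length(kappa_grid) * reps)
  dim(run_seeds) <- c(reps, length(kappa_grid))
  chi <- matrix(NA_real_, reps, length(kappa_grid))
  for (g in seq_along(kappa_grid)) {
    for (r in seq_len(reps)) {
      cfg <- config
      cfg$kappa <- kappa_grid[g]
      cfg$seed <- run_seeds[r, g]
      sim <- simulate_cbm(cfg)
      chi[r, g] <- susceptibility(activity_series(sim))
    }
  }
  out <- data.frame(kappa = kappa_grid,
                    chi_mean = colMeans(chi),
                    chi_sd = apply(chi, 2, sd))
  attr(out, "peak_kappa") <- kappa_grid[which.max(out$chi_mean)]
  class(out) <- c("kappa_sweep", "data.frame")
  out
}

#' @export
print.kappa_sweep <- function(x, ...) {
  cat(sprintf("kappa sweep, peak at kappa = %.4g\n", attr(x, "peak_kappa")))
  print.data.frame(x, ...)
  invisible(x)
}
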