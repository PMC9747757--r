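#' Configuration for the cortical branching model
#'
#' Bundles the parameters of the CBM automaton: a random directed network of
#' \code{n_nodes} nodes, each receiving exactly \code{k_in} inbound
#' connections whose unscaled transmission probabilities follow the
#' exponential weighting function with bias \code{bias} (see
#' \code{\link{weighting_probabilities}}), scaled by the branching parameter
#' \code{kappa}.  Nodes activate spontaneously with probability \code{p_s}
#' per step and are refractory for \code{refractory} steps after firing.
#'
#' @param n_nodes number of nodes (default 256).
#' @param k_in inbound degree of every node (default 5); must be
#'   smaller than \code{n_nodes}.
#' @param kappa branching parameter \eqn{\kappa \ge 0} scaling all
#'   transmission probabilities; \eqn{\kappa = 1} with \code{p_s = 0} is the
#'   critical point.
#' @param p_s per-node, per-step spontaneous activation probability in
#'   [0, 1] (default \code{1e-3}).
#' @param bias exponential weighting bias \eqn{B \ge 0}; 0 gives homogeneous
#'   inbound weights, larger values give few strong and many weak
#'   connections.
#' @param refractory refractory period \eqn{\tau_r} in steps (default 1).
#' @param n_steps number of recorded time steps.
#' @param burn_in steps discarded before recording (default 1000).
#' @param seed integer seed governing wiring and dynamics.
#' @return An object of class \code{cbm_config} (a validated list).
#' @examples
#' cfg <- cbm_config(kappa = 1.07, bias = 1.8, n_steps = 1e4, seed = 1)
#' cfg
#' @export
cbm_config <- function(n_nodes = 256L, k_in = 5L, kappa = 1, p_s = 1e-3,
                       bias = 0, refractory = 1L, n_steps = 1e5L,
                       burn_in = 1000L, seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes), k_in = as.integer(k_in),
              kappa = as.numeric(kappa), p_s = as.numeric(p_s),
              bias = as.numeric(bias), refractory = as.integer(refractory),
              n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
              seed = as.integer(seed))
  validate_cbm_config(cfg)
  class(cfg) <- "cbm_config"
  cfg
}

validate_cbm_config <- function(cfg) {
  stopifnot(cfg$n_nodes >= 2L, cfg$k_in >= 1L)
  if (cfg$k_in >= cfg$n_nodes)
    stop("invalid argument: k_in must be smaller than n_nodes", call. = FALSE)
  if (cfg$p_s < 0 || cfg$p_s > 1)
    stop("invalid argument: p_s must lie in [0, 1]", call. = FALSE)
  if (cfg$kappa < 0) stop("invalid argument: kappa must be >= 0", call. = FALSE)
  if (cfg$bias < 0) stop("invalid argument: bias must be >= 0", call. = FALSE)
  if (cfg$refractory < 0L)
    stop("invalid argument: refractory must be >= 0", call. = FALSE)
  stopifnot(cfg$n_steps >= 1L, cfg$burn_in >= 0L)
  invisible(cfg)
}

#' @export
print.cbm_config <- function(x, ...) {
  cat("CBM configuration\n")
  cat(sprintf("  nodes %d, k_in %d, kappa %.4g, p_s %.3g, bias %.3g, tau_r %d\n",
              x$n_nodes, x$k_in, x$kappa, x$p_s, x$bias, x$refractory))
  cat(sprintf("  steps %d (+ %d burn-in), seed %d\n",
              x$n_steps, x$burn_in, x$seed))
  invisible(x)
}

#' Read a CBM configuration from a YAML file
#'
#' Keys are the argument names of \code{\link{cbm_config}}; missing keys take
#' the defaults.
#'
#' @param path path to a YAML file.
#' @return A \code{\link{cbm_config}} object.
#' @export
read_cbm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cbm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown CBM config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(cbm_config, vals)
}

#' Exponential inbound weighting function
#'
#' Unscaled transmission probabilities by inbound rank,
#' \eqn{p_n = e^{-Bn} / \sum_{m=1}^{k_{in}} e^{-Bm}} for
#' \eqn{n = 1, \dots, k_{in}}.  Rank 1 is the strongest inbound connection.
#' With \code{bias = 0} the distribution is homogeneous; as the bias grows
#' the weights become increasingly skewed (few strong, many weak), the
#' mechanism used to model aging connectivity.
#'
#' @param k_in number of inbound connections per node.
#' @param bias bias exponent \eqn{B \ge 0}.
#' @return Numeric vector of length \code{k_in}, decreasing, summing to 1.
#' @examples
#' weighting_probabilities(5, 0)    # rep(0.2, 5)
#' weighting_probabilities(5, 1.8)  # first weight ~0.835
#' @export
weighting_probabilities <- function(k_in, bias) {
  if (length(k_in) != 1L || is.na(k_in) || k_in < 1)
    stop("invalid argument: k_in must be a positive integer", call. = FALSE)
  if (length(bias) != 1L || is.na(bias) || bias < 0)
    stop("invalid argument: bias must be >= 0", call. = FALSE)
  k_in <- as.integer(k_in)
  w <- exp(-bias * seq_len(k_in))
  w / sum(w)
}
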