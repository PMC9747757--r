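#' Build the random directed CBM network
#'
#' Every node j draws \code{k_in} distinct source nodes (excluding itself)
#' uniformly at random; the inbound connections are ranked
#' \eqn{n_{ij} = 1, \dots, k_{in}} (rank 1 strongest) and carry unscaled
#' probabilities from \code{\link{weighting_probabilities}}, so each node's
#' inbound probabilities sum to one.  The transmission probability of an edge
#' is \eqn{P_{ij} = \kappa\, p_{n_{ij}}}.  Wirings whose underlying
#' undirected graph is not connected are resampled (up to
#' \code{max_attempts}) so that at least one path joins any two nodes.
#'
#' Consumes the R RNG: call \code{set.seed()} first (or use
#' \code{\link{simulate_cbm}}, which seeds from the config).
#'
#' @param config a \code{\link{cbm_config}}.
#' @param max_attempts resampling budget for the connectivity requirement.
#' @return An object of class \code{cbm_network}: list with \code{in_src}
#'   (\code{k_in x n_nodes} integer matrix, column j = ranked sources of
#'   node j), \code{in_p} (matching unscaled probabilities), \code{p_edge}
#'   (\code{kappa * in_p}), and the config.
#' @examples
#' set.seed(1)
#' net <- build_network(cbm_config(n_nodes = 20, k_in = 3, kappa = 0.9))
#' colSums(net$in_p)  # all 1
#' @export
build_network <- function(config, max_attempts = 1000L) {
  validate_cbm_config(config)
  n <- config$n_nodes
  k <- config$k_in
  p_rank <- weighting_probabilities(k, config$bias)
  for (attempt in seq_len(max_attempts)) {
    in_src <- vapply(seq_len(n),
                     function(j) sample.int(n - 1L, k),
                     integer(k))
    # map 1..n-1 onto 1..n skipping j (no self-loops); sample order = rank
    in_src <- in_src + (in_src >= matrix(rep(seq_len(n), each = k), k, n))
    if (network_is_connected(in_src, n)) {
      in_p <- matrix(p_rank, nrow = k, ncol = n)
      net <- list(in_src = in_src, in_p = in_p,
                  p_edge = config$kappa * in_p, config = config)
      class(net) <- "cbm_network"
      return(net)
    }
  }
  stop("construction failure: no connected wiring found in ", max_attempts,
       " attempts", call. = FALSE)
}

network_is_connected <- function(in_src, n) {
  edges <- cbind(as.vector(in_src), rep(seq_len(n), each = nrow(in_src)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::vcount(g) == n && igraph::is_connected(g)
}

#' @export
print.cbm_network <- function(x, ...) {
  cat(sprintf("CBM network: %d nodes, k_in = %d, kappa = %.4g, bias = %.3g\n",
              x$config$n_nodes, x$config$k_in, x$config$kappa, x$config$bias))
  invisible(x)
}
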