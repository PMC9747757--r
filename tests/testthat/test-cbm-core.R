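# CBM configuration, weighting function, network construction

test_that("weighting probabilities are normalized, monotone, and match the
           exponential form", {
  expect_equal(weighting_probabilities(5, 0), rep(0.2, 5))
  expect_equal(weighting_probabilities(1, 3.7), 1.0)
  # direct hand evaluation of e^{-Bn} / sum e^{-Bm}
  w <- exp(-1.8 * 1:5)
  expect_equal(weighting_probabilities(5, 1.8), w / sum(w))
  expect_equal(weighting_probabilities(5, 1.8)[1], 0.835, tolerance = 1e-3)
  for (B in c(0.3, 0.6, 1.8, 4)) {
    p <- weighting_probabilities(7, B)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) < 0))
  }
  expect_error(weighting_probabilities(0, 1), "positive")
  expect_error(weighting_probabilities(3, -1), ">= 0")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(cbm_config(n_nodes = 5, k_in = 5), "k_in")
  expect_error(cbm_config(p_s = 1.5), "p_s")
  expect_error(cbm_config(kappa = -0.1), "kappa")
})

test_that("network has exact in-degree, unit inbound weight sums, no self
           loops, and is reproducible", {
  cfg <- cbm_config(n_nodes = 40, k_in = 5, kappa = 1.07, bias = 1.8,
                    seed = 5)
  set.seed(5)
  net <- build_network(cfg)
  expect_identical(dim(net$in_src), c(5L, 40L))
  expect_equal(unname(colSums(net$in_p)), rep(1, 40), tolerance = 1e-12)
  expect_true(all(net$p_edge >= 0 & net$p_edge <= cfg$kappa))
  for (j in 1:40) {
    expect_false(any(net$in_src[, j] == j))
    expect_equal(anyDuplicated(net$in_src[, j]), 0L)
  }
  # strongest inbound connection carries rank-1 weight
  expect_equal(net$in_p[1, 1], weighting_probabilities(5, 1.8)[1])
  set.seed(5)
  net2 <- build_network(cfg)
  expect_identical(net$in_src, net2$in_src)
})

test_that("two-node network with k_in = 1 wires each node to the other", {
  set.seed(1)
  net <- build_network(cbm_config(n_nodes = 2, k_in = 1, kappa = 1, bias = 0))
  expect_equal(as.vector(net$in_src), c(2L, 1L))
  expect_equal(as.vector(net$p_edge), c(1, 1))
})

test_that("simulation is deterministic and respects absorbing / forced
           regimes", {
  cfg <- small_cfg(seed = 77)
  s1 <- simulate_cbm(cfg, keep_raster = TRUE)
  s2 <- simulate_cbm(cfg, keep_raster = TRUE)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$network$in_src, s2$network$in_src)

  # p_s = 0 from all-quiescent start: absorbing, all zero
  s0 <- simulate_cbm(small_cfg(p_s = 0, burn_in = 0))
  expect_true(all(s0$counts == 0L))

  # p_s = 1, tau_r = 1: forced alternation, density 1/2
  sf <- simulate_cbm(small_cfg(n_nodes = 8, k_in = 2, kappa = 0, p_s = 1,
                               n_steps = 1000, burn_in = 0))
  expect_equal(mean(sf$counts) / 8, 0.5, tolerance = 0.01)
  expect_true(all(sf$counts %in% c(0L, 8L)))

  # refractoriness: a node active at t is never active at t+1
  sr <- simulate_cbm(small_cfg(kappa = 1.2, p_s = 0.05, n_steps = 2000),
                     keep_raster = TRUE)
  both <- sr$raster[, -1] & sr$raster[, -ncol(sr$raster)]
  expect_false(any(both))
})

test_that("raster and counts agree and density stays in [0, 1]", {
  sim <- simulate_cbm(small_cfg(n_steps = 2000), keep_raster = TRUE)
  expect_equal(as.integer(colSums(sim$raster)), as.integer(sim$counts))
  rho <- activity_series(sim)$rho
  expect_true(all(rho >= 0 & rho <= 1))
})

test_that("certain transmission propagates activity to the target", {
  # 2-node loop with P = 1 and one seeded avalanche: the activation ping-pongs
  av <- seeded_avalanches(cbm_config(n_nodes = 2, k_in = 1, kappa = 1,
                                     bias = 0, p_s = 0, seed = 3),
                          n_avalanches = 5, max_steps = 50)
  expect_true(all(av$durations == 50))  # never dies: certain transmission
})

test_that("subcritical seeded avalanches match the Galton-Watson mean size
           1/(1-kappa)", {
  for (kap in c(0.5, 0.8)) {
    av <- seeded_avalanches(cbm_config(kappa = kap, p_s = 0, bias = 1.0,
                                       seed = 11), n_avalanches = 4000)
    expect_equal(mean(av$sizes), 1 / (1 - kap), tolerance = 0.05)
  }
})

test_that("increasing p_s concatenates avalanches (mean duration does not
           decrease)", {
  mean_dur <- function(ps) {
    sim <- simulate_cbm(small_cfg(kappa = 0.9, p_s = ps, n_steps = 3e4,
                                  seed = 21))
    mean(extract_avalanches(sim)$duration)
  }
  d <- vapply(c(1e-4, 1e-3, 5e-3), mean_dur, numeric(1))
  expect_true(all(is.finite(d)))
  expect_true(all(diff(d) >= 0))
})

test_that("kappa sweep returns the grid, a peak, and errors on empty grid", {
  cfg <- small_cfg(n_steps = 3000)
  sw <- kappa_sweep(cfg, kappa_grid = c(0.6, 0.9, 1.05), reps = 2)
  expect_equal(sw$kappa, c(0.6, 0.9, 1.05))
  expect_true(attr(sw, "peak_kappa") %in% sw$kappa)
  expect_true(all(sw$chi_mean >= 0))
  # chi vanishes deep in the subcritical regime
  expect_lt(sw$chi_mean[1], sw$chi_mean[3])
  expect_error(kappa_sweep(cfg, numeric(0)), "non-empty")
})

test_that("stronger spontaneous drive blunts the susceptibility peak", {
  peak_chi <- function(ps) {
    cfg <- cbm_config(n_nodes = 256, k_in = 5, p_s = ps, bias = 1.8,
                      n_steps = 1e5, seed = 31)
    sw <- kappa_sweep(cfg, kappa_grid = c(1.04, 1.07, 1.10), reps = 2)
    max(sw$chi_mean)
  }
  chis <- vapply(c(1e-3, 1e-2, 5e-2), peak_chi, numeric(1))
  expect_true(all(diff(chis) < 0))
})

test_that("YAML config round-trips", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_nodes: 64", "k_in: 4", "kappa: 1.05", "bias: 1.8",
               "p_s: 0.001", "n_steps: 1000", "seed: 9"), path)
  cfg <- read_cbm_config(path)
  expect_s3_class(cfg, "cbm_config")
  expect_equal(cfg$kappa, 1.05)
  expect_equal(cfg$n_nodes, 64L)
  writeLines("nonsense_key: 1", path)
  expect_error(read_cbm_config(path), "unknown")
})
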