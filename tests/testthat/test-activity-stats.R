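# density, susceptibility, LTF, var(S), branching estimators

test_that("density, susceptibility and LTF match hand computations", {
  # N = 5, two active at one bin
  r <- matrix(0L, 5, 3)
  r[1:2, 2] <- 1L
  s <- activity_series(r)
  expect_equal(s$rho, c(0, 0.4, 0))

  # alternating density 0/1 with N = 2: chi = 2 * (0.5 - 0.25) = 0.5
  alt <- activity_series(rep(c(0L, 2L), 50), n_nodes = 2)
  expect_equal(susceptibility(alt), 0.5, tolerance = 1e-12)
  # LTF = (1 / 0.5) * sqrt(0.5 / 2) = 1
  expect_equal(ltf(alt), 1, tolerance = 1e-12)

  # constant density: chi = 0, LTF = 0
  const <- activity_series(rep(3L, 40), n_nodes = 8)
  expect_equal(susceptibility(const), 0)
  expect_equal(ltf(const), 0)
  # checkerboard N = 2 has density identically 1/2
  cb <- rbind(rep(c(1L, 0L), 10), rep(c(0L, 1L), 10))
  expect_equal(activity_series(cb)$rho, rep(0.5, 20))
  # zero activity: LTF undefined
  expect_error(ltf(activity_series(rep(0L, 10), n_nodes = 4)), "undefined")
})

test_that("chi is invariant under row permutation and the LTF identity
           holds exactly", {
  set.seed(2)
  r <- matrix(rbinom(20 * 200, 1, 0.1), 20, 200)
  s <- activity_series(r)
  expect_equal(susceptibility(activity_series(r[sample(20), ])),
               susceptibility(s), tolerance = 1e-14)
  # LTF^2 * <rho>^2 * N = chi
  expect_equal(ltf(s)^2 * mean(s$rho)^2 * s$n_nodes, susceptibility(s),
               tolerance = 1e-12)
})

test_that("avalanche size variance is the population variance", {
  expect_equal(avalanche_size_variance(c(2, 2, 2)), 0)
  expect_equal(avalanche_size_variance(c(1, 3)), 1)  # <S^2>=5, <S>^2=4
  ct <- extract_avalanches(c(0L, 1L, 0L, 3L, 0L))
  expect_equal(avalanche_size_variance(ct), 1)
  expect_error(avalanche_size_variance(c(5)), "undefined")
})

test_that("naive branching ratio matches deterministic bin patterns", {
  # every avalanche has bins (1, 2): ratio 2
  expect_equal(branching_naive(rep(c(0L, 1L, 2L), 10)), 2)
  # bins (2, 2): ratio 1
  expect_equal(branching_naive(rep(c(0L, 2L, 2L), 10)), 1)
  # duration-1 avalanches contribute ratio 0
  expect_equal(branching_naive(c(0L, 1L, 0L, 1L, 2L, 0L)), 1)
  expect_error(branching_naive(rep(0L, 10)), "undefined")
})

test_that("naive branching on seeded subcritical avalanches recovers the
           offspring mean", {
  av <- seeded_avalanches(cbm_config(kappa = 0.8, p_s = 0, bias = 0.6,
                                     seed = 19), n_avalanches = 8000)
  expect_equal(branching_naive(av$counts), 0.8, tolerance = 0.05)
})

test_that("multistep regression recovers a known AR(1) branching value and
           is scale invariant", {
  set.seed(44)
  n <- 1e5
  a <- numeric(n)
  a[1] <- 10
  for (t in 2:n) a[t] <- 0.9 * a[t - 1] + rnorm(1, mean = 1, sd = 1)
  fit <- branching_mr(a)
  expect_equal(fit$m, 0.9, tolerance = 0.02)
  fit_scaled <- branching_mr(a * 37.5)
  expect_equal(fit_scaled$m, fit$m, tolerance = 1e-10)
})

test_that("white noise has no multistep structure", {
  set.seed(9)
  res <- tryCatch(branching_mr(rnorm(5000, mean = 10)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "fit failure")
  } else {
    # no temporal structure: every lag slope is tiny
    expect_true(all(abs(res$slopes) < 0.06))
    expect_lt(res$m, 0.7)
  }
})

test_that("multistep regression is robust to subsampling while the naive
           estimator is biased down", {
  sim <- simulate_cbm(cbm_config(n_nodes = 256, k_in = 5, kappa = 1.0,
                                 bias = 0.6, p_s = 1e-3, n_steps = 1e5,
                                 seed = 29), keep_raster = TRUE)
  full_mr <- branching_mr(sim)
  full_naive <- branching_naive(sim)
  set.seed(30)
  sub <- sim$raster[sample(256, 64), ]
  sub_mr <- branching_mr(sub)
  sub_naive <- branching_naive(sub)
  expect_lt(sub_naive, full_naive)  # subsampling bias of the naive ratio
  expect_lt(abs(sub_mr$m - full_mr$m),
            3 * (full_mr$stderr + sub_mr$stderr) + 0.05)
})
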