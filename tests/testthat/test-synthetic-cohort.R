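# synthetic MEG-like cohort generator

test_that("age-to-bias map is linear, monotone, endpoint-exact, and
           range-checked", {
  cfg <- tiny_cohort_cfg()
  expect_equal(age_to_bias(18, cfg), 0.6)
  expect_equal(age_to_bias(88, cfg), 1.8)
  expect_equal(age_to_bias(53, cfg), 1.2)  # midpoint -> mean of endpoints
  ages <- seq(18, 88, by = 5)
  expect_true(all(diff(age_to_bias(ages, cfg)) > 0))
  expect_error(age_to_bias(17, cfg), "outside")
  expect_error(age_to_bias(89, cfg), "outside")
})

test_that("peak-pinned kappa interpolates between the sweep anchors and is
           clamped", {
  expect_equal(kappa_for_bias(0.6), 1.12)
  expect_equal(kappa_for_bias(1.8), 1.07)
  expect_equal(kappa_for_bias(1.2), 1.095)
  expect_equal(kappa_for_bias(0.1), 1.12)
  expect_equal(kappa_for_bias(3.0), 1.07)
})

test_that("cohort metadata is reproducible, spans the age range, balances
           gender", {
  cfg <- tiny_cohort_cfg(n_subjects = 20)
  m1 <- cohort_metadata(cfg)
  m2 <- cohort_metadata(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 20L)
  expect_true(all(m1$age >= 18 & m1$age <= 88))
  expect_gt(diff(range(m1$age)), 30)  # spans a wide slice of the range
  expect_equal(sort(as.integer(table(m1$gender))), c(10L, 10L))
  expect_equal(anyDuplicated(m1$seed), 0L)
})

test_that("subject generation is deterministic and carries ground truth", {
  cfg <- tiny_cohort_cfg(duration_s = 2)
  s1 <- generate_subject(40, cfg, seed = 301)
  s2 <- generate_subject(40, cfg, seed = 301)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_equal(s1$bias, age_to_bias(40, cfg))
  expect_equal(s1$kappa, kappa_for_bias(s1$bias))
  expect_equal(dim(s1$recording$samples),
               c(cfg$n_channels, cfg$duration_s * cfg$sampling_rate))
  expect_equal(dim(s1$raster),
               c(64L, 2000L %/% cfg$samples_per_step))
})

test_that("noise-free identity mixing recovers nearly all ground-truth
           events through 3-SD thresholding", {
  cfg <- tiny_cohort_cfg(n_channels = 64L, noise_sd = 0, duration_s = 6,
                         p_observe = 1)
  subj <- generate_subject(70, cfg, seed = 401, mixing = "identity")
  z <- zscore_recording(subj$recording)
  ev <- detect_events(z, 3)
  # model step m maps into the sample window (m-1)*sps + 1 .. m*sps
  # (event timing is jittered within the window by the sensor model)
  sps <- cfg$samples_per_step
  n_truth <- 0L
  n_hit <- 0L
  for (i in seq_along(ev)) {
    steps <- which(subj$raster[i, ])
    n_truth <- n_truth + length(steps)
    hit_steps <- unique((ev[[i]] - 1L) %/% sps + 1L)
    n_hit <- n_hit + sum(steps %in% hit_steps)
  }
  expect_gt(n_truth, 100)       # enough activity to make the check real
  expect_gt(n_hit / n_truth, 0.95)
})

test_that("older (high-bias) subjects have smaller fitted exponents than
           young ones", {
  cfg <- cohort_config(n_subjects = 2, duration_s = 60, seed = 1)
  tau_of <- function(age, seed) {
    subj <- generate_subject(age, cfg, seed = seed)
    raster <- bin_events(detect_events(zscore_recording(subj$recording), 3))
    fit_power_law(extract_avalanches(raster)$size, method = "lsq")$exponent
  }
  old <- mean(vapply(1:3, function(i) tau_of(88, 500 + i), numeric(1)))
  young <- mean(vapply(1:3, function(i) tau_of(18, 500 + i), numeric(1)))
  expect_lt(old, young)
})

test_that("generate_cohort writes metadata and per-subject recordings", {
  cfg <- tiny_cohort_cfg(n_subjects = 2, duration_s = 1)
  dir <- tempfile()
  out <- generate_cohort(cfg, out_dir = dir)
  expect_equal(length(out$subjects), 2L)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "S001.csv")))
  back <- read_recording_csv(file.path(dir, "S001.csv"))
  expect_equal(back$samples, out$subjects[[1]]$recording$samples,
               tolerance = 1e-6, ignore_attr = TRUE)
})
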