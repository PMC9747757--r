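# z-scoring, excursion detection, binning

test_that("zscore gives per-channel mean 0 / SD 1 and is idempotent", {
  set.seed(4)
  rec <- recording(matrix(rnorm(3 * 500, mean = 5, sd = 3), 3, 500), 1000)
  z <- zscore_recording(rec)
  expect_equal(unname(rowMeans(z$samples)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(z$samples, 1, sd)), rep(1, 3), tolerance = 1e-10)
  z2 <- zscore_recording(z)
  expect_equal(z2$samples, z$samples, tolerance = 1e-10)
})

test_that("constant channels are rejected by name and NaN at load", {
  x <- matrix(rnorm(2 * 100), 2, 100)
  x[2, ] <- 5
  rec <- recording(x, 1000, channel_ids = c("good", "flatline"))
  expect_error(zscore_recording(rec), "flatline")
  x[1, 3] <- NaN
  expect_error(recording(x, 1000), "finite")
})

test_that("excursion detection places one event per excursion at the
           absolute extremum", {
  # flat signal: no events
  flat <- recording(matrix(rnorm(300, sd = 0.1), 1), 1000)
  expect_equal(sum(lengths(detect_events(flat))), 0L)

  # one positive bump peaking at sample 100, one negative at 200
  rec <- bump_recording(list(100), noise_sd = 0.05)
  rec$samples[1, 198:202] <- -c(4, 7, 9, 7, 4)
  z <- zscore_recording(rec)
  ev <- detect_events(z, 3)
  expect_equal(ev[[1]], c(100L, 200L))

  # brute-force oracle: enumerate excursions directly from the definition
  set.seed(10)
  x <- rnorm(2000)
  x[sample(2000, 40)] <- x[sample(2000, 40)] + sample(c(-6, 6), 40, TRUE)
  rec2 <- zscore_recording(recording(matrix(x, 1), 1000))
  ev2 <- detect_events(rec2, 3)[[1]]
  over <- abs(rec2$samples[1, ]) > 3
  oracle <- integer(0)
  i <- 1
  while (i <= length(over)) {
    if (over[i]) {
      j <- i
      while (j < length(over) && over[j + 1]) j <- j + 1
      seg <- abs(rec2$samples[1, i:j])
      oracle <- c(oracle, i - 1L + which(seg == max(seg))[1])
      i <- j + 1
    } else i <- i + 1
  }
  expect_equal(ev2, unname(oracle))
})

test_that("ties at the excursion extremum break to the earliest sample", {
  x <- rep(0, 100)
  x[40:43] <- 5  # plateau excursion, already in SD-like units
  ev <- detect_events(recording(matrix(x, 1), 1000), 3)
  expect_equal(ev[[1]], 40L)
})

test_that("event count is invariant under sign flip and monotone in
           threshold", {
  rec <- bump_recording(list(c(50, 150, 250)), n_samples = 400,
                        amplitude = 6, noise_sd = 0.3)
  z <- zscore_recording(rec)
  n3 <- sum(lengths(detect_events(z, 3)))
  flipped <- recording(-z$samples, z$sampling_rate)
  expect_equal(sum(lengths(detect_events(flipped, 3))), n3)
  for (thr in c(1, 2, 4, 5)) {
    expect_true(sum(lengths(detect_events(z, thr))) >=
                sum(lengths(detect_events(z, thr + 0.5))))
  }
  expect_error(detect_events(z, 0), "positive")
})

test_that("binning maps events to the correct bins and conserves touched
           channels", {
  ev <- structure(list(ch1 = c(3L, 7L, 8L), ch2 = integer(0)),
                  class = "event_train", n_samples = 10L,
                  channel_ids = c("ch1", "ch2"), sampling_rate = 1000,
                  threshold_sd = 3)
  r1 <- bin_events(ev, 1)
  expect_equal(ncol(r1), 10L)
  expect_equal(which(r1[1, ]), c(3L, 7L, 8L))
  r4 <- bin_events(ev, 4)
  expect_equal(ncol(r4), 3L)  # ceiling(10 / 4)
  expect_equal(which(r4[1, ]), c(1L, 2L))  # events 3 -> bin 1; 7, 8 -> bin 2
  expect_false(any(r4[2, ]))
  # channel touched iff it has events
  expect_equal(rowSums(r4) > 0, c(ch1 = TRUE, ch2 = FALSE))
  # events in adjacent samples collapse to one bin
  ev2 <- structure(list(ch1 = c(1L, 2L)), class = "event_train",
                   n_samples = 4L, channel_ids = "ch1", sampling_rate = 1000,
                   threshold_sd = 3)
  expect_equal(which(bin_events(ev2, 2)[1, ]), 1L)
})

test_that("auto bin width is the rounded pooled mean inter-event interval", {
  ev <- structure(list(a = c(10L, 30L), b = c(20L, 40L)),
                  class = "event_train", n_samples = 50L,
                  channel_ids = c("a", "b"), sampling_rate = 1000,
                  threshold_sd = 3)
  expect_equal(auto_bin_width(ev), 10L)  # pooled 10,20,30,40 -> mean diff 10
})

test_that("recording and event-list CSV round-trip", {
  rec <- bump_recording(list(c(60, 120)), n_samples = 200)
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$sampling_rate, rec$sampling_rate)

  ev <- detect_events(zscore_recording(rec), 3)
  ep <- tempfile(fileext = ".csv")
  write_events_csv(ev, ep)
  ev2 <- read_events_csv(ep, n_samples = 200)
  expect_equal(ev2[["ch001"]], ev[["ch001"]])
})
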