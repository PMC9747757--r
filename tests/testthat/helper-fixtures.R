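# shared fixtures, all generated in code

# small config that simulates fast
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_nodes = 64L, k_in = 4L, kappa = 1, p_s = 1e-3, bias = 1.0,
         n_steps = 5000L, burn_in = 200L, seed = 123L),
    list(...))
  do.call(cbm_config, args)
}

# recording with Gaussian-bump events at known sample positions
bump_recording <- function(event_samples, n_samples = 400L, n_channels = 1L,
                           amplitude = 8, noise_sd = 0.2, seed = 99L,
                           sampling_rate = 1000) {
  set.seed(seed)
  x <- matrix(rnorm(n_channels * n_samples, sd = noise_sd),
              n_channels, n_samples)
  if (!is.list(event_samples)) event_samples <- list(event_samples)
  kern <- amplitude * exp(-((-2:2)^2) / 2)
  for (c_i in seq_len(n_channels)) {
    for (s in event_samples[[c_i]]) {
      idx <- s + (-2:2)
      ok <- idx >= 1 & idx <= n_samples
      x[c_i, idx[ok]] <- x[c_i, idx[ok]] + kern[ok]
    }
  }
  recording(x, sampling_rate)
}

# tiny cohort configuration: short recordings, small network, quick to run
tiny_cohort_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 6L, n_channels = 32L, duration_s = 8,
         sampling_rate = 1000, n_nodes = 64L, k_in = 4L,
         noise_sd = 0.05, seed = 7L),
    list(...))
  do.call(cohort_config, args)
}
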