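#' Configuration of a synthetic MEG-like cohort
#'
#' Describes an age-labeled cohort of synthetic continuous recordings whose
#' generative engine is the CBM: each subject's connection-weight bias B is
#' set from their age (older subjects get a more skewed weight distribution)
#' and the branching parameter is pinned near the susceptibility peak for
#' that bias, so cohort-level trends in exponents, susceptibility and
#' position-on-line follow the quasicriticality model of aging.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range ages in years, default \code{c(18, 88)}.
#' @param n_channels sensor channels (default 102).
#' @param duration_s recording length in seconds (default 520).
#' @param sampling_rate Hz (default 1000).
#' @param samples_per_step duration of one CBM step in samples (default 5,
#'   i.e. a 5 ms propagation tick at 1 kHz, matching typical avalanche
#'   time scales in sensor-array analyses).  Sparse sensor traces require
#'   the model clock to be coarser than the sampling clock.
#' @param bias_at_min_age,bias_at_max_age endpoints of the linear age-to-bias
#'   map (defaults 0.6 and 1.8, the two biases whose simulations bracket the
#'   aging trend).
#' @param noise_sd additive Gaussian sensor noise SD, in units of the unit
#'   event amplitude (default 0.15).  Background noise must dominate the
#'   per-channel variance so that the 3-SD detection threshold is the same
#'   for every subject regardless of event rate, while unit-amplitude
#'   events still clear it.
#' @param p_observe probability that a node event registers on a listening
#'   channel (default 0.2).  Sensor arrays observe a vanishing fraction of
#'   the underlying units, and this fractional observability is what makes
#'   sensor-level event trains sparse even when the generative network is
#'   dense; 1 disables subsampling (useful for round-trip checks).
#' @param p_s spontaneous activation probability of the generative CBM.
#' @param n_nodes,k_in generative network size and in-degree.
#' @param nodes_per_channel how many nodes mix into each channel (default 3).
#' @param kappa optional fixed branching parameter for all subjects;
#'   \code{NULL} (default) pins each subject's kappa to the susceptibility
#'   peak for their bias via \code{\link{kappa_for_bias}}.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects, age_range = c(18, 88),
                          n_channels = 102L, duration_s = 520,
                          sampling_rate = 1000, samples_per_step = 5L,
                          bias_at_min_age = 0.6, bias_at_max_age = 1.8,
                          noise_sd = 0.15, p_observe = 0.2, p_s = 1e-3,
                          n_nodes = 256L, k_in = 5L, nodes_per_channel = 3L,
                          kappa = NULL, seed = 1L) {
  stopifnot(n_subjects >= 2, length(age_range) == 2,
            age_range[1] < age_range[2], bias_at_min_age >= 0,
            bias_at_max_age >= 0, noise_sd >= 0, duration_s > 0,
            sampling_rate > 0, n_channels >= 1, nodes_per_channel >= 1,
            samples_per_step >= 1, p_observe > 0, p_observe <= 1)
  cfg <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
              n_channels = as.integer(n_channels), duration_s = duration_s,
              sampling_rate = sampling_rate,
              samples_per_step = as.integer(samples_per_step),
              bias_at_min_age = bias_at_min_age,
              bias_at_max_age = bias_at_max_age, noise_sd = noise_sd,
              p_observe = p_observe,
              p_s = p_s, n_nodes = as.integer(n_nodes),
              k_in = as.integer(k_in),
              nodes_per_channel = as.integer(nodes_per_channel),
              kappa = kappa, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, ages %g-%g, %d channels, %.0f s at %g Hz\n",
              x$n_subjects, x$age_range[1], x$age_range[2], x$n_channels,
              x$duration_s, x$sampling_rate))
  cat(sprintf("  bias %g -> %g over age range, noise SD %g, seed %d\n",
              x$bias_at_min_age, x$bias_at_max_age, x$noise_sd, x$seed))
  invisible(x)
}

#' Read a cohort configuration from YAML
#'
#' Keys are the argument names of \code{\link{cohort_config}}.
#'
#' @param path path to a YAML file.
#' @return A \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown cohort config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(cohort_config, vals)
}

#' Map age to connection-weight bias
#'
#' Linear interpolation between the configured endpoint biases over the age
#' range: monotone non-decreasing in age, equal to the endpoints at the
#' range boundaries.  Aging connectivity data motivate monotonicity (weight
#' distributions steepen with age) but no functional form, so the map is
#' the simplest monotone choice.
#'
#' @param age age in years, within \code{config$age_range}.
#' @param config a \code{\link{cohort_config}}.
#' @return Bias value(s) B.
#' @export
age_to_bias <- function(age, config) {
  r <- config$age_range
  if (any(age < r[1] | age > r[2]))
    stop("invalid argument: age outside configured range", call. = FALSE)
  config$bias_at_min_age + (age - r[1]) / (r[2] - r[1]) *
    (config$bias_at_max_age - config$bias_at_min_age)
}

#' Susceptibility-peak branching parameter for a bias
#'
#' Linear interpolation of the peak location between the two simulated
#' anchor biases — kappa* = 1.12 at B = 0.6 and kappa* = 1.07 at B = 1.8 —
#' clamped outside that range.  Pinning each synthetic subject to the peak
#' expresses quasicritical homeostasis: the network sits where its
#' susceptibility is maximal for its structural parameters.
#'
#' @param bias bias value(s) B.
#' @return Branching parameter(s) at the susceptibility peak.
#' @export
kappa_for_bias <- function(bias) {
  b <- pmin(pmax(bias, 0.6), 1.8)
  1.12 + (b - 0.6) / (1.8 - 0.6) * (1.07 - 1.12)
}

#' Generate one synthetic subject
#'
#' Runs the CBM with the subject's age-derived bias and peak-pinned kappa,
#' then maps the node raster to sensor channels: a fixed random non-negative
#' mixing matrix assigns \code{nodes_per_channel} nodes to each channel,
#' each node event registers with probability \code{p_observe} (sensor
#' subsampling), registered events are convolved with a short smooth kernel
#' (unit peak), and Gaussian noise of SD \code{noise_sd} is added.  With
#' identity mixing, full observation (\code{p_observe = 1}) and low noise,
#' 3-SD thresholding recovers almost all ground-truth events.
#'
#' @param age subject age in years.
#' @param config a \code{\link{cohort_config}}.
#' @param seed subject-level seed.
#' @param subject_id,gender labels stored in the result.
#' @param mixing \code{"random"} (default) or \code{"identity"} (requires
#'   \code{n_channels == n_nodes}; channels are noisy copies of nodes).
#' @return Object of class \code{synthetic_subject}: \code{recording}, plus
#'   ground truth (\code{age}, \code{bias}, \code{kappa}, \code{p_s},
#'   \code{seed}, \code{raster} of the generating CBM).
#' @export
generate_subject <- function(age, config, seed, subject_id = "S001",
                             gender = "F", mixing = c("random", "identity")) {
  mixing <- match.arg(mixing)
  bias <- age_to_bias(age, config)
  kappa <- if (is.null(config$kappa)) kappa_for_bias(bias) else config$kappa
  n_steps <- as.integer(round(config$duration_s * config$sampling_rate /
                                config$samples_per_step))
  cbm <- cbm_config(n_nodes = config$n_nodes, k_in = config$k_in,
                    kappa = kappa, p_s = config$p_s, bias = bias,
                    n_steps = n_steps, seed = seed)
  sim <- simulate_cbm(cbm, keep_raster = TRUE)
  raster <- sim$raster
  # narrow smooth kernel (events two steps apart stay separable excursions)
  kern <- c(0.15, 1, 0.15)
  if (mixing == "identity") {
    if (config$n_channels != config$n_nodes)
      stop("identity mixing requires n_channels == n_nodes", call. = FALSE)
    mix_nodes <- matrix(seq_len(config$n_nodes), nrow = 1)
    mix_w <- matrix(1, nrow = 1, ncol = config$n_nodes)
  } else {
    # sparse mixing: a few weighted nodes per channel, drawn per channel so
    # the wiring is reproducible from the subject seed
    mix_nodes <- matrix(0L, config$nodes_per_channel, config$n_channels)
    mix_w <- matrix(0, config$nodes_per_channel, config$n_channels)
    for (c_i in seq_len(config$n_channels)) {
      mix_nodes[, c_i] <- sample.int(config$n_nodes, config$nodes_per_channel)
      # near-unit amplitudes: every contributing node stays detectable
      mix_w[, c_i] <- stats::runif(config$nodes_per_channel, 0.75, 1)
    }
  }
  sig <- .mix_smooth_cpp(raster, mix_nodes, mix_w, kern,
                         config$samples_per_step, config$p_observe)
  if (config$noise_sd > 0)
    sig <- sig + stats::rnorm(length(sig), sd = config$noise_sd)
  rec <- recording(sig, config$sampling_rate)
  structure(list(subject_id = subject_id, age = age, gender = gender,
                 recording = rec, bias = bias, kappa = kappa,
                 p_s = config$p_s, seed = seed, raster = raster),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("synthetic subject %s: age %.1f (%s), B = %.3f, kappa = %.4f\n",
              x$subject_id, x$age, x$gender, x$bias, x$kappa))
  print(x$recording)
  invisible(x)
}

#' Cohort metadata table
#'
#' Draws ages uniformly over the configured range, assigns balanced gender
#' labels and per-subject seeds derived from the master seed.  This is the
#' deterministic "roster" of the cohort; recordings are produced lazily by
#' \code{\link{generate_subject}} so that large cohorts need not be held in
#' memory at once.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return Data frame with columns \code{subject_id}, \code{age},
#'   \code{gender}, \code{bias}, \code{kappa}, \code{seed}.
#' @export
cohort_metadata <- function(config) {
  set.seed(config$seed)
  n <- config$n_subjects
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  genders <- rep_len(c("F", "M"), n)[sample.int(n)]
  seeds <- sample.int(.Machine$integer.max, n)
  bias <- age_to_bias(ages, config)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), age = ages,
             gender = genders, bias = bias,
             kappa = if (is.null(config$kappa)) kappa_for_bias(bias)
                     else config$kappa,
             seed = seeds, stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Materializes every subject of \code{\link{cohort_metadata}}.  Optionally
#' writes per-subject recording CSVs plus a metadata CSV to \code{out_dir}.
#' For long recordings prefer streaming subjects one at a time through
#' \code{\link{analyze_synthetic_cohort}}, which never holds more than one
#' recording in memory.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param out_dir optional output directory.
#' @return List with \code{metadata} (data frame) and \code{subjects} (list
#'   of \code{synthetic_subject}).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  meta <- cohort_metadata(config)
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    generate_subject(meta$age[i], config, meta$seed[i],
                     subject_id = meta$subject_id[i],
                     gender = meta$gender[i])
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    for (s in subjects)
      write_recording_csv(s$recording,
                          file.path(out_dir, paste0(s$subject_id, ".csv")))
  }
  list(metadata = meta, subjects = subjects)
}
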