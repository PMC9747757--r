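#' Analysis parameters for the subject pipeline
#'
#' @param threshold_sd event-detection threshold in SD units (default 3).
#' @param bin_width raster bin width in samples, or \code{NULL} for the
#'   pooled mean inter-event interval (\code{\link{auto_bin_width}}).
#' @param fit_method \code{"lsq"} (default; windowed log-binned least
#'   squares, appropriate for driven-system catalogs) or \code{"mle"} for
#'   the exponent fits.
#' @param fit_xmin lower cutoff for the exponent fits (default 1).  Cohort
#'   analyses use one fixed cutoff for every subject so that exponent pairs
#'   are methodologically comparable across the cohort; set \code{NULL} to
#'   let each fit select its own cutoff.
#' @param n_boot bootstrap resamples for exponent standard errors.
#' @param mr_k_max maximum lag of the multistep-regression branching fit.
#' @return List of class \code{analysis_params}.
#' @export
analysis_params <- function(threshold_sd = 3, bin_width = NULL,
                            fit_method = "lsq", fit_xmin = 1L,
                            n_boot = 200L, mr_k_max = 40L) {
  structure(list(threshold_sd = threshold_sd, bin_width = bin_width,
                 fit_method = fit_method, fit_xmin = fit_xmin,
                 n_boot = as.integer(n_boot), mr_k_max = as.integer(mr_k_max)),
            class = "analysis_params")
}

#' Analyze one subject's recording
#'
#' Chains the subject-level pipeline: z-score, threshold excursion
#' detection, binning, avalanche extraction, exponent fits and activity
#' statistics.  Fit failures (degenerate channels, too few avalanches, ...)
#' do not abort: the subject is returned flagged \code{excluded} with the
#' reason, mirroring how human-cohort subjects with unusable fits are
#' dropped before line fitting.
#'
#' @param rec a \code{\link{recording}}.
#' @param params an \code{\link{analysis_params}}.
#' @return List of class \code{subject_analysis}: \code{metrics} (mean
#'   rate, chi, ltf, var_S, log10_var_S, sigma_naive, sigma_mr, n_avalanches,
#'   bin_width), \code{exponents} (an \code{\link{exponent_pair}} or
#'   \code{NULL}), \code{excluded} (FALSE or the reason string).
#' @export
analyze_subject <- function(rec, params = analysis_params()) {
  out <- tryCatch({
    z <- zscore_recording(rec)
    events <- detect_events(z, params$threshold_sd)
    raster <- bin_events(events, params$bin_width)
    catalog <- extract_avalanches(raster, attr(raster, "bin_width"))
    series <- activity_series(raster)
    pair <- fit_exponents(catalog, method = params$fit_method,
                          n_boot = params$n_boot, xmin = params$fit_xmin)
    chi <- susceptibility(series)
    var_s <- avalanche_size_variance(catalog)
    metrics <- list(
      mean_rate = mean(series$rho),
      chi = chi,
      ltf = ltf(series),
      var_S = var_s,
      log10_var_S = log10(var_s),
      sigma_naive = branching_naive(raster),
      sigma_mr = branching_mr(series, params$mr_k_max)$m,
      n_avalanches = nrow(catalog),
      bin_width = attr(raster, "bin_width"))
    list(metrics = metrics, exponents = pair, excluded = FALSE)
  }, error = function(e) {
    list(metrics = NULL, exponents = NULL, excluded = conditionMessage(e))
  })
  class(out) <- "subject_analysis"
  out
}

#' @export
print.subject_analysis <- function(x, ...) {
  if (!isFALSE(x$excluded)) {
    cat("subject excluded:", x$excluded, "\n")
    return(invisible(x))
  }
  m <- x$metrics
  cat(sprintf("subject analysis: %d avalanches (bin width %d)\n",
              m$n_avalanches, m$bin_width))
  cat(sprintf("  rate %.4g, chi %.4g, LTF %.3g, sigma (naive %.3f, MR %.3f)\n",
              m$mean_rate, m$chi, m$ltf, m$sigma_naive, m$sigma_mr))
  print(x$exponents)
  invisible(x)
}

#' Cohort-level statistics table
#'
#' Pearson correlations (two-sided) between the variable pairs of interest —
#' age vs position-on-line, susceptibility, mean rate, LTF, log10 var(S) and
#' both branching-ratio estimates, plus position vs chi and chi vs
#' log10 var(S) — and a Welch two-tailed t-test of position by gender label.
#' Avalanche-size variance enters on the log10 scale.  No multiple-testing
#' correction is applied.
#'
#' @param results data frame with one row per included subject; columns
#'   \code{age}, \code{gender}, \code{position}, \code{chi},
#'   \code{mean_rate}, \code{ltf}, \code{log10_var_S}, \code{sigma_naive},
#'   \code{sigma_mr} (missing columns are skipped).
#' @param min_n statistics with fewer complete pairs are omitted.
#' @return Data frame with columns \code{test}, \code{var1}, \code{var2},
#'   \code{estimate}, \code{p_value}, \code{n}.
#' @export
cohort_statistics <- function(results, min_n = 3L) {
  pairs <- list(c("age", "position"), c("age", "chi"), c("position", "chi"),
                c("age", "mean_rate"), c("age", "ltf"),
                c("age", "log10_var_S"), c("chi", "log10_var_S"),
                c("age", "sigma_naive"), c("age", "sigma_mr"))
  rows <- list()
  for (p in pairs) {
    if (!all(p %in% names(results))) next
    ok <- stats::complete.cases(results[, p])
    if (sum(ok) < min_n || stats::sd(results[ok, p[1]]) == 0 ||
        stats::sd(results[ok, p[2]]) == 0) next
    ct <- stats::cor.test(results[ok, p[1]], results[ok, p[2]])
    rows[[length(rows) + 1L]] <-
      data.frame(test = "pearson_r", var1 = p[1], var2 = p[2],
                 estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(ok))
  }
  if (all(c("position", "gender") %in% names(results))) {
    ok <- stats::complete.cases(results[, c("position", "gender")])
    g <- results$gender[ok]
    if (length(unique(g)) == 2 && min(table(g)) >= min_n) {
      tt <- stats::t.test(results$position[ok] ~ g)  # Welch by default
      rows[[length(rows) + 1L]] <-
        data.frame(test = "welch_t", var1 = "position", var2 = "gender",
                   estimate = unname(tt$statistic), p_value = tt$p.value,
                   n = sum(ok))
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Streams the cohort subject by subject: generates each recording from the
#' cohort roster, analyzes it, and discards it, keeping only per-subject
#' metrics.  Then fits the cohort gamma-scaling line over the included
#' exponent pairs, computes the normalized position-on-line biomarker, and
#' the statistics table.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param params an \code{\link{analysis_params}}.
#' @param verbose print one line per subject?
#' @return List of class \code{cohort_results}: \code{results} (per-subject
#'   data frame with metadata, metrics, exponents, position), \code{line}
#'   (the \code{\link{scaling_line}}), \code{statistics} (the table),
#'   \code{excluded} (data frame of excluded subjects with reasons).
#' @export
analyze_synthetic_cohort <- function(config, params = analysis_params(),
                                     verbose = FALSE) {
  meta <- cohort_metadata(config)
  rows <- vector("list", nrow(meta))
  excluded <- list()
  for (i in seq_len(nrow(meta))) {
    subj <- generate_subject(meta$age[i], config, meta$seed[i],
                             subject_id = meta$subject_id[i],
                             gender = meta$gender[i])
    an <- analyze_subject(subj$recording, params)
    if (!isFALSE(an$excluded)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = meta$subject_id[i], reason = an$excluded)
      if (verbose) message(meta$subject_id[i], " excluded: ", an$excluded)
      next
    }
    m <- an$metrics
    e <- an$exponents
    rows[[i]] <- data.frame(
      meta[i, c("subject_id", "age", "gender", "bias", "kappa", "seed")],
      tau_S = e$tau_S$exponent, tau_S_err = e$tau_S$stderr,
      tau_T = e$tau_T$exponent, tau_T_err = e$tau_T$stderr,
      gamma_fit = e$gamma$gamma, fraction = e$fraction, dcc = e$dcc,
      mean_rate = m$mean_rate, chi = m$chi, ltf = m$ltf,
      var_S = m$var_S, log10_var_S = m$log10_var_S,
      sigma_naive = m$sigma_naive, sigma_mr = m$sigma_mr,
      n_avalanches = m$n_avalanches, bin_width = m$bin_width)
    if (verbose)
      message(sprintf("%s age %5.1f  tau_S %.3f  chi %.3g",
                      meta$subject_id[i], meta$age[i],
                      e$tau_S$exponent, m$chi))
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results) || nrow(results) < 3)
    stop("fewer than 3 subjects survived analysis", call. = FALSE)
  line <- fit_scaling_line(results[, c("tau_S", "tau_T")])
  results$position <- position_on_line(results[, c("tau_S", "tau_T")], line)
  structure(list(results = results, line = line,
                 statistics = cohort_statistics(results),
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                            else NULL),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("cohort results: %d subjects analyzed", nrow(x$results)))
  if (!is.null(x$excluded)) cat(sprintf(", %d excluded", nrow(x$excluded)))
  cat("\n")
  print(x$line)
  print(x$statistics, row.names = FALSE)
  invisible(x)
}
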