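#' Multichannel continuous recording
#'
#' Thin container for continuous multichannel data (e.g. MEG magnetometer
#' traces): a channels-by-samples numeric matrix plus sampling rate and
#' channel labels.  Non-finite samples are rejected at construction — they
#' are upstream artifacts, not something to impute here.
#'
#' @param samples numeric matrix, rows = channels, columns = samples.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_ids optional channel labels (default \code{ch001}, ...).
#' @return Object of class \code{recording}.
#' @export
recording <- function(samples, sampling_rate, channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("recording samples must be finite numbers (no NaN/NA)",
         call. = FALSE)
  if (length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar", call. = FALSE)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%03d", seq_len(nrow(samples)))
  stopifnot(length(channel_ids) == nrow(samples))
  rownames(samples) <- channel_ids
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate),
                 channel_ids = as.character(channel_ids)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Z-score a recording channel-wise
#'
#' Subtracts each channel's mean and divides by its standard deviation, the
#' standard normalization before threshold-based event detection.
#'
#' @param rec a \code{\link{recording}}.
#' @return A z-scored \code{\link{recording}} (per-channel mean 0, SD 1).
#' @export
zscore_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  sds <- apply(rec$samples, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rec$channel_ids[sds == 0][1]
    stop("degenerate channel: '", bad, "' is constant (zero SD)",
         call. = FALSE)
  }
  z <- (rec$samples - rowMeans(rec$samples)) / sds
  recording(z, rec$sampling_rate, rec$channel_ids)
}

#' Detect threshold excursion events
#'
#' Finds, per channel, maximal contiguous runs of samples whose absolute
#' value exceeds \code{threshold_sd} (both polarities treated symmetrically)
#' and places exactly one event per excursion at the sample of maximum
#' absolute amplitude (earliest sample on ties).  One event per excursion
#' prevents double-counting sustained deflections.  The recording should be
#' z-scored first so the threshold is in SD units; 3 SD is the conventional
#' optimum for separating neural events from background in MEG sensor data.
#'
#' @param rec a z-scored \code{\link{recording}}.
#' @param threshold_sd positive threshold in SD units (default 3).
#' @return Object of class \code{event_train}: list of per-channel sorted
#'   1-based sample indices; attributes \code{n_samples},
#'   \code{channel_ids}, \code{sampling_rate}, \code{threshold_sd}.
#' @export
detect_events <- function(rec, threshold_sd = 3) {
  stopifnot(inherits(rec, "recording"))
  if (length(threshold_sd) != 1L || threshold_sd <= 0)
    stop("invalid argument: threshold_sd must be positive", call. = FALSE)
  ev <- lapply(seq_len(nrow(rec$samples)), function(c_i) {
    x <- abs(rec$samples[c_i, ])
    r <- rle(x > threshold_sd)
    if (!any(r$values)) return(integer(0))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    st <- starts[r$values]
    en <- ends[r$values]
    vapply(seq_along(st), function(i) {
      st[i] - 1L + which.max(x[st[i]:en[i]])  # which.max: earliest tie
    }, integer(1))
  })
  names(ev) <- rec$channel_ids
  structure(ev, class = "event_train", n_samples = ncol(rec$samples),
            channel_ids = rec$channel_ids, sampling_rate = rec$sampling_rate,
            threshold_sd = threshold_sd)
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("event train: %d channels, %d events over %d samples\n",
              length(x), sum(lengths(x)), attr(x, "n_samples")))
  invisible(x)
}

#' Automatic bin width from the pooled inter-event interval
#'
#' The mean interval between consecutive events of the pooled (all-channel)
#' event train, rounded to the nearest sample (floor 1).  Binning at the
#' array-wide mean inter-event interval is the conventional choice: it
#' targets roughly one event per bin, the scale at which empty bins separate
#' avalanches without fragmenting propagating activity.
#'
#' @param events an \code{\link{detect_events}} train.
#' @return Positive integer bin width in samples.
#' @export
auto_bin_width <- function(events) {
  all_t <- sort(unlist(events, use.names = FALSE))
  if (length(all_t) < 2) return(1L)
  max(1L, as.integer(round(mean(diff(all_t)))))
}

#' Bin an event train into a raster
#'
#' Raster entry (channel, bin) is 1 iff the channel has at least one event
#' in the bin; the number of bins is \code{ceiling(n_samples / bin_width)}.
#'
#' @param events an \code{\link{detect_events}} train.
#' @param bin_width positive integer width in samples, or \code{NULL} for
#'   \code{\link{auto_bin_width}}.
#' @return Logical matrix (channels x bins) with attribute \code{bin_width}.
#' @export
bin_events <- function(events, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- auto_bin_width(events)
  bin_width <- as.integer(bin_width)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  n_samples <- attr(events, "n_samples")
  n_bins <- as.integer(ceiling(n_samples / bin_width))
  raster <- matrix(FALSE, nrow = length(events), ncol = n_bins,
                   dimnames = list(attr(events, "channel_ids"), NULL))
  for (c_i in seq_along(events)) {
    if (length(events[[c_i]]))
      raster[c_i, (events[[c_i]] - 1L) %/% bin_width + 1L] <- TRUE
  }
  attr(raster, "bin_width") <- bin_width
  raster
}

#' Read / write recordings and event lists as delimited text
#'
#' \code{write_recording_csv}/\code{read_recording_csv} store channels as
#' columns with a header row of channel ids (sampling rate in a leading
#' comment line).  \code{write_events_csv}/\code{read_events_csv} store an
#' event list with columns \code{channel_id,sample_index}.
#'
#' @param rec a \code{\link{recording}}.
#' @param path file path.
#' @return Readers return a \code{recording} / \code{event_train}.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate), con)
  utils::write.csv(as.data.frame(t(rec$samples)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate override for files lacking the header comment.
#' @export
read_recording_csv <- function(path, sampling_rate = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^# sampling_rate_hz:", first)) {
    sr <- as.numeric(sub("^# sampling_rate_hz:\\s*", "", first))
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  } else {
    sr <- sampling_rate
    df <- utils::read.csv(path, check.names = FALSE)
  }
  if (is.null(sr) || is.na(sr))
    stop("sampling rate not found in file; pass sampling_rate=",
         call. = FALSE)
  recording(t(as.matrix(df)), sr, channel_ids = names(df))
}

#' @rdname write_recording_csv
#' @param events an \code{\link{detect_events}} train.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(
    channel_id = rep(attr(events, "channel_ids"), lengths(events)),
    sample_index = unlist(events, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param n_samples total sample count of the source recording.
#' @export
read_events_csv <- function(path, n_samples, sampling_rate = NA) {
  df <- utils::read.csv(path)
  stopifnot(all(c("channel_id", "sample_index") %in% names(df)))
  ids <- unique(df$channel_id)
  ev <- lapply(ids, function(id) sort(df$sample_index[df$channel_id == id]))
  names(ev) <- ids
  structure(ev, class = "event_train", n_samples = as.integer(n_samples),
            channel_ids = ids, sampling_rate = sampling_rate,
            threshold_sd = NA)
}
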