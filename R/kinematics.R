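#' Construct a sampled time series
#'
#' Time series are plain tibbles with a `time` column (seconds), one column
#' per channel, and the sampling rate stored in the `"rate"` attribute.
#'
#' @param data Data frame or matrix of channel samples (frames x channels).
#' @param rate Sampling rate in Hz (> 0).
#' @param labels Optional channel names.
#' @return A `spineload_ts` tibble.
#' @export
timeseries <- function(data, rate, labels = NULL) {
  if (!is.finite(rate) || rate <= 0) abort("sampling rate must be positive")
  data <- tibble::as_tibble(as.data.frame(data))
  if (!is.null(labels)) names(data) <- labels
  if (anyNA(data)) abort("time series must contain no missing values")
  out <- dplyr::bind_cols(tibble::tibble(time = (seq_len(nrow(data)) - 1) / rate), data)
  attr(out, "rate") <- rate
  class(out) <- c("spineload_ts", class(out))
  out
}

#' @rdname timeseries
#' @param series A `spineload_ts` tibble.
#' @export
ts_rate <- function(series) {
  rate <- attr(series, "rate")
  if (is.null(rate)) abort("series has no sampling-rate attribute; build it with timeseries()")
  rate
}

ts_channels <- function(series) setdiff(names(series), "time")

ts_apply <- function(series, f) {
  rate <- ts_rate(series)
  out <- series
  for (ch in ts_channels(series)) out[[ch]] <- f(series[[ch]])
  attr(out, "rate") <- rate
  out
}

#' Zero-lag low-pass Butterworth filter
#'
#' Forward-backward (zero phase) 2nd-order-by-default Butterworth low-pass,
#' applied per channel. The two passes square the magnitude response, so the
#' gain at the cutoff frequency is 0.5.
#'
#' @param series A `spineload_ts` tibble.
#' @param cutoff Cutoff frequency, Hz; must lie below the Nyquist frequency.
#' @param order Filter order of each pass (default 2).
#' @return Filtered series of the same shape.
#' @export
zero_lag_lowpass <- function(series, cutoff, order = 2) {
  rate <- ts_rate(series)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2) {
    abort("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  ts_apply(series, function(x) as.numeric(signal::filtfilt(bf, x)))
}

#' Zero-lag band-pass Butterworth filter
#'
#' Forward-backward Butterworth band-pass (default 2nd order per pass);
#' removes DC and retains the passband with near-unity gain mid-band.
#'
#' @param series A `spineload_ts` tibble.
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param order Filter order of each pass (default 2).
#' @return Filtered series of the same shape.
#' @export
bandpass <- function(series, low, high, order = 2) {
  rate <- ts_rate(series)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high || high >= rate / 2) {
    abort("band edges must satisfy 0 < low < high < rate/2")
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  ts_apply(series, function(x) as.numeric(signal::filtfilt(bf, x)))
}

#' Mean of each channel over a static hold window
#'
#' @param series A `spineload_ts` tibble.
#' @param start Window start, seconds from the first sample.
#' @param duration Window length, seconds (default 3, the static hold).
#' @return One-row tibble of per-channel means.
#' @export
static_phase_average <- function(series, start = 0, duration = 3) {
  rate <- ts_rate(series)
  t_end <- (nrow(series) - 1) / rate
  if (start < 0 || start + duration > t_end + 1e-9) {
    abort("averaging window must fit within the recording")
  }
  idx <- series$time >= start - 1e-9 & series$time <= start + duration + 1e-9
  series[idx, ts_channels(series), drop = FALSE] |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean))
}

#' Lumbar rhythm coefficients
#'
#' Per-plane shares of the total trunk-pelvis rotation carried by each
#' intervertebral joint (T12-L1 down to L5-S1). Each plane's six shares must
#' be nonnegative and sum to 1.
#'
#' @param coeffs Optional named list with numeric vectors `flexion`,
#'   `lateral`, `axial` (length 6 each); defaults to the configured rhythm.
#' @param defaults Package defaults list.
#' @return Tibble with columns `joint`, `flexion`, `lateral`, `axial`.
#' @export
lumbar_rhythm_coefficients <- function(coeffs = NULL, defaults = spineload_defaults()) {
  coeffs <- coeffs %||% defaults$lumbar_rhythm
  joints <- c("T12-L1", "L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")
  out <- tibble::tibble(joint = joints)
  for (plane in c("flexion", "lateral", "axial")) {
    v <- as.numeric(coeffs[[plane]])
    if (length(v) != 6 || any(v < 0)) {
      abort(paste0("rhythm plane '", plane, "' needs 6 nonnegative coefficients"))
    }
    if (abs(sum(v) - 1) > 1e-9) {
      abort(paste0("rhythm plane '", plane, "' coefficients must sum to 1"))
    }
    out[[plane]] <- v
  }
  out
}

#' Distribute a total lumbar rotation over the intervertebral joints
#'
#' Joint rotation in each plane is the plane's rhythm coefficient times the
#' total rotation in that plane, so per-plane sums reproduce the total
#' exactly.
#'
#' @param total Length-3 numeric (flexion, lateral, axial) in degrees.
#' @param coeffs Rhythm tibble from [lumbar_rhythm_coefficients()].
#' @return Tibble with columns `joint`, `flexion`, `lateral`, `axial`.
#' @export
distribute_lumbar_rotation <- function(total, coeffs = lumbar_rhythm_coefficients()) {
  stopifnot(length(total) == 3, all(is.finite(total)))
  for (plane in c("flexion", "lateral", "axial")) {
    if (abs(sum(coeffs[[plane]]) - 1) > 1e-9) {
      abort("rhythm coefficients must sum to 1 in every plane")
    }
  }
  tibble::tibble(
    joint = coeffs$joint,
    flexion = coeffs$flexion * total[1],
    lateral = coeffs$lateral * total[2],
    axial = coeffs$axial * total[3]
  )
}

#' Read a TRC marker-trajectory file
#'
#' Parses the tab-delimited TRC format (header block with `DataRate` and
#' marker names, then `Frame#`/`Time` and X/Y/Z triples in mm) into a
#' `spineload_ts` tibble with columns `<marker>_x/_y/_z` in metres.
#'
#' @param path Path to a `.trc` file.
#' @return A `spineload_ts` tibble.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) abort("TRC file too short")
  hdr_names <- strsplit(lines[3], "\t")[[1]]
  hdr_vals <- strsplit(lines[4], "\t")[[1]]
  rate <- as.numeric(hdr_vals[match("DataRate", hdr_names)])
  if (!is.finite(rate) || rate <= 0) abort("TRC header lacks a valid DataRate")
  markers <- strsplit(lines[5], "\t")[[1]]
  markers <- markers[nzchar(markers)][-(1:2)]  # drop Frame#, Time
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  mat <- do.call(rbind, lapply(strsplit(body, "\t"), function(x) as.numeric(x)))
  coords <- mat[, -(1:2), drop = FALSE] / 1000  # mm -> m
  labels <- as.vector(t(outer(markers, c("x", "y", "z"), paste, sep = "_")))
  if (ncol(coords) != length(labels)) abort("TRC marker columns do not match header markers")
  timeseries(coords, rate, labels = labels)
}

#' Read a channel CSV (GRF or EMG) into a time series
#'
#' Expected layout: a first line `rate,<Hz>`, then a header of channel names
#' and the samples.
#'
#' @param path Path to the CSV file.
#' @return A `spineload_ts` tibble.
#' @export
read_series_csv <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (tolower(first[1]) != "rate") abort("series CSV must start with a 'rate,<Hz>' line")
  rate <- as.numeric(first[2])
  dat <- readr::read_csv(path, skip = 1, show_col_types = FALSE)
  timeseries(dat, rate)
}

#' Write a time series as CSV
#'
#' Inverse of [read_series_csv()]: a `rate,<Hz>` line followed by the channel
#' table (without the derived `time` column).
#'
#' @param series A `spineload_ts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  writeLines(paste0("rate,", format(ts_rate(series), digits = 12)), path)
  readr::write_csv(series[, ts_channels(series), drop = FALSE], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
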