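# EMG processing: band-pass -> rectification -> low-pass envelope -> MVC
# normalization, mirroring the kinematic filters (zero-lag Butterworth).

#' Twelve-site electrode layout
#'
#' Bilateral surface sites over multifidus, lumbar and thoracic erector
#' spinae, external oblique, internal oblique and rectus abdominis.
#'
#' @return Tibble with columns `site`, `muscle_site`, `side`.
#' @export
emg_sites <- function() {
  sites <- c("multifidus", "lumbar_erector_spinae", "thoracic_erector_spinae",
             "external_oblique", "internal_oblique", "rectus_abdominis")
  tidyr::expand_grid(muscle_site = sites, side = c("left", "right")) |>
    dplyr::mutate(site = paste(.data$muscle_site, .data$side, sep = "_"), .before = 1)
}

#' MVC-normalized EMG envelope
#'
#' Band-pass (default 30-450 Hz), full-wave rectification, zero-lag low-pass
#' (default 3 Hz), then division by the per-channel MVC peak.
#'
#' @param raw A `spineload_ts` of raw EMG (rate >= 1000 Hz).
#' @param mvc_peak Positive scalar or named per-channel vector of MVC peak
#'   envelope values.
#' @param defaults Package defaults (band edges, envelope cutoff, order).
#' @return A `spineload_ts` of normalized envelopes.
#' @export
emg_envelope <- function(raw, mvc_peak, defaults = spineload_defaults()) {
  if (ts_rate(raw) < 1000) abort("EMG rate must be at least 1000 Hz")
  if (any(!is.finite(mvc_peak)) || any(mvc_peak <= 0)) {
    abort("MVC peak values must be strictly positive")
  }
  cfg <- defaults$emg
  env <- raw |>
    bandpass(cfg$bandpass[1], cfg$bandpass[2], order = cfg$filter_order) |>
    ts_apply(abs) |>
    zero_lag_lowpass(cfg$envelope_cutoff, order = cfg$filter_order)
  chans <- ts_channels(env)
  peaks <- if (length(mvc_peak) == 1) setNames(rep(mvc_peak, length(chans)), chans) else mvc_peak
  missing <- setdiff(chans, names(peaks))
  if (length(missing) > 0) abort(paste0("no MVC peak for channel(s): ", paste(missing, collapse = ", ")))
  for (ch in chans) env[[ch]] <- env[[ch]] / peaks[[ch]]
  env
}

#' Per-channel MVC peak from maximal-contraction trials
#'
#' Processes each MVC trial with the task envelope chain (band-pass,
#' rectification, low-pass) and takes the per-channel maximum over all
#' trials.
#'
#' @param trials List of `spineload_ts` MVC recordings.
#' @param defaults Package defaults.
#' @return Named numeric vector of per-channel peaks.
#' @export
mvc_peaks <- function(trials, defaults = spineload_defaults()) {
  if (inherits(trials, "spineload_ts")) trials <- list(trials)
  peaks <- NULL
  for (tr in trials) {
    env <- emg_envelope(tr, mvc_peak = 1, defaults = defaults)
    p <- vapply(ts_channels(env), function(ch) max(env[[ch]]), numeric(1))
    peaks <- if (is.null(peaks)) p else pmax(peaks, p[names(peaks)])
  }
  peaks
}

#' Model-predicted activity at each electrode site
#'
#' Site activity is the mean of the mapped fascicles' force/strength on the
#' site's side.
#'
#' @param solution A `spineload_recruitment`.
#' @param mapping Named list site -> character vector of fascicle muscles;
#'   defaults to the configured mapping.
#' @param defaults Package defaults.
#' @return Tibble with columns `site`, `muscle_site`, `side`, `activity`.
#' @export
predicted_site_activity <- function(solution, mapping = NULL,
                                    defaults = spineload_defaults()) {
  mapping <- mapping %||% defaults$emg_site_mapping
  forces <- solution$forces
  emg_sites() |>
    dplyr::mutate(activity = purrr::map2_dbl(.data$muscle_site, .data$side, function(ms, sd) {
      muscles <- mapping[[ms]]
      if (is.null(muscles) || length(muscles) == 0) {
        abort(paste0("EMG site '", ms, "' maps to no fascicle"))
      }
      rows <- forces$muscle %in% muscles & forces$side == sd
      if (!any(rows)) abort(paste0("EMG site '", ms, "' maps to unknown fascicles"))
      mean(forces$activity[rows])
    }))
}

#' Pearson correlation with a t-based p value
#'
#' Product-moment correlation with the two-sided p value from the
#' `t = r * sqrt((n-2)/(1-r^2))` transform.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) abort("need equal-length vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance", class = "spineload_undefined")
  }
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}
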