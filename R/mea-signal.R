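## Spike detection from raw voltage: 200-3000 Hz zero-phase band-pass, then
## an adaptive per-electrode threshold at a multiple (default 6) of the
## background-noise SD estimated robustly in 1 s bins.

#' Band-pass filter settings
#'
#' Defaults reproduce the standard MEA acquisition band, 200-3000 Hz,
#' realized as a 4th-order Butterworth applied forward-backward (zero
#' phase).
#'
#' @param low_cut,high_cut Passband edges in Hz (`0 < low_cut < high_cut`).
#' @param order Butterworth order of each pass.
#' @return An object of class `filter_settings`.
#' @export
filter_settings <- function(low_cut = 200, high_cut = 3000, order = 4) {
  check_number(low_cut, "low_cut", lower = 0, allow_zero = FALSE)
  check_number(high_cut, "high_cut", lower = 0, allow_zero = FALSE)
  stop_if(low_cut >= high_cut, "`low_cut` must be below `high_cut`")
  order <- check_count(order, "order", lower = 1L)
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order),
            class = "filter_settings")
}

#' Spike detection settings
#'
#' @param threshold_multiplier Threshold as a multiple of the local noise SD
#'   (default 6).
#' @param noise_window Length in seconds of the non-overlapping bins over
#'   which the noise SD is re-estimated ("1 second binning").
#' @param dead_time Minimum separation between accepted events, s; closer
#'   threshold crossings are merged to the larger extremum.
#' @param polarity Detect on `"both"` polarities (default), `"negative"`
#'   only, or `"positive"` only.
#' @param noise_floor Noise SD (microvolts) below which an electrode is
#'   considered dead; also an absolute floor for the threshold so silent
#'   stretches cannot yield a zero threshold.
#' @return An object of class `detection_settings`.
#' @export
detection_settings <- function(threshold_multiplier = 6, noise_window = 1,
                               dead_time = 0.0015,
                               polarity = c("both", "negative", "positive"),
                               noise_floor = 0.01) {
  check_number(threshold_multiplier, "threshold_multiplier",
               lower = 0, allow_zero = FALSE)
  check_number(noise_window, "noise_window", lower = 0, allow_zero = FALSE)
  check_number(dead_time, "dead_time", lower = 0, allow_zero = FALSE)
  check_number(noise_floor, "noise_floor", lower = 0)
  structure(list(threshold_multiplier = threshold_multiplier,
                 noise_window = noise_window, dead_time = dead_time,
                 polarity = match.arg(polarity), noise_floor = noise_floor),
            class = "detection_settings")
}

## Zero-phase Butterworth band-pass of a single trace.
apply_bandpass <- function(x, sampling_rate, low = 200, high = 3000,
                           order = 4) {
  nyq <- sampling_rate / 2
  stop_if(high >= nyq, "high cutoff %g Hz >= Nyquist %g Hz", high, nyq)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Band-pass filter a voltage recording
#'
#' Applies a zero-phase Butterworth band-pass to every electrode trace.
#' The DC component lies outside the passband and is removed.
#'
#' @param rec A [voltage_recording()].
#' @param settings A [filter_settings()].
#' @return A filtered [voltage_recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, settings = filter_settings()) {
  stop_if(!inherits(rec, "voltage_recording"),
          "`rec` must be a voltage_recording")
  stop_if(!inherits(settings, "filter_settings"),
          "`settings` must be filter_settings")
  stop_if(settings$high_cut >= rec$sampling_rate / 2,
          "high cutoff %g Hz >= Nyquist %g Hz",
          settings$high_cut, rec$sampling_rate / 2)
  out <- rec
  out$traces <- lapply(rec$traces, apply_bandpass,
                       sampling_rate = rec$sampling_rate,
                       low = settings$low_cut, high = settings$high_cut,
                       order = settings$order)
  out$provenance$filter <- unclass(settings)
  out
}

#' Robust per-bin noise SD of a filtered trace
#'
#' The background-noise scale is estimated in non-overlapping bins of
#' `noise_window` seconds as `median(|x|) / 0.6745` (the normal-consistent
#' median absolute deviation about zero), so that sparse large spikes do not
#' inflate the estimate the way a plain SD would.
#'
#' @param x Numeric vector, a filtered single-electrode trace (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param settings A [detection_settings()].
#' @return Numeric vector with one SD estimate per bin; attribute `dead` is
#'   `TRUE` when the median bin estimate falls below `noise_floor` (a
#'   flat/disconnected electrode), never an error.
#' @export
estimate_noise_sd <- function(x, sampling_rate,
                              settings = detection_settings()) {
  stop_if(!inherits(settings, "detection_settings"),
          "`settings` must be detection_settings")
  win <- max(100L, round(settings$noise_window * sampling_rate))
  n_bins <- max(1L, floor(length(x) / win))
  bin_of <- pmin(((seq_along(x) - 1L) %/% win) + 1L, n_bins)
  est <- as.numeric(tapply(abs(x), bin_of, stats::median)) / 0.6745
  attr(est, "dead") <- stats::median(est) < settings$noise_floor
  est
}

## Candidate clustering: indices of supra-threshold samples are grouped
## whenever consecutive candidates are closer than the dead time; each
## cluster contributes its largest-|x| sample as the event.
cluster_extrema <- function(idx, vals, min_gap) {
  if (length(idx) == 0) return(integer(0))
  grp <- cumsum(c(TRUE, diff(idx) >= min_gap))
  vapply(split(seq_along(idx), grp), function(ii) {
    idx[ii[which.max(vals[ii])]]
  }, integer(1), USE.NAMES = FALSE)
}

detect_spikes_trace <- function(x, sampling_rate, dset) {
  noise <- estimate_noise_sd(x, sampling_rate, dset)
  win <- max(100L, round(dset$noise_window * sampling_rate))
  bin_of <- pmin(((seq_along(x) - 1L) %/% win) + 1L, length(noise))
  thr <- dset$threshold_multiplier * pmax(noise, dset$noise_floor)[bin_of]
  y <- switch(dset$polarity,
              both = abs(x),
              negative = pmax(-x, 0),
              positive = pmax(x, 0))
  cand <- which(y >= thr & y > 0)
  # exclude the filter transient at both ends (3 x order samples, order 4)
  edge <- 12L
  cand <- cand[cand > edge & cand <= length(x) - edge]
  ev <- cluster_extrema(cand, y[cand],
                        min_gap = ceiling(dset$dead_time * sampling_rate))
  times <- (ev - 1) / sampling_rate
  dead <- isTRUE(attr(noise, "dead")) && length(times) == 0
  list(times = times, dead = dead)
}

#' Detect spikes with an adaptive per-electrode threshold
#'
#' Each electrode trace is band-pass filtered, its noise SD estimated per
#' bin ([estimate_noise_sd()]), and a spike recorded at every local extremum
#' whose amplitude (according to `polarity`) reaches
#' `threshold_multiplier` times the local noise SD.  Events closer than
#' `dead_time` are merged to the larger extremum.  Thresholds are computed
#' independently per electrode, so detections are invariant to rescaling a
#' trace by a positive constant.  Electrodes whose noise estimate sits below
#' `noise_floor` and that yield no events are flagged dead and reported in
#' the result's `dead` table.
#'
#' @param rec A [voltage_recording()] (raw; filtering is applied here).
#' @param fset A [filter_settings()].
#' @param dset A [detection_settings()].
#' @return A [spike_train_set()] with provenance recording all settings.
#' @export
detect_spikes <- function(rec, fset = filter_settings(),
                          dset = detection_settings()) {
  stop_if(!inherits(rec, "voltage_recording"),
          "`rec` must be a voltage_recording")
  stop_if(rec$duration < dset$noise_window,
          "recording shorter than the noise window")
  stop_if(fset$high_cut >= rec$sampling_rate / 2,
          "high cutoff %g Hz >= Nyquist %g Hz",
          fset$high_cut, rec$sampling_rate / 2)
  keys <- names(rec$traces)
  rows <- vector("list", length(keys))
  dead_rows <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    w <- parts[1]; e <- as.integer(parts[2])
    filt <- apply_bandpass(rec$traces[[i]], rec$sampling_rate,
                           low = fset$low_cut, high = fset$high_cut,
                           order = fset$order)
    det <- detect_spikes_trace(filt, rec$sampling_rate, dset)
    if (length(det$times) > 0) {
      rows[[i]] <- data.frame(well = w, electrode = e, time_s = det$times)
    }
    if (det$dead) {
      dead_rows[[length(dead_rows) + 1L]] <- data.frame(well = w,
                                                        electrode = e)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  spikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(), electrode = integer(), time_s = numeric())
  dead <- if (length(dead_rows)) do.call(rbind, dead_rows) else NULL
  wells <- unique(vapply(strsplit(keys, ".", fixed = TRUE), `[`, "", 1))
  epw <- if (!is.null(rec$layout)) rec$layout$electrodes_per_well else {
    el <- vapply(strsplit(keys, ".", fixed = TRUE),
                 function(p) as.integer(p[2]), integer(1))
    if (length(el)) max(el) else NA_integer_
  }
  spike_train_set(spikes, rec$duration, wells = wells,
                  electrodes_per_well = epw, dead = dead,
                  provenance = list(filter = unclass(fset),
                                    detection = unclass(dset)))
}
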