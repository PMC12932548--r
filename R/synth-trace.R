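## Rendering spike trains into extracellular-like voltage traces: a biphasic
## waveform template stamped at each spike time on top of band-limited
## Gaussian noise.  Overlapping waveforms sum linearly.

#' Canonical biphasic extracellular spike waveform
#'
#' A 1.2 ms biphasic shape (dominant negative deflection followed by a
#' smaller positive rebound), sampled at `sampling_rate` and scaled so the
#' dominant extremum equals `-peak_amplitude`.
#'
#' @param peak_amplitude Absolute amplitude of the dominant (negative)
#'   extremum, in microvolts.
#' @param duration Waveform support in seconds (<= 3 ms).
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `waveform_template` with fields `samples`
#'   (microvolts), `peak_index` (index of the dominant extremum),
#'   `peak_amplitude`, `duration`, `sampling_rate`.
#' @export
waveform_template <- function(peak_amplitude = 50, duration = 0.0012,
                              sampling_rate = 12500) {
  check_number(peak_amplitude, "peak_amplitude", lower = 0, allow_zero = FALSE)
  check_number(duration, "duration", lower = 0, upper = 0.003,
               allow_zero = FALSE)
  n <- max(3L, round(duration * sampling_rate))
  t <- seq(0, 1, length.out = n)
  shape <- -exp(-((t - 0.30) / 0.12)^2) + 0.45 * exp(-((t - 0.65) / 0.18)^2)
  samples <- shape / max(abs(shape)) * peak_amplitude
  structure(list(samples = samples,
                 peak_index = which.max(abs(samples)),
                 peak_amplitude = peak_amplitude,
                 duration = duration,
                 sampling_rate = sampling_rate),
            class = "waveform_template")
}

## Band-limited (200-3000 Hz by default) zero-mean Gaussian noise rescaled
## to an exact target SD; matches the acquisition band so detector
## thresholds behave as on real filtered data.
bandlimited_noise <- function(n, sd, sampling_rate,
                              low = 200, high = 3000) {
  if (sd <= 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n)
  x <- apply_bandpass(x, sampling_rate, low = low, high = high, order = 4)
  x * (sd / stats::sd(x))
}

#' Container for a multielectrode voltage recording
#'
#' @param traces Named list of numeric vectors (microvolts), one per
#'   electrode, named `"<well>.<electrode>"`.
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Duration in seconds; every trace must have
#'   `round(sampling_rate * duration)` samples.
#' @param layout Optional [plate_layout()] reference.
#' @param ground_truth Optional `data.frame` of true spike times (`well`,
#'   `electrode`, `time_s`) retained by the simulator.
#' @param provenance List of generation settings.
#' @return An object of class `voltage_recording`.
#' @export
voltage_recording <- function(traces, sampling_rate, duration, layout = NULL,
                              ground_truth = NULL, provenance = list()) {
  stop_if(!is.list(traces) || is.null(names(traces)),
          "`traces` must be a named list of numeric vectors")
  n_expected <- round(sampling_rate * duration)
  lens <- vapply(traces, length, integer(1))
  stop_if(length(lens) > 0 && any(lens != n_expected),
          "every trace must have round(sampling_rate * duration) = %d samples",
          n_expected)
  structure(list(traces = traces, sampling_rate = sampling_rate,
                 duration = duration, layout = layout,
                 ground_truth = ground_truth, provenance = provenance),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("<voltage_recording> %d electrode(s), %.6g s @ %g Hz\n",
              length(x$traces), x$duration, x$sampling_rate))
  invisible(x)
}

electrode_key <- function(well, electrode) paste(well, electrode, sep = ".")

#' Render spike trains into a voltage recording
#'
#' Stamps `template` at every spike time — the template is aligned so that
#' its dominant extremum falls on the spike's sample, hence detected event
#' times coincide with ground-truth times — on top of zero-mean band-limited
#' Gaussian noise with standard deviation `noise_sd`.  Overlapping waveforms
#' sum linearly.
#'
#' @param trains A [spike_train_set()] (or the `trains` element of a
#'   [generate_spike_trains()] result).
#' @param template A [waveform_template()].
#' @param noise_sd Noise standard deviation in microvolts (>= 0; the
#'   rendered noise SD matches it exactly).
#' @param sampling_rate Sampling rate in Hz.
#' @param wells Wells to render (defaults to all wells of the set).  Full
#'   plates are large; rendering well-by-well keeps memory bounded.
#' @param electrodes_per_well Electrodes per well; defaults to the set's.
#' @param noise_band Length-2 numeric, noise passband in Hz.
#' @param seed Optional integer seed for the noise.
#' @return A [voltage_recording()] with ground-truth spike times attached.
#' @export
render_voltage_trace <- function(trains, template, noise_sd = 5,
                                 sampling_rate = template$sampling_rate,
                                 wells = NULL, electrodes_per_well = NULL,
                                 noise_band = c(200, 3000), seed = NULL) {
  if (inherits(trains, "mea_simulation")) trains <- trains$trains
  stop_if(!inherits(trains, "spike_train_set"),
          "`trains` must be a spike_train_set")
  stop_if(!inherits(template, "waveform_template"),
          "`template` must be a waveform_template")
  stop_if(template$peak_amplitude <= 0, "template peak amplitude must be > 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  stop_if(any(trains$spikes$time_s > trains$duration),
          "spike time beyond recording duration")
  if (is.null(wells)) wells <- trains$wells
  if (is.null(electrodes_per_well)) {
    electrodes_per_well <- trains$electrodes_per_well
  }
  stop_if(is.na(electrodes_per_well),
          "`electrodes_per_well` unknown; pass it explicitly")
  n <- round(sampling_rate * trains$duration)
  tpl <- template$samples
  peak <- template$peak_index
  with_seed(seed, {
    traces <- list()
    for (w in wells) {
      for (e in seq_len(electrodes_per_well)) {
        x <- bandlimited_noise(n, noise_sd, sampling_rate,
                               low = noise_band[1], high = noise_band[2])
        if (noise_sd <= 0) x <- numeric(n)
        tt <- get_train(trains, w, e)
        for (t0 in tt) {
          centre <- round(t0 * sampling_rate) + 1L
          idx <- (centre - peak + 1L):(centre - peak + length(tpl))
          keep <- idx >= 1L & idx <= n
          x[idx[keep]] <- x[idx[keep]] + tpl[keep]
        }
        traces[[electrode_key(w, e)]] <- x
      }
    }
    gt <- trains$spikes[trains$spikes$well %in% wells, , drop = FALSE]
    voltage_recording(traces, sampling_rate, trains$duration,
                      ground_truth = gt,
                      provenance = list(noise_sd = noise_sd,
                                        noise_band = noise_band,
                                        template_peak = template$peak_amplitude,
                                        seed = seed))
  })
}
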