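## Per-electrode and per-well network activity metrics computed from spike
## trains: firing, ISI-threshold bursting, pairwise spike-timing synchrony,
## and an entropy-based multivariate dependence measure.

#' ISI-threshold burst detection settings
#'
#' An electrode burst is a maximal run of at least `min_spikes` consecutive
#' spikes on one electrode in which every inter-spike interval is at most
#' `max_isi` seconds; the defaults (5 spikes, 0.1 s) are the standard
#' ISI-threshold rule.
#'
#' @param min_spikes Minimum number of spikes in a burst (>= 2).
#' @param max_isi Maximum inter-spike interval within a burst, s.
#' @return An object of class `burst_settings`.
#' @export
burst_settings <- function(min_spikes = 5, max_isi = 0.1) {
  min_spikes <- check_count(min_spikes, "min_spikes", lower = 2L)
  check_number(max_isi, "max_isi", lower = 0, allow_zero = FALSE)
  structure(list(min_spikes = min_spikes, max_isi = max_isi),
            class = "burst_settings")
}

#' Synchrony index settings
#'
#' @param window Coincidence half-window in seconds: two spikes on different
#'   electrodes count as coincident when they fall within `window` of each
#'   other.
#' @param bin Time resolution in seconds at which trains are discretized
#'   before the coincidence computation (`bin < window`).
#' @return An object of class `synchrony_settings`.
#' @export
synchrony_settings <- function(window = 0.05, bin = 0.01) {
  check_number(window, "window", lower = 0, allow_zero = FALSE)
  check_number(bin, "bin", lower = 0, allow_zero = FALSE)
  stop_if(window <= bin, "`window` must exceed `bin`")
  structure(list(window = window, bin = bin), class = "synchrony_settings")
}

#' Mean firing rate over an analysis interval
#'
#' Defined as the number of spikes divided by the duration of the analysis,
#' in Hz.
#'
#' @param x Sorted numeric vector of spike times (seconds), or a
#'   [spike_train_set()] together with `well` and `electrode`.
#' @param interval Length-2 numeric analysis interval `(start, end]` in
#'   seconds (the start is included when it is 0).
#' @param well,electrode Electrode address when `x` is a `spike_train_set`.
#' @return Firing rate in Hz.
#' @export
mean_firing_rate <- function(x, interval, well = NULL, electrode = NULL) {
  if (inherits(x, "spike_train_set")) {
    if (missing(interval)) interval <- c(0, x$duration)
    x <- get_train(x, well, electrode)
  }
  stop_if(length(interval) != 2 || diff(interval) <= 0,
          "`interval` must have positive length")
  lo <- interval[1]; hi <- interval[2]
  n <- sum(if (lo == 0) x >= lo & x <= hi else x > lo & x <= hi)
  n / (hi - lo)
}

#' Detect single-electrode bursts by the ISI-threshold rule
#'
#' Returns the maximal runs of consecutive spikes whose inter-spike
#' intervals are all at most `max_isi` and whose length is at least
#' `min_spikes`.  Runs are computed greedily left to right, which for this
#' rule provably yields exactly the maximal qualifying runs; bursts are
#' therefore non-overlapping and not extendable by an adjacent spike.
#'
#' @param times Sorted numeric vector of spike times for one electrode, s.
#' @param settings A [burst_settings()].
#' @return `data.frame` with columns `start`, `end`, `n_spikes`, one row per
#'   burst (zero rows when none).
#' @export
detect_bursts_isi <- function(times, settings = burst_settings()) {
  stop_if(!inherits(settings, "burst_settings"),
          "`settings` must be burst_settings")
  stop_if(is.unsorted(times), "`times` must be sorted ascending")
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer())
  if (length(times) < settings$min_spikes) return(empty)
  ok <- diff(times) <= settings$max_isi
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= settings$min_spikes)
  if (!any(keep)) return(empty)
  i0 <- starts[keep]              # index of first spike of each run
  i1 <- ends[keep] + 1L           # index of last spike
  data.frame(start = times[i0], end = times[i1],
             n_spikes = i1 - i0 + 1L)
}

#' Per-well burst summary
#'
#' The number of bursts for a well is the total count of single-electrode
#' bursts across all its electrodes; the average burst frequency is the
#' mean, over electrodes that burst at all, of their bursts per second.
#'
#' @param trains List of sorted spike-time vectors, one per electrode of
#'   one well.
#' @param settings A [burst_settings()].
#' @param duration Analysis duration in seconds.
#' @return List with `number_of_bursts`, `burst_frequency_avg` (Hz), and
#'   `bursts` (per-electrode `data.frame` with an `electrode` column).
#' @export
well_burst_stats <- function(trains, settings = burst_settings(), duration) {
  stop_if(duration <= 0, "`duration` must be positive")
  per <- lapply(trains, detect_bursts_isi, settings = settings)
  counts <- vapply(per, nrow, integer(1))
  bursts <- do.call(rbind, lapply(seq_along(per), function(e) {
    if (nrow(per[[e]]) == 0) return(NULL)
    cbind(electrode = e, per[[e]])
  }))
  if (is.null(bursts)) {
    bursts <- data.frame(electrode = integer(), start = numeric(),
                         end = numeric(), n_spikes = integer())
  }
  list(number_of_bursts = sum(counts),
       burst_frequency_avg = if (any(counts > 0)) {
         mean(counts[counts > 0] / duration)
       } else 0,
       bursts = bursts)
}

#' Count active electrodes
#'
#' An electrode is active when its mean firing rate over the analysis
#' reaches `min_rate` (default 5 spikes/min, a widespread MEA convention).
#'
#' @param trains List of spike-time vectors, one per electrode.
#' @param duration Analysis duration, s.
#' @param min_rate Activity threshold in Hz.
#' @return Integer count.
#' @export
active_electrodes <- function(trains, duration, min_rate = 5 / 60) {
  stop_if(duration <= 0, "`duration` must be positive")
  rates <- vapply(trains, length, integer(1)) / duration
  sum(rates >= min_rate)
}

## Occupancy vector of a train at resolution `bin`, plus its dilation by
## +/- k bins (1 where any spike lies within the coincidence window).
bin_occupancy <- function(times, n_bins, bin) {
  idx <- pmin(pmax(floor(times / bin) + 1L, 1L), n_bins)
  z <- integer(n_bins)
  z[unique(idx)] <- 1L
  list(z = z, idx = idx)
}

dilate_binary <- function(z, k) {
  n <- length(z)
  s <- cumsum(z)
  hi <- pmin(seq_len(n) + k, n)
  lo <- pmax(seq_len(n) - k - 1L, 0L)
  win <- s[hi] - c(0L, s)[lo + 1L]
  as.integer(win > 0)
}

#' Pairwise spike-timing synchrony index of a well
#'
#' A unitless measure in \[0, 1\]; values closer to 1 indicate higher
#' synchrony.  For each electrode pair the spike time tiling coefficient
#' (STTC) is computed at resolution `bin` with coincidence half-window
#' `window`: with `P_a` the fraction of electrode-a spikes falling within
#' the window of any electrode-b spike and `T_b` the fraction of recording
#' time covered by windows around electrode-b spikes,
#' `STTC = ((P_a - T_b)/(1 - P_a T_b) + (P_b - T_a)/(1 - P_b T_a)) / 2`.
#' The chance-level correction makes independent trains score near 0 while
#' identical trains score 1.  The well index is the mean over all pairs of
#' non-empty electrodes, clipped to \[0, 1\].
#'
#' @param trains List of sorted spike-time vectors, one per electrode.
#' @param duration Recording duration, s.
#' @param settings A [synchrony_settings()].
#' @return Synchrony index in \[0, 1\]; 0 (with attribute
#'   `insufficient = TRUE` and a warning) when fewer than two electrodes
#'   carry spikes.
#' @export
synchrony_index <- function(trains, duration,
                            settings = synchrony_settings()) {
  stop_if(!inherits(settings, "synchrony_settings"),
          "`settings` must be synchrony_settings")
  stop_if(duration <= 0, "`duration` must be positive")
  nonempty <- which(vapply(trains, length, integer(1)) > 0)
  if (length(nonempty) < 2) {
    warning("fewer than 2 active electrodes; synchrony index undefined, ",
            "returning 0")
    return(structure(0, insufficient = TRUE))
  }
  bin <- settings$bin
  k <- round(settings$window / bin)
  n_bins <- max(1L, ceiling(duration / bin))
  occ <- lapply(trains[nonempty], bin_occupancy, n_bins = n_bins, bin = bin)
  dil <- lapply(occ, function(o) dilate_binary(o$z, k))
  tfrac <- vapply(dil, mean, numeric(1))
  m <- length(nonempty)
  vals <- numeric(0)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      pa <- mean(dil[[b]][occ[[a]]$idx])
      pb <- mean(dil[[a]][occ[[b]]$idx])
      ta <- tfrac[a]; tb <- tfrac[b]
      term1 <- if (pa * tb >= 1) 1 else (pa - tb) / (1 - pa * tb)
      term2 <- if (pb * ta >= 1) 1 else (pb - ta) / (1 - pb * ta)
      vals <- c(vals, (term1 + term2) / 2)
    }
  }
  min(max(mean(vals), 0), 1)
}

#' Normalized multiinformation of a well's binned activity
#'
#' Trains are binarized in bins of `bin` seconds; the multiinformation
#' `sum_i H(X_i) - H(X_1, ..., X_m)` (plug-in entropy over observed binary
#' patterns) is normalized by `sum_i H(X_i) - max_i H(X_i)`, its maximum
#' over distributions in which every channel is a deterministic function of
#' one of them, so identical channels score exactly 1 and independent
#' channels near 0.  The result is clipped to \[0, 1\].  At most
#' `max_electrodes` channels (the most active ones) enter the joint-entropy
#' estimate to keep the pattern space identifiable from the available bins.
#'
#' @param trains List of sorted spike-time vectors, one per electrode.
#' @param duration Recording duration, s.
#' @param bin Bin width in seconds (default 0.05).
#' @param max_electrodes Cap on the number of channels entering the joint
#'   entropy (default 12).
#' @return NMI in \[0, 1\]; 0 for wells with fewer than two non-silent
#'   electrodes.
#' @export
normalized_multiinformation <- function(trains, duration, bin = 0.05,
                                        max_electrodes = 12) {
  check_number(bin, "bin", lower = 0, allow_zero = FALSE)
  stop_if(duration <= 0, "`duration` must be positive")
  counts <- vapply(trains, length, integer(1))
  nonempty <- which(counts > 0)
  if (length(nonempty) < 2) return(0)
  if (length(nonempty) > max_electrodes) {
    nonempty <- nonempty[order(-counts[nonempty],
                               seq_along(nonempty))][seq_len(max_electrodes)]
  }
  n_bins <- max(1L, ceiling(duration / bin))
  z <- vapply(trains[nonempty], function(tt) {
    bin_occupancy(tt, n_bins, bin)$z
  }, integer(n_bins))
  plugin_entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h_marg <- apply(z, 2, function(col) {
    plugin_entropy(c(mean(col), 1 - mean(col)))
  })
  code <- as.vector(z %*% 2^(seq_len(ncol(z)) - 1))
  h_joint <- plugin_entropy(as.numeric(table(code)) / n_bins)
  normalizer <- sum(h_marg) - max(h_marg)
  if (normalizer <= 0) return(0)
  min(max((sum(h_marg) - h_joint) / normalizer, 0), 1)
}

#' Assemble the per-well network metric panel
#'
#' Computes the well-level metric set: number of spikes, mean firing rate,
#' number of bursts, average burst frequency, number of active electrodes,
#' synchrony index and normalized multiinformation.
#'
#' The per-well mean firing rate divides the total spike count by the
#' analysis duration times the number of active electrodes
#' (`mfr_mode = "per_active_electrode"`, the default, reported as 0 when no
#' electrode is active), or by the duration alone
#' (`mfr_mode = "well_total"`).
#'
#' @param trains List of sorted spike-time vectors, one per electrode of
#'   one well.
#' @param duration Analysis duration, s.
#' @param burst A [burst_settings()].
#' @param sync A [synchrony_settings()].
#' @param active_min_rate Active-electrode threshold in Hz (default 5
#'   spikes/min).
#' @param mfr_mode See Details.
#' @param nmi_bin,nmi_max_electrodes Passed to
#'   [normalized_multiinformation()].
#' @param compute_nmi Set `FALSE` to skip the (optional) NMI.
#' @return An object of class `well_metrics`: a one-row `data.frame` with
#'   columns `number_of_spikes`, `mean_firing_rate`, `number_of_bursts`,
#'   `burst_frequency_avg`, `n_active_electrodes`, `synchrony_index`, `nmi`.
#' @export
compute_well_metrics <- function(trains, duration,
                                 burst = burst_settings(),
                                 sync = synchrony_settings(),
                                 active_min_rate = 5 / 60,
                                 mfr_mode = c("per_active_electrode",
                                              "well_total"),
                                 nmi_bin = 0.05, nmi_max_electrodes = 12,
                                 compute_nmi = TRUE) {
  mfr_mode <- match.arg(mfr_mode)
  stop_if(duration <= 0, "`duration` must be positive")
  n_spikes <- sum(vapply(trains, length, integer(1)))
  n_active <- active_electrodes(trains, duration, active_min_rate)
  mfr <- if (mfr_mode == "well_total") {
    n_spikes / duration
  } else if (n_active > 0) {
    n_spikes / (duration * n_active)
  } else 0
  bs <- well_burst_stats(trains, burst, duration)
  si <- if (sum(vapply(trains, length, integer(1)) > 0) >= 2) {
    synchrony_index(trains, duration, sync)
  } else 0
  nmi <- if (compute_nmi) {
    normalized_multiinformation(trains, duration, nmi_bin,
                                nmi_max_electrodes)
  } else NA_real_
  out <- data.frame(number_of_spikes = n_spikes,
                    mean_firing_rate = mfr,
                    number_of_bursts = bs$number_of_bursts,
                    burst_frequency_avg = bs$burst_frequency_avg,
                    n_active_electrodes = n_active,
                    synchrony_index = as.numeric(si),
                    nmi = nmi)
  attr(out, "settings") <- list(burst = unclass(burst),
                                sync = unclass(sync),
                                active_min_rate = active_min_rate,
                                mfr_mode = mfr_mode, nmi_bin = nmi_bin)
  class(out) <- c("well_metrics", class(out))
  out
}

#' Per-well metrics for every well of a spike train set
#'
#' @param sts A [spike_train_set()].
#' @param ... Passed to [compute_well_metrics()].
#' @return `data.frame` with one row per well (column `well` first).
#'   Electrodes flagged dead by the detector are dropped before metrics are
#'   computed.
#' @export
compute_plate_metrics <- function(sts, ...) {
  stop_if(!inherits(sts, "spike_train_set"), "`sts` must be a spike_train_set")
  rows <- lapply(sts$wells, function(w) {
    trains <- well_trains(sts, w)
    if (!is.null(sts$dead)) {
      drop <- sts$dead$electrode[sts$dead$well == w]
      for (e in drop) if (e <= length(trains)) trains[[e]] <- numeric(0)
    }
    m <- compute_well_metrics(trains, sts$duration, ...)
    cbind(well = w, as.data.frame(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
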