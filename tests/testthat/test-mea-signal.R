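make_rec <- function(x, fs = 12500) {
  voltage_recording(list(A1.1 = x), fs, length(x) / fs)
}

test_that("band-pass removes DC and mains-range tones but keeps in-band
           signal", {
  fs <- 12500; t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  filt <- function(x) bandpass_filter(make_rec(x))$traces[["A1.1"]]
  dc <- filt(rep(100, fs))
  expect_lt(max(abs(dc[1000:11000])), 1e-4)
  inband <- filt(sin(2 * pi * 1000 * t))
  expect_lt(abs(max(abs(inband[3000:9000])) - 1) , 0.05)
  mains <- filt(sin(2 * pi * 50 * t))
  expect_lt(max(abs(mains[3000:9000])), 0.1)
})

test_that("filter settings are validated against Nyquist", {
  expect_error(filter_settings(low_cut = 500, high_cut = 300), "below")
  rec <- make_rec(rnorm(12500))
  expect_error(bandpass_filter(rec, filter_settings(high_cut = 7000)),
               "Nyquist")
})

test_that("noise SD estimator is consistent and robust to spikes", {
  set.seed(1)
  x <- rnorm(12500 * 4, sd = 5)
  est <- estimate_noise_sd(x, 12500)
  expect_equal(length(est), 4)
  expect_true(all(abs(est - 5) < 0.5))
  expect_false(attr(est, "dead"))
  ## sparse large spikes: robust estimate stays near 5, plain SD does not
  xs <- x
  spike_at <- seq(6000, length(xs) - 20, by = 12500)
  for (i in spike_at) xs[i:(i + 14)] <- xs[i:(i + 14)] +
      waveform_template(100)$samples
  est_s <- estimate_noise_sd(xs, 12500)
  expect_true(all(abs(est_s - 5) < 0.5))
  expect_gt(sd(xs), max(est_s))   # the naive estimator is inflated
  zero <- estimate_noise_sd(numeric(25000), 12500)
  expect_true(all(zero == 0))
  expect_true(attr(zero, "dead"))
})

test_that("noiseless template spikes are each detected once at their
           insertion time", {
  tt <- seq(0.5, 9.5, by = 1)
  sts0 <- spike_train_set(data.frame(well = "A1", electrode = 1L,
                                     time_s = tt),
                          duration = 10, wells = "A1",
                          electrodes_per_well = 1L)
  rec <- render_voltage_trace(sts0, waveform_template(50), noise_sd = 0)
  det <- detect_spikes(rec)
  got <- get_train(det, "A1", 1)
  expect_equal(length(got), 10)
  expect_true(all(abs(got - tt) <= 0.0005))
})

test_that("raising the threshold multiplier never adds detections", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 1, duration = 20)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 2,
                                                     burst_rate = 4,
                                                     seed = 8))
  rec <- render_voltage_trace(sim$trains, waveform_template(30),
                              noise_sd = 5, seed = 8)
  counts <- vapply(c(3, 4.5, 6, 8), function(k) {
    nrow(detect_spikes(rec,
                       dset = detection_settings(threshold_multiplier = k)
                       )$spikes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is scale-equivariant and electrode-independent", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 2, duration = 20)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 2,
                                                     seed = 4))
  rec <- render_voltage_trace(sim$trains, waveform_template(50),
                              noise_sd = 5, seed = 4)
  det1 <- detect_spikes(rec)
  rec10 <- rec
  rec10$traces <- lapply(rec$traces, `*`, 10)
  det10 <- detect_spikes(rec10)
  expect_equal(det1$spikes, det10$spikes)
  swapped <- rec
  swapped$traces <- rec$traces[c("A1.2", "A1.1")]
  names(swapped$traces) <- c("A1.1", "A1.2")
  det_sw <- detect_spikes(swapped)
  expect_equal(get_train(det_sw, "A1", 2), get_train(det1, "A1", 1))
  expect_equal(get_train(det_sw, "A1", 1), get_train(det1, "A1", 2))
})

test_that("detector reaches its operating point at SNR 10 on a small
           recording", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 2, duration = 30)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 2,
                                                     burst_rate = 6,
                                                     seed = 21))
  rec <- render_voltage_trace(sim$trains, waveform_template(50),
                              noise_sd = 5, seed = 22)
  det <- detect_spikes(rec)
  for (e in 1:2) {
    m <- match_events(get_train(det, "A1", e),
                      get_train(sim$trains, "A1", e))
    expect_gte(m$recall, 0.95)
    expect_gte(m$precision, 0.95)
  }
})

test_that("flat electrodes are flagged dead, not raised as errors", {
  rec <- make_rec(numeric(25000))
  det <- detect_spikes(rec)
  expect_equal(nrow(det$spikes), 0)
  expect_equal(det$dead, data.frame(well = "A1", electrode = 1L))
})
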