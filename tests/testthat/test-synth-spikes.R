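test_that("silent spec yields empty trains and empty ground truth", {
  lay <- plate_layout(n_wells = 2, electrodes_per_well = 4, duration = 30)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 0,
                                                     burst_rate = 0,
                                                     seed = 1))
  expect_equal(nrow(sim$trains$spikes), 0)
  expect_equal(nrow(sim$bursts), 0)
})

test_that("background spike counts follow the Poisson expectation", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 100,
                      duration = 300)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 1,
                                                     burst_rate = 0,
                                                     seed = 11))
  n <- nrow(sim$trains$spikes)
  expect_lt(abs(n - 30000), 3 * sqrt(30000))
})

test_that("ground-truth bursts are detectable under the ISI rule and are
           present in the trains", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 8, duration = 120)
  spec <- spike_train_spec(background_rate = 0, burst_rate = 6,
                           spikes_per_burst_mean = 8,
                           intra_burst_isi = 0.02, seed = 5)
  sim <- generate_spike_trains(lay, spec)
  expect_gt(nrow(sim$bursts), 0)
  expect_true(all(sim$bursts$n_spikes >= 5))
  for (k in seq_len(nrow(sim$bursts))) {
    b <- sim$bursts[k, ]
    tt <- get_train(sim$trains, b$well, b$electrode)
    inside <- tt[tt >= b$start & tt <= b$end]
    expect_equal(length(inside), b$n_spikes)
    expect_true(all(diff(inside) <= 0.1))
  }
})

test_that("generation is deterministic in the seed and times stay in
           range", {
  lay <- plate_layout(n_wells = 2, electrodes_per_well = 4, duration = 60)
  spec <- spike_train_spec(seed = 42)
  a <- generate_spike_trains(lay, spec)
  b <- generate_spike_trains(lay, spec)
  expect_identical(a$trains$spikes, b$trains$spikes)
  expect_identical(a$bursts, b$bursts)
  expect_true(all(a$trains$spikes$time_s >= 0 &
                    a$trains$spikes$time_s <= 60))
  d <- generate_spike_trains(lay, spike_train_spec(seed = 43))
  expect_false(identical(a$trains$spikes, d$trains$spikes))
})

test_that("invalid layouts and specs are rejected", {
  expect_error(plate_layout(duration = 0), "positive")
  expect_error(plate_layout(duration = -5), "positive")
  expect_error(spike_train_spec(background_rate = -1))
  expect_error(spike_train_spec(synchrony_coupling = 1.5))
})

test_that("dose effects scale generator parameters and validate inputs", {
  eff <- dose_effect_spec(data.frame(
    dose = c(0, 10, 10), timepoint = c(0, 0, 24), factor = c(1, 1, 0.5)))
  base <- spike_train_spec(background_rate = 2, burst_rate = 6)
  same <- apply_dose_effect(base, eff, 10, 0)
  expect_equal(same$background_rate, 2)
  half <- apply_dose_effect(base, eff, 10, 24)
  expect_equal(half$background_rate, 1)
  expect_equal(half$burst_rate, 3)
  expect_equal(attr(half, "dose_effect")$factor, 0.5)
  expect_error(apply_dose_effect(base, eff, 99, 24), "no factor")
  morph <- morphology_spec(segment_length = c(30, 60))
  shrunk <- apply_dose_effect(morph, eff, 10, 24)
  expect_equal(shrunk$segment_length, c(15, 30))
  expect_error(dose_effect_spec(data.frame(dose = 0, timepoint = 0,
                                           factor = 2)),
               "factor must be 1")
})
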