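empty_set <- function(duration, wells = "A1", epw = 1L) {
  spike_train_set(data.frame(well = character(), electrode = integer(),
                             time_s = numeric()),
                  duration, wells = wells, electrodes_per_well = epw)
}

test_that("waveform template is biphasic with a single dominant extremum", {
  tpl <- waveform_template(peak_amplitude = 50)
  expect_lte(tpl$duration, 0.003)
  expect_equal(min(tpl$samples), -50)
  expect_lt(max(tpl$samples), 50 * 0.6)         # rebound clearly smaller
  expect_equal(sum(abs(tpl$samples) > 49), 1)   # one dominant extremum
})

test_that("pure-noise traces carry the requested SD and band", {
  rec <- render_voltage_trace(empty_set(10), waveform_template(),
                              noise_sd = 5, seed = 3)
  x <- rec$traces[["A1.1"]]
  expect_equal(length(x), 125000)
  expect_lt(abs(sd(x) - 5) / 5, 0.1)
  expect_lt(abs(mean(x)), 0.5)
})

test_that("a noiseless spike reproduces the template at its sample, peak
           aligned", {
  sts <- spike_train_set(data.frame(well = "A1", electrode = 1L,
                                    time_s = 1.0),
                         duration = 2, wells = "A1",
                         electrodes_per_well = 1L)
  tpl <- waveform_template(peak_amplitude = 40)
  rec <- render_voltage_trace(sts, tpl, noise_sd = 0)
  x <- rec$traces[["A1.1"]]
  centre <- round(1.0 * 12500) + 1
  expect_equal(which.max(abs(x)), centre)
  expect_equal(x[centre], -40)
  span <- (centre - tpl$peak_index + 1):(centre - tpl$peak_index +
                                           length(tpl$samples))
  expect_equal(x[span], tpl$samples)
  expect_true(all(x[-span] == 0))
})

test_that("every ground-truth spike is stamped into the trace
           (conservation)", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 2, duration = 20)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 1,
                                                     burst_rate = 2,
                                                     seed = 2))
  tpl <- waveform_template(peak_amplitude = 40)
  rec <- render_voltage_trace(sim$trains, tpl, noise_sd = 0)
  for (e in 1:2) {
    tt <- get_train(sim$trains, "A1", e)
    x <- rec$traces[[paste0("A1.", e)]]
    ## linear superposition: total stamped mass equals spikes x template
    expect_equal(sum(x), length(tt) * sum(tpl$samples), tolerance = 1e-6)
    expect_equal(nrow(rec$ground_truth[rec$ground_truth$electrode == e, ]),
                 length(tt))
  }
})

test_that("spike times beyond the recording duration are rejected", {
  sts <- spike_train_set(data.frame(well = "A1", electrode = 1L,
                                    time_s = 1.5),
                         duration = 2, wells = "A1",
                         electrodes_per_well = 1L)
  sts$duration <- 1   # corrupt after construction
  expect_error(render_voltage_trace(sts, waveform_template(), noise_sd = 0),
               "beyond")
})

test_that("rendering is deterministic in the seed", {
  a <- render_voltage_trace(empty_set(5), waveform_template(),
                            noise_sd = 5, seed = 9)
  b <- render_voltage_trace(empty_set(5), waveform_template(),
                            noise_sd = 5, seed = 9)
  expect_identical(a$traces, b$traces)
})
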