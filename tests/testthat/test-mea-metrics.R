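test_that("mean firing rate is count over duration, exactly", {
  expect_equal(mean_firing_rate(seq(0.5, 299.5, by = 1), c(0, 300)), 1.0)
  expect_equal(mean_firing_rate(numeric(0), c(0, 300)), 0.0)
  set.seed(3)
  tt <- sort(runif(737, 0, 120))
  expect_identical(mean_firing_rate(tt, c(0, 120)), length(tt) / 120)
  expect_error(mean_firing_rate(tt, c(10, 10)), "positive")
})

test_that("ISI-threshold burst detection matches the worked examples", {
  b <- detect_bursts_isi(c(0, .05, .10, .15, .20, .25))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 6L)
  expect_equal(c(b$start, b$end), c(0, 0.25))
  expect_equal(nrow(detect_bursts_isi(c(0, .05, .10, .15))), 0)
  expect_error(detect_bursts_isi(c(1, 0.5)), "sorted")
})

test_that("burst detection equals the brute-force maximal-run oracle on
           random trains", {
  for (s in 1:200) {
    tt <- random_mixed_train(s)
    expect_equal(detect_bursts_isi(tt), brute_force_bursts(tt),
                 ignore_attr = TRUE)
  }
})

test_that("bursts are maximal, non-overlapping, and contained in the
           train", {
  for (s in c(7, 77, 777)) {
    tt <- random_mixed_train(s)
    b <- detect_bursts_isi(tt)
    if (nrow(b) == 0) next
    expect_true(all(b$end[-nrow(b)] < b$start[-1]))
    expect_lte(sum(b$n_spikes), length(tt))
    for (k in seq_len(nrow(b))) {
      i0 <- which(tt == b$start[k]); i1 <- which(tt == b$end[k])
      if (i0 > 1) expect_gt(tt[i0] - tt[i0 - 1], 0.1)
      if (i1 < length(tt)) expect_gt(tt[i1 + 1] - tt[i1], 0.1)
    }
  }
})

test_that("well burst statistics aggregate per the definitions", {
  mk <- function(n) if (n == 0) numeric(0) else
    as.vector(vapply(seq_len(n), function(k) 10 * k + seq(0, 0.2, by = .05),
                     numeric(5)))
  trains <- list(mk(2), mk(0), mk(4))
  ws <- well_burst_stats(trains, duration = 60)
  expect_equal(ws$number_of_bursts, 6)
  expect_equal(ws$burst_frequency_avg, mean(c(2, 4) / 60))
  empty <- well_burst_stats(list(numeric(0), numeric(0)), duration = 60)
  expect_equal(empty$number_of_bursts, 0)
  expect_equal(empty$burst_frequency_avg, 0)
})

test_that("active-electrode counting applies the 5 spikes/min rule", {
  expect_equal(active_electrodes(list(numeric(0), numeric(0)), 60), 0)
  expect_equal(active_electrodes(list(seq(0.5, 59.5, 1), numeric(0)), 60),
               1)
  set.seed(9)
  trains <- lapply(1:20, function(i) sort(runif(rpois(1, 8), 0, 60)))
  oracle <- sum(vapply(trains, length, integer(1)) / 60 >= 5 / 60)
  expect_equal(active_electrodes(trains, 60), oracle)
})

test_that("synchrony index separates identical, independent and coupled
           activity", {
  set.seed(5)
  tt <- sort(runif(200, 0, 120))
  expect_gt(synchrony_index(list(tt, tt), 120), 0.9)
  vals <- vapply(1:5, function(s) {
    set.seed(s)
    trains <- lapply(1:8, function(i) sort(runif(120, 0, 120)))
    synchrony_index(trains, 120)
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
  expect_warning(si <- synchrony_index(list(tt, numeric(0)), 120),
                 "fewer than 2")
  expect_equal(as.numeric(si), 0)
})

test_that("synchrony index is invariant to a common time shift", {
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 6, duration = 60)
  sim <- generate_spike_trains(lay, spike_train_spec(synchrony_coupling = .7,
                                                     seed = 31))
  trains <- well_trains(sim$trains, "A1")
  shift <- 0.5   # a multiple of the 10 ms discretization
  shifted <- lapply(trains, function(tt) (tt + shift) %% 60)
  shifted <- lapply(shifted, sort)
  a <- synchrony_index(trains, 60)
  b <- synchrony_index(shifted, 60)
  expect_lt(abs(a - b), 0.05)
})

test_that("normalized multiinformation hits its boundary cases", {
  set.seed(8)
  tt <- sort(runif(300, 0, 300))
  expect_equal(normalized_multiinformation(list(tt, tt, tt), 300), 1)
  expect_equal(normalized_multiinformation(list(tt), 300), 0)
  expect_equal(normalized_multiinformation(list(numeric(0), numeric(0)),
                                           300), 0)
  indep <- lapply(1:6, function(i) sort(runif(300, 0, 300)))
  expect_lte(normalized_multiinformation(indep, 300), 0.05)
})

test_that("well metric assembly is symmetric and matches generative
           rates", {
  empty <- compute_well_metrics(list(numeric(0), numeric(0)), 60)
  expect_equal(empty$number_of_spikes, 0)
  expect_equal(empty$mean_firing_rate, 0)
  expect_equal(empty$synchrony_index, 0)
  lay <- plate_layout(n_wells = 1, electrodes_per_well = 16,
                      duration = 300)
  sim <- generate_spike_trains(lay, spike_train_spec(background_rate = 1,
                                                     burst_rate = 0,
                                                     seed = 17))
  trains <- well_trains(sim$trains, "A1")
  m <- compute_well_metrics(trains, 300)
  expect_equal(m$n_active_electrodes, 16)
  expect_lt(abs(m$mean_firing_rate - 1) / 1, 0.05)
  perm <- compute_well_metrics(trains[sample(16)], 300)
  expect_equal(as.data.frame(m), as.data.frame(perm), ignore_attr = TRUE)
  ## per-well total convention
  m2 <- compute_well_metrics(trains, 300, mfr_mode = "well_total")
  expect_equal(m2$mean_firing_rate, m$number_of_spikes / 300)
})
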