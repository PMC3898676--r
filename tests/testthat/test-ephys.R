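test_that("voltage trial and trial set validate their metadata", {
  expect_error(voltage_trial(rep(0, 100), 10000, stimulus_onset = 5),
               "outside the trace")
  expect_error(voltage_trial(c(0, NA), 10000, 0), "finite")
  v1 <- voltage_trial(rep(0, 1000), 10000, 0.05)
  v2 <- voltage_trial(rep(0, 1000), 11100, 0.05)
  expect_error(trial_set(list(v1, v2)), "sampling rate")
  ts <- trial_set(list(v1), control_label = "oil")
  expect_s3_class(ts, "trial_set")
})

test_that("trial sets round-trip through the CSV directory format", {
  sim <- simulate_trialset(ephys_sim_spec(onset = 0.3, post_s = 0.2,
                                          n_trials = 2L, seed = 9L),
                           odors = "cVA")
  dir <- withr::local_tempdir()
  write_trials(sim$trialset, dir)
  back <- read_trials(dir)
  expect_equal(length(back$trials), length(sim$trialset$trials))
  for (i in seq_along(back$trials)) {
    expect_equal(back$trials[[i]]$voltage, sim$trialset$trials[[i]]$voltage)
    expect_equal(back$trials[[i]]$stimulus_label,
                 sim$trialset$trials[[i]]$stimulus_label)
    expect_equal(back$trials[[i]]$stimulus_onset,
                 sim$trialset$trials[[i]]$stimulus_onset)
  }
  expect_equal(back$control_label, "mineral_oil")
  unlink(file.path(dir, "trials.csv"))
  expect_error(read_trials(dir), "sidecar")
})

test_that("binomial smoothing has the stated kernel and frequency response", {
  fs <- 11100
  k <- binomial_kernel(400, fs)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_true(length(k) %% 2L == 1L)
  expect_lte(attr(k, "f3db"), 400)

  # a shorter kernel (two fewer taps) must NOT reach the cutoff
  m_short <- length(k) - 3L
  f3db_short <- fs / pi * acos(2^(-1 / (2 * m_short)))
  expect_gt(f3db_short, 400)

  flat <- voltage_trial(rep(-55, 5000), fs, 0.1)
  expect_equal(binomial_smooth(flat, 400)$voltage, rep(-55, 5000))

  imp <- voltage_trial(c(rep(0, 2000), 1, rep(0, 2000)), fs, 0.1)
  sm <- binomial_smooth(imp, 400)$voltage
  got <- sm[sm > 0]
  expect_equal(got, as.numeric(k), tolerance = 1e-12)

  # sine at the kernel's -3 dB frequency attenuates to ~1/sqrt(2)
  f <- attr(k, "f3db")
  tt <- seq_len(4 * fs) / fs
  sine <- voltage_trial(sin(2 * pi * f * tt), fs, 1)
  out <- binomial_smooth(sine, 400)$voltage
  core <- seq.int(fs, 3 * fs)   # avoid edges
  gain <- max(abs(out[core]))
  expect_equal(gain, 1 / sqrt(2), tolerance = 0.05)

  # range can never grow
  set.seed(4)
  noisy <- voltage_trial(rnorm(5000), fs, 0.1)
  expect_lte(diff(range(binomial_smooth(noisy, 400)$voltage)),
             diff(range(noisy$voltage)))
  expect_error(binomial_smooth(flat, 6000), "Nyquist")
})

test_that("spike detection finds injected spikes and rejects noise", {
  fs <- 11100
  set.seed(10)
  # noise-only traces: false positives are essentially absent
  fp <- 0
  for (i in 1:25) {
    v <- voltage_trial(-55 + rnorm(2 * fs, sd = 0.2), fs, 0.5)
    fp <- fp + length(detect_spikes(v)$times)
  }
  expect_lt(fp / (25 * 2), 0.1)   # < 0.1 false spikes per second

  # injected spikes: recover 20/20 within 1 ms
  set.seed(11)
  inject <- sort(runif(20, 0.1, 1.9))
  inject <- inject[c(TRUE, diff(inject) > 0.005)]
  v <- voltage_trial(-55 + rnorm(2 * fs, sd = 0.5), fs, 0.5)
  v$voltage <- pherocircuit:::add_spikes(v$voltage, inject, 40, 0.002, fs)
  st <- detect_spikes(v)
  hits <- vapply(inject, function(t0) any(abs(st$times - t0) <= 1e-3),
                 logical(1L))
  expect_gte(sum(hits), length(inject) - 1L)

  # refractory rule merges spikes 1 ms apart into one event
  v2 <- voltage_trial(rep(-55, fs), fs, 0.01)
  v2$voltage <- pherocircuit:::add_spikes(v2$voltage, c(0.5, 0.501), 40,
                                          0.002, fs)
  expect_length(detect_spikes(v2)$times, 1L)

  # DC invariance
  v3 <- v; v3$voltage <- v3$voltage + 30
  expect_equal(detect_spikes(v3)$times, st$times)

  expect_error(detect_spikes(v, threshold_mode = "fixed"),
               "threshold_value")
})

test_that("detection recall and precision clear 0.95 on the benchmark", {
  tp <- fp <- fn <- 0
  for (s in 1:10) {
    esp <- ephys_sim_spec(seed = s, onset = 0.5, post_s = 0.35,
                          refractory_ms = 3, noise_sd = 0.5,
                          spike_amplitude = 40)
    sim <- simulate_trialset(esp, odors = "cVA")
    for (i in seq_along(sim$trialset$trials)) {
      st <- detect_spikes(sim$trialset$trials[[i]])
      tru <- sim$truth$spikes[[i]]
      for (t0 in tru) {
        if (any(abs(st$times - t0) <= 1e-3)) tp <- tp + 1 else fn <- fn + 1
      }
      for (t0 in st$times) {
        if (!any(abs(tru - t0) <= 1e-3)) fp <- fp + 1
      }
    }
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})
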