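test_that("window spike counts use the half-open 150-650 ms window", {
  st <- spike_train(c(0.2, 0.4, 0.7) + 1)
  expect_equal(window_spike_count(st, onset = 1), 2)
  expect_equal(window_spike_count(spike_train(numeric(0)), 1), 0)
  set.seed(3)
  times <- sort(runif(100, 0, 3))
  st <- spike_train(times)
  expect_equal(window_spike_count(st, 1),
               sum(times >= 1.15 & times < 1.65))
  expect_error(window_spike_count(st, 1, length = -1), "nonnegative")
})

test_that("response magnitude subtracts the control mean", {
  m <- response_magnitude(c(4, 5, 4, 5), c(1, 1, 1, 1), 0.5)
  expect_equal(m$mean_response, 3.5)
  expect_equal(m$rate_hz, 7)
  expect_equal(response_magnitude(1:4, 1:4)$mean_response, 0)
  set.seed(8)
  a <- rpois(6, 5); b <- rpois(6, 2)
  expect_equal(response_magnitude(a, b, 0.5)$mean_response,
               sum(a) / 6 - sum(b) / 6)
  expect_error(response_magnitude(numeric(0), 1), "nonempty")
})

test_that("the exact Poisson test equals the binomial tail", {
  expect_equal(poisson_response_test(10, 2), 79 / 4096)
  expect_gte(poisson_response_test(c(3, 2), c(4, 1)), 0.5)  # K_o == K_c
  expect_equal(poisson_response_test(0, 0), 1)
  for (ko in c(0L, 3L, 17L)) for (kc in c(0L, 5L, 12L)) {
    expect_equal(poisson_response_test(ko, kc), binom_tail(ko, kc),
                 tolerance = 1e-12)
  }
  # unequal exposure: 8 odor trials vs 4 control trials
  p <- poisson_response_test(rep(2, 8), rep(2, 4), exposure_ratio = 2)
  expect_equal(p, pbinom(15, 24, 2 / 3, lower.tail = FALSE))
  expect_error(poisson_response_test(-1, 2), "nonnegative")
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  set.seed(14)
  for (i in 1:5) {
    p <- runif(sample(3:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, hand_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # permutation equivariance
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("peak firing rate is the max over five 200 ms windows", {
  # spikes only in the third window [0.55, 0.75) after onset 0
  st <- spike_train(c(0.56, 0.60, 0.65, 0.70))
  expect_equal(peak_firing_rate(st, 0), 20)
  expect_equal(peak_firing_rate(spike_train(numeric(0)), 0), 0)
  set.seed(5)
  times <- sort(runif(60, 0, 2))
  st <- spike_train(times)
  brute <- max(vapply(0:4, function(w) {
    sum(times >= 0.15 + w * 0.2 & times < 0.35 + w * 0.2)
  }, numeric(1L))) / 0.2
  expect_equal(peak_firing_rate(st, 0), brute)
})

test_that("lifetime sparseness hits its bounds and known values", {
  expect_equal(lifetime_sparseness(rep(7, 8)), 0)
  expect_equal(lifetime_sparseness(c(11, 0, 0, 0, 0)), 1)
  expect_equal(lifetime_sparseness(c(2, 1, 0, 0)), 0.733333,
               tolerance = 1e-6)
  expect_equal(lifetime_sparseness(rep(0, 4)), 0)
  # scale invariance and rectification
  set.seed(6)
  r <- rexp(7)
  expect_equal(lifetime_sparseness(3.7 * r), lifetime_sparseness(r))
  expect_equal(lifetime_sparseness(c(2, 1, -3, 0)),
               lifetime_sparseness(c(2, 1, 0, 0)))
  expect_error(lifetime_sparseness(5), "at least 2")
})

test_that("subthreshold response measures peak depolarization over baseline", {
  fs <- 11100
  flat <- flat_trial(dur_s = 3, onset = 1.5)
  expect_equal(subthreshold_response(flat), 0)

  # injected 4 mV plateau from +300 to +600 ms
  v <- flat
  tt <- seq_along(v$voltage) / fs
  v$voltage <- v$voltage + 4 * (tt >= 1.8 & tt < 2.1)
  r <- subthreshold_response(v)
  expect_equal(r, 4, tolerance = 0.2)
  v$voltage <- v$voltage + 12   # DC offset invariance
  expect_equal(subthreshold_response(v), r)
  expect_error(subthreshold_response(flat_trial(dur_s = 1, onset = 0.5)),
               "outside trace")
})

test_that("group permutation test matches exact enumeration", {
  expect_equal(group_comparison_test(c(1, 2), c(1, 2)), 1)
  expect_equal(group_comparison_test(c(0, 0, 0), c(10, 10, 10)), 0.1)
  # one-sided orientation
  expect_equal(group_comparison_test(c(10, 11, 12), c(0, 1, 2),
                                     alternative = "greater"), 1 / 20)
  # Monte-Carlo branch is seeded and reproducible
  set.seed(99)
  a <- rnorm(12); b <- rnorm(12) + 1
  p1 <- group_comparison_test(a, b, n_perm = 500, seed = 7)
  p2 <- group_comparison_test(a, b, n_perm = 500, seed = 7)
  expect_identical(p1, p2)
  expect_error(group_comparison_test(numeric(0), 1), "nonempty")
})

test_that("permutation test holds its type-I error under the null", {
  # exact branch: n = 8 + 8
  set.seed(20)
  rej <- vapply(1:400, function(i) {
    group_comparison_test(rnorm(8), rnorm(8)) <= 0.05
  }, logical(1L))
  expect_gte(mean(rej), 0.03); expect_lte(mean(rej), 0.07)
  # Monte-Carlo branch: n = 10 + 10
  set.seed(21)
  rej <- vapply(1:300, function(i) {
    group_comparison_test(rnorm(10), rnorm(10), n_perm = 400,
                          seed = i) <= 0.05
  }, logical(1L))
  expect_gte(mean(rej), 0.03); expect_lte(mean(rej), 0.07)
})

test_that("subthreshold permutation test behaves at the extremes", {
  # zero-variance identical traces: p = 1
  trials <- lapply(1:4, function(i)
    voltage_trial(rep(-55, 6 * 11100), 11100, 4.8,
                  stimulus_label = "cVA", cell_id = "c1"))
  ts <- trial_set(trials, control_label = NA_character_)
  res <- subthreshold_test(ts)
  expect_equal(res$raw_p, 1)
  expect_false(res$significant)
  expect_length(attr(res, "null_pseudo_responses"), 8L)

  # large injected response: FDR-significant at 0.01
  sig <- vapply(1:10, function(s) {
    sim <- simulate_trialset(
      ephys_sim_spec(seed = s, onset = 4.8, post_s = 0.5,
                     epsp_amplitude = 5, odor_rate_hz = 0,
                     control_rate_hz = 0),
      odors = "cVA")
    st <- subset_trials(sim$trialset, stimulus_label = "cVA")
    st$control_label <- NA_character_
    subthreshold_test(st)$adjusted_p < 0.01
  }, logical(1L))
  expect_true(all(sig))

  # insufficient pre-stimulus room is refused
  short <- trial_set(list(voltage_trial(rep(-55, 22200), 11100, 1,
                                        stimulus_label = "cVA")),
                     control_label = NA_character_)
  expect_error(subthreshold_test(short), "pre-stimulus")
})

test_that("response table flags responsive odors per cell", {
  sim_counts <- function(seed, odor_rate, cell) {
    esp <- ephys_sim_spec(seed = seed, onset = 0.3, post_s = 0.2,
                          odor_rate_hz = odor_rate)
    simulate_trialset(esp, odors = c("cVA", "PA"), responsive = "cVA",
                      cell_id = cell)
  }
  sim <- sim_counts(33L, 40, "c1")
  trains <- lapply(seq_along(sim$trialset$trials), function(i)
    spike_train(sim$truth$spikes[[i]], sim$trialset$trials[[i]]))
  tab <- response_table(trains, control_label = "mineral_oil")
  expect_setequal(tab$stimulus_label, c("cVA", "PA"))
  expect_true(tab$significant[tab$stimulus_label == "cVA"])
  expect_false(tab$significant[tab$stimulus_label == "PA"])
  expect_true(all(tab$adjusted_p >= tab$raw_p))
  expect_gt(tab$rate_hz[tab$stimulus_label == "cVA"], 20)
})
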