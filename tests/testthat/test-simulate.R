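test_that("generators are pure functions of spec and seed", {
  ms <- morpho_population_spec(n_per_group = 3L, seed = 42L)
  p1 <- simulate_skeleton_population(ms)
  p2 <- simulate_skeleton_population(ms)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_swc(p1$skeletons[[1]], f1); write_swc(p2$skeletons[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  es <- ephys_sim_spec(onset = 0.3, post_s = 0.2, seed = 43L)
  s1 <- simulate_trialset(es); s2 <- simulate_trialset(es)
  expect_identical(s1$trialset$trials[[1]]$voltage,
                   s2$trialset$trials[[1]]$voltage)
  expect_identical(s1$truth$spikes, s2$truth$spikes)

  sp1 <- simulate_stimulation_pair(seed = 44L)
  sp2 <- simulate_stimulation_pair(seed = 44L)
  expect_identical(sp1$pair$test_trials[[1]]$voltage,
                   sp2$pair$test_trials[[1]]$voltage)
})

test_that("generated objects satisfy their container invariants", {
  pop <- simulate_skeleton_population(morpho_population_spec(
    n_per_group = 4L, seed = 7L))
  for (sk in pop$skeletons) {
    expect_s3_class(sk, "neuron_skeleton")  # constructor ran validation
    expect_equal(sum(is.na(sk$nodes$parent_id)), 1L)
  }
  sim <- simulate_trialset(ephys_sim_spec(onset = 0.3, post_s = 0.2,
                                          seed = 8L),
                           odors = c("cVA", "PA"), responsive = "cVA")
  expect_s3_class(sim$trialset, "trial_set")
  expect_equal(length(sim$trialset$trials), 3L * 4L)
  expect_true(all(vapply(sim$truth$spikes, function(s)
    !is.unsorted(s, strictly = TRUE), logical(1L))))
})

test_that("zero jitter with a fixed branch count gives identical group members", {
  ms <- morpho_population_spec(n_per_group = 3L, jitter_sd = 0,
                               branch_count = c(5L, 5L), seed = 9L)
  pop <- simulate_skeleton_population(ms)
  a <- pop$skeletons[names(pop$labels)[pop$labels == "A"]]
  coords <- lapply(a, function(s) s$nodes[, c("x", "y", "z")])
  expect_equal(coords[[2]], coords[[1]], ignore_attr = TRUE)
  expect_equal(coords[[3]], coords[[1]], ignore_attr = TRUE)
})

test_that("group separation shows up in dot-property distances", {
  ok <- vapply(1:5, function(s) {
    pop <- simulate_skeleton_population(morpho_population_spec(
      n_per_group = 3L, jitter_sd = 2, seed = s))
    dps <- lapply(pop$skeletons, function(x) to_dotprops(x, 5))
    dm <- distance_matrix(dps)$values
    same <- outer(pop$labels, pop$labels, "==") & upper.tri(dm)
    diff_g <- outer(pop$labels, pop$labels, "!=") & upper.tri(dm)
    mean(dm[same]) < mean(dm[diff_g])
  }, logical(1L))
  expect_true(all(ok))
})

test_that("window spike counts from the generator are Poisson", {
  set.seed(123)
  rate <- 40; win <- 0.5
  counts <- replicate(1000, length(sim_spike_times(rate, 0, win)))
  lambda <- rate * win
  # chi-squared GOF against Poisson(lambda), tail-pooled to expected >= 5
  breaks <- qpois(c(0.001, 0.999), lambda)
  cells <- breaks[1]:breaks[2]
  obs <- vapply(cells, function(k) sum(counts == k), numeric(1L))
  obs <- c(sum(counts < cells[1]), obs, sum(counts > cells[length(cells)]))
  pr <- dpois(cells, lambda)
  pr <- c(ppois(cells[1] - 1, lambda), pr,
          ppois(cells[length(cells)], lambda, lower.tail = FALSE))
  keep <- pr * 1000 >= 5
  chi <- sum((obs[keep] - 1000 * pr[keep])^2 / (1000 * pr[keep]))
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("null odor trials produce zero expected response magnitude", {
  diffs <- vapply(1:200, function(s) {
    set.seed(s)
    odor <- replicate(4, length(sim_spike_times(10, 0, 0.5)))
    ctrl <- replicate(4, length(sim_spike_times(10, 0, 0.5)))
    response_magnitude(odor, ctrl)$mean_response
  }, numeric(1L))
  expect_lt(abs(mean(diffs)), 0.5)
})

test_that("noise-free, spike-free trials are flat at baseline", {
  es <- ephys_sim_spec(noise_sd = 0, odor_rate_hz = 0, control_rate_hz = 0,
                       epsp_amplitude = 0, onset = 0.3, post_s = 0.2,
                       seed = 1L)
  sim <- simulate_trialset(es)
  expect_equal(sim$trialset$trials[[1]]$voltage,
               rep(-55, length(sim$trialset$trials[[1]]$voltage)))
})

test_that("stimulation pairs carry the artifact and EPSP as specified", {
  # amplitude 0: no latency detectable
  sp0 <- simulate_stimulation_pair(epsp_amplitude = 0, seed = 11L)
  expect_true(is.na(stimulation_latency(sp0$pair)))
  # gain 1 mV/V at 3 V: control window mean ~3 mV above baseline
  v <- sp0$pair$control_trials[[1]]
  expect_equal(evoked_depolarization(v, 0.6, 0.5), 3, tolerance = 0.1)
  # latency 2 ms at high SNR: estimator lands within one bin
  sp <- simulate_stimulation_pair(onset_latency_ms = 2,
                                  epsp_amplitude = 15, noise_sd = 0.5,
                                  seed = 12L)
  expect_lte(abs(as.numeric(stimulation_latency(sp$pair)) - 2), 0.5)
})
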