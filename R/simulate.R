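#' Specification of a synthetic skeleton population
#'
#' Describes groups of branching neurons whose dendritic point clouds sit at
#' group-specific locations (emulating sex-specific dendritic placement),
#' while axons can target a shared region.
#'
#' @param n_per_group neurons per group (>= 1).
#' @param groups list of groups, each a list with `label`,
#'   `dendrite_centroid` (um triplet) and `axon_target_centroid` (um
#'   triplet).
#' @param branch_count integer range (length-2) of dendritic branches per
#'   neuron.
#' @param branch_segments nodes per dendritic branch.
#' @param segment_length um between successive nodes.
#' @param jitter_sd isotropic Gaussian positional jitter in um (>= 0).
#' @param seed integer seed; the generator is a pure function of
#'   spec + seed.
#' @return object of class `morpho_population_spec`.
#' @export
morpho_population_spec <- function(n_per_group = 10L,
                                   groups = list(
                                     list(label = "A",
                                          dendrite_centroid = c(0, 0, 0),
                                          axon_target_centroid = c(0, 80, 0)),
                                     list(label = "B",
                                          dendrite_centroid = c(30, 0, 0),
                                          axon_target_centroid = c(0, 80, 0))),
                                   branch_count = c(4L, 7L),
                                   branch_segments = 10L,
                                   segment_length = 2,
                                   jitter_sd = 2, seed = 1L) {
  stopifnot(n_per_group >= 1L, jitter_sd >= 0, segment_length > 0,
            length(branch_count) == 2L, branch_count[1L] >= 1L,
            branch_count[2L] >= branch_count[1L])
  for (g in groups) {
    stopifnot(all(is.finite(g$dendrite_centroid)),
              all(is.finite(g$axon_target_centroid)),
              length(g$dendrite_centroid) == 3L,
              length(g$axon_target_centroid) == 3L)
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 branch_count = as.integer(branch_count),
                 branch_segments = as.integer(branch_segments),
                 segment_length = segment_length, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "morpho_population_spec")
}

# deterministic spread of unit directions (golden-angle spiral on a sphere)
spread_directions <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# chain of nodes from 'from' towards 'to' in steps of <= seg um (excluding
# the start point, including the end point)
chain_points <- function(from, to, seg) {
  len <- sqrt(sum((to - from)^2))
  n <- max(1L, ceiling(len / seg))
  frac <- seq_len(n) / n
  sweep(outer(frac, to - from), 2L, from, "+")
}

#' Simulate a population of branching skeletons with group structure
#'
#' Each neuron is a rooted tree: a soma midway between the group's dendrite
#' and axon centroids, an axonal chain toward the axon target, a trunk to
#' the dendrite centroid, and a set of dendritic branches radiating from it
#' along deterministically spread directions, so the dendritic node cloud is
#' centred on the group's `dendrite_centroid`. Every non-soma node gets
#' isotropic Gaussian jitter of sd `jitter_sd`. The branch count is drawn
#' uniformly from `branch_count`. Deterministic given `spec$seed`.
#'
#' @param spec a [morpho_population_spec()].
#' @return list with `skeletons` (named list of [neuron_skeleton()]) and
#'   `labels` (named character vector of true group labels).
#' @export
simulate_skeleton_population <- function(spec) {
  stopifnot(inherits(spec, "morpho_population_spec"))
  set.seed(spec$seed)
  skeletons <- list()
  labels <- character(0)
  for (g in spec$groups) {
    for (i in seq_len(spec$n_per_group)) {
      dc <- as.numeric(g$dendrite_centroid)
      ac <- as.numeric(g$axon_target_centroid)
      soma <- (dc + ac) / 2
      b <- if (spec$branch_count[1L] == spec$branch_count[2L])
        spec$branch_count[1L]
      else sample(spec$branch_count[1L]:spec$branch_count[2L], 1L)
      dirs <- spread_directions(b)
      trunk <- chain_points(soma, dc, spec$segment_length)
      axon <- chain_points(soma, ac, spec$segment_length)
      # offset each branch so its node cloud straddles the centroid
      half_len <- spec$branch_segments * spec$segment_length / 2
      branches <- lapply(seq_len(b), function(j) {
        t(dc + outer(dirs[j, ],
                     seq_len(spec$branch_segments) * spec$segment_length -
                       half_len))
      })
      pts <- rbind(soma, trunk, axon, do.call(rbind, branches))
      # parents: soma=1; chains link sequentially, branches root at the
      # trunk's last node (the dendrite centroid)
      n_trunk <- nrow(trunk); n_axon <- nrow(axon)
      trunk_ids <- 1L + seq_len(n_trunk)
      axon_ids <- 1L + n_trunk + seq_len(n_axon)
      parent <- c(NA_integer_,
                  c(1L, trunk_ids[-n_trunk]),
                  c(1L, axon_ids[-n_axon]))
      centroid_id <- trunk_ids[n_trunk]
      nxt <- 1L + n_trunk + n_axon
      for (j in seq_len(b)) {
        ids <- nxt + seq_len(spec$branch_segments)
        parent <- c(parent, c(centroid_id, ids[-length(ids)]))
        nxt <- nxt + spec$branch_segments
      }
      if (spec$jitter_sd > 0) {
        jit <- matrix(stats::rnorm(3L * (nrow(pts) - 1L),
                                   sd = spec$jitter_sd), ncol = 3L)
        pts[-1L, ] <- pts[-1L, ] + jit
      }
      lab <- sprintf("%s_%02d", g$label, i)
      skeletons[[lab]] <- neuron_skeleton(
        data.frame(node_id = seq_len(nrow(pts)), parent_id = parent,
                   x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]),
        label = lab, space_tag = "synthetic_template")
      labels[lab] <- g$label
    }
  }
  list(skeletons = skeletons, labels = labels)
}

#' Specification of a synthetic recording session
#'
#' Statistical structure of the simulated current-clamp trials: Gaussian
#' baseline noise, odor-locked EPSP-like depolarizations, stereotyped spike
#' waveforms at inhomogeneous-Poisson times, 500 ms stimulus pulses and
#' 150-200 ms odor-arrival latencies at an 11.1 kHz sampling rate.
#'
#' @param sampling_rate Hz (default 11100).
#' @param baseline resting potential in mV (default -55).
#' @param noise_sd Gaussian noise sd in mV (default 0.5).
#' @param spike_amplitude spike height in mV (default 40).
#' @param spike_width_ms spike width in ms (default 2).
#' @param epsp_amplitude odor-evoked depolarization in mV (default 8).
#' @param epsp_latency_range odor-arrival latency range in s (default
#'   `c(0.150, 0.200)`, uniform per trial).
#' @param tau_rise,tau_decay EPSP difference-of-exponentials time constants
#'   in s (defaults 0.005 and 0.040).
#' @param odor_rate_hz spike rate inside the odor response window for a
#'   responsive odor (default 40).
#' @param control_rate_hz spontaneous spike rate (default 2).
#' @param refractory_ms absolute refractory period in ms: drawn spike times
#'   closer than this to the previous kept spike are dropped. Default 0
#'   (pure Poisson spiking, so window counts are exactly Poisson); set to
#'   ~3 ms for biologically spaced trains when benchmarking the detector,
#'   whose event grouping cannot separate spikes closer than 2 ms by
#'   design.
#' @param n_trials trials per stimulus (default 4, the standard design).
#' @param onset stimulus onset in s (default 5.0: enough pre-stimulus
#'   baseline for two tiled pseudo-response null blocks).
#' @param stimulus_duration odor pulse length in s (default 0.5).
#' @param post_s trace length after stimulus offset (default 1.0).
#' @param seed integer seed.
#' @return object of class `ephys_sim_spec`.
#' @export
ephys_sim_spec <- function(sampling_rate = 11100, baseline = -55,
                           noise_sd = 0.5, spike_amplitude = 40,
                           spike_width_ms = 2, epsp_amplitude = 8,
                           epsp_latency_range = c(0.150, 0.200),
                           tau_rise = 0.005, tau_decay = 0.040,
                           odor_rate_hz = 40, control_rate_hz = 2,
                           refractory_ms = 0,
                           n_trials = 4L, onset = 5.0,
                           stimulus_duration = 0.5, post_s = 1.0,
                           seed = 1L) {
  stopifnot(sampling_rate > 0, noise_sd >= 0, odor_rate_hz >= 0,
            control_rate_hz >= 0, n_trials >= 1L, onset >= 0,
            epsp_latency_range[1L] <= epsp_latency_range[2L])
  structure(list(sampling_rate = sampling_rate, baseline = baseline,
                 noise_sd = noise_sd, spike_amplitude = spike_amplitude,
                 spike_width_ms = spike_width_ms,
                 epsp_amplitude = epsp_amplitude,
                 epsp_latency_range = epsp_latency_range,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 odor_rate_hz = odor_rate_hz,
                 control_rate_hz = control_rate_hz,
                 refractory_ms = refractory_ms,
                 n_trials = as.integer(n_trials), onset = onset,
                 stimulus_duration = stimulus_duration, post_s = post_s,
                 seed = as.integer(seed)),
            class = "ephys_sim_spec")
}

#' Draw homogeneous-Poisson spike times on an interval
#'
#' The elementary building block of the recording generator: the number of
#' spikes is Poisson(`rate_hz * (t1 - t0)`) and times are uniform on
#' `[t0, t1)`. Uses the current RNG state (seed it from the enclosing
#' simulation).
#'
#' @param rate_hz rate in Hz (>= 0).
#' @param t0,t1 interval bounds in s.
#' @return sorted numeric vector of spike times.
#' @export
sim_spike_times <- function(rate_hz, t0, t1) {
  stopifnot(rate_hz >= 0, t1 >= t0)
  n <- stats::rpois(1L, rate_hz * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# drop spikes closer than `gap` s to the previously kept spike
thin_refractory <- function(times, gap) {
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= gap) { keep <- c(keep, t); last <- t }
  }
  keep
}

# difference-of-exponentials kernel, peak-normalized to `amp`
epsp_wave <- function(t, amp, tau_rise, tau_decay) {
  w <- exp(-t / tau_decay) - exp(-t / tau_rise)
  w[t < 0] <- 0
  t_peak <- log(tau_decay / tau_rise) /
    (1 / tau_rise - 1 / tau_decay)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  amp * w / peak
}

# symmetric triangular spike transient added at time t_spike
add_spikes <- function(voltage, t_spike, amp, width_s, fs) {
  half <- max(1L, round(width_s * fs / 2))
  shape <- amp * (1 - abs(seq.int(-half, half)) / half)
  n <- length(voltage)
  for (ts in t_spike) {
    centre <- round(ts * fs) + 1L
    idx <- centre + seq.int(-half, half)
    ok <- idx >= 1L & idx <= n
    voltage[idx[ok]] <- voltage[idx[ok]] + shape[ok]
  }
  voltage
}

#' Simulate a trial set of odor-stimulation recordings
#'
#' For each odor in `odors` plus the control condition, `spec$n_trials`
#' voltage trials are generated: baseline + Gaussian noise, with spikes from
#' an inhomogeneous Poisson process (`control_rate_hz` everywhere,
#' `odor_rate_hz` inside the odor-locked window for responsive odors) and an
#' EPSP-like depolarization starting one odor-arrival latency after valve
#' opening for responsive odors. Deterministic given `spec$seed`.
#'
#' @param spec an [ephys_sim_spec()].
#' @param odors odor labels to simulate (default `"cVA"`).
#' @param responsive subset of `odors` that evoke a response (default: all
#'   of them).
#' @param control_label label of the mineral-oil control condition.
#' @param cell_id cell label stamped on every trial.
#' @return list with `trialset` (a [trial_set()]) and `truth`: a data.frame
#'   of per-trial ground truth (stimulus, responsive flag, EPSP amplitude
#'   and latency) with true spike times in the list-column `spikes`.
#' @export
simulate_trialset <- function(spec, odors = "cVA", responsive = odors,
                              control_label = "mineral_oil",
                              cell_id = "cell1") {
  stopifnot(inherits(spec, "ephys_sim_spec"))
  set.seed(spec$seed)
  fs <- spec$sampling_rate
  total_s <- spec$onset + spec$stimulus_duration + spec$post_s
  n_samp <- round(total_s * fs)
  stims <- c(odors, control_label)
  trials <- list()
  truth <- list()
  for (stim in stims) {
    is_resp <- stim %in% responsive && stim != control_label
    for (tr in seq_len(spec$n_trials)) {
      lat <- stats::runif(1L, spec$epsp_latency_range[1L],
                          spec$epsp_latency_range[2L])
      t_on <- spec$onset + lat
      t_off <- t_on + spec$stimulus_duration
      v <- spec$baseline +
        stats::rnorm(n_samp, sd = spec$noise_sd)
      if (is_resp) {
        spk <- c(sim_spike_times(spec$control_rate_hz, 0, t_on),
                 sim_spike_times(spec$odor_rate_hz, t_on, t_off),
                 sim_spike_times(spec$control_rate_hz, t_off, total_s))
        tt <- seq_len(n_samp) / fs - t_on
        v <- v + epsp_wave(tt, spec$epsp_amplitude, spec$tau_rise,
                           spec$tau_decay)
      } else {
        spk <- sim_spike_times(spec$control_rate_hz, 0, total_s)
      }
      if (spec$refractory_ms > 0) spk <- thin_refractory(
        spk, spec$refractory_ms / 1000)
      v <- add_spikes(v, spk, spec$spike_amplitude,
                      spec$spike_width_ms / 1000, fs)
      trials[[length(trials) + 1L]] <-
        voltage_trial(v, fs, spec$onset, spec$stimulus_duration,
                      stimulus_label = stim, cell_id = cell_id)
      row <- data.frame(cell_id = cell_id, stimulus_label = stim,
                        trial = tr, responsive = is_resp,
                        epsp_amplitude = if (is_resp) spec$epsp_amplitude
                                         else 0,
                        latency_s = if (is_resp) lat else NA_real_)
      row$spikes <- list(spk)
      truth[[length(truth) + 1L]] <- row
    }
  }
  list(trialset = trial_set(trials, control_label = control_label),
       truth = do.call(rbind, truth))
}

#' Simulate a glomerular-stimulation trial pair
#'
#' Test trials carry the sustained stimulation artifact (a
#' `artifact_gain * stim_voltage` step over the pulse) plus an EPSP delayed
#' by `onset_latency_ms`; control trials carry the artifact step only. The
#' stimulation-evoked EPSP is a saturating rise to a sustained plateau
#' (exponential rise, plateau through the pulse, exponential decay after),
#' matching the sustained depolarizations these experiments evoke, so that
#' the response persists through the whole stimulation period.
#' Deterministic given `seed`.
#'
#' @param onset_latency_ms true synaptic latency in ms (> 0).
#' @param epsp_amplitude plateau amplitude in mV.
#' @param artifact_gain sustained artifact gain in mV/V (default 1).
#' @param stim_voltage stimulation voltage in V (default 3).
#' @param n_trials trials per condition (default 6).
#' @param noise_sd Gaussian noise sd in mV (default 0.5).
#' @param sampling_rate Hz (default 11100).
#' @param baseline resting potential in mV (default -55).
#' @param stim_onset pulse onset in s (default 0.6).
#' @param stim_duration pulse length in s (default 0.5).
#' @param post_s trace length after pulse offset (default 0.2).
#' @param tau_rise_ms EPSP rise time constant in ms (default 1).
#' @param tau_decay_ms post-pulse decay time constant in ms (default 40).
#' @param seed integer seed.
#' @return list with `pair` (a [stim_pair()]) and `truth` (latency, plateau
#'   amplitude, artifact gain).
#' @export
simulate_stimulation_pair <- function(onset_latency_ms = 2,
                                      epsp_amplitude = 10,
                                      artifact_gain = 1, stim_voltage = 3,
                                      n_trials = 6L, noise_sd = 0.5,
                                      sampling_rate = 11100,
                                      baseline = -55, stim_onset = 0.6,
                                      stim_duration = 0.5, post_s = 0.2,
                                      tau_rise_ms = 1, tau_decay_ms = 40,
                                      seed = 1L) {
  stopifnot(onset_latency_ms > 0, n_trials >= 1L)
  set.seed(seed)
  fs <- sampling_rate
  total_s <- stim_onset + stim_duration + post_s
  n_samp <- round(total_s * fs)
  tt <- seq_len(n_samp) / fs
  stim_win <- tt >= stim_onset & tt < stim_onset + stim_duration
  t_on <- stim_onset + onset_latency_ms / 1000
  t_end <- stim_onset + stim_duration
  rise <- 1 - exp(-pmax(0, tt - t_on) / (tau_rise_ms / 1000))
  plateau_at_end <- 1 - exp(-(t_end - t_on) / (tau_rise_ms / 1000))
  epsp <- ifelse(tt < t_end, rise,
                 plateau_at_end * exp(-(tt - t_end) / (tau_decay_ms / 1000)))
  epsp[tt < t_on] <- 0
  make_trial <- function(with_epsp, lab) {
    v <- baseline + stats::rnorm(n_samp, sd = noise_sd) +
      artifact_gain * stim_voltage * stim_win
    if (with_epsp) v <- v + epsp_amplitude * epsp
    voltage_trial(v, fs, stim_onset, stim_duration,
                  stimulus_label = lab, cell_id = "stim_cell")
  }
  test <- lapply(seq_len(n_trials), function(i) make_trial(TRUE, "DA1"))
  ctrl <- lapply(seq_len(n_trials), function(i) make_trial(FALSE,
                                                           "control_glom"))
  list(pair = stim_pair(test, ctrl, stim_onset, stim_duration,
                        stim_voltage),
       truth = list(latency_ms = onset_latency_ms,
                    epsp_amplitude = epsp_amplitude,
                    artifact_gain = artifact_gain))
}
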