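#' Construct a stimulation trial pair
#'
#' Trials from a single-glomerulus stimulation experiment: `test_trials`
#' from stimulation of the target (DA1) glomerulus and `control_trials`
#' from a neighbouring control glomerulus, with shared onset and duration.
#'
#' @param test_trials,control_trials lists of [voltage_trial()] sharing a
#'   sampling rate.
#' @param stim_onset stimulation onset in s.
#' @param stim_duration pulse length in s (default 0.5, the standard square
#'   pulse).
#' @param stim_voltage stimulation voltage(s) in V, recycled across trials.
#' @return object of class `stim_pair`.
#' @export
stim_pair <- function(test_trials, control_trials, stim_onset,
                      stim_duration = 0.5, stim_voltage = 1) {
  if (length(test_trials) == 0L || length(control_trials) == 0L)
    stop("both test and control trials are required")
  all_tr <- c(test_trials, control_trials)
  stopifnot(all(vapply(all_tr, inherits, logical(1L), "voltage_trial")))
  rates <- vapply(all_tr, `[[`, numeric(1L), "sampling_rate")
  if (diff(range(rates)) / rates[1L] > 0.001)
    stop("test and control trials must share a sampling rate")
  structure(list(test_trials = test_trials,
                 control_trials = control_trials,
                 stim_onset = stim_onset, stim_duration = stim_duration,
                 stim_voltage = stim_voltage),
            class = "stim_pair")
}

#' @export
print.stim_pair <- function(x, ...) {
  cat(sprintf(
    "<stim_pair> %d test / %d control trials, %.0f ms pulse at %.2f s\n",
    length(x$test_trials), length(x$control_trials),
    1000 * x$stim_duration, x$stim_onset))
  invisible(x)
}

#' Fit the sustained stimulation-artifact gain for a cell
#'
#' The sustained artifact is modelled as a constant offset proportional to
#' the stimulation voltage (typically around 1 mV/V). The gain is estimated
#' from control-glomerulus trials as the mean of
#' (late-plateau mean - pre-onset baseline mean) / stim_voltage, with the
#' plateau taken over the last 100 ms of the stimulation window.
#'
#' @param control_trials list of [voltage_trial()] from control
#'   stimulation.
#' @param stim_onset,stim_duration stimulation window in s.
#' @param stim_voltage per-trial stimulation voltages in V (recycled).
#' @param plateau_s plateau length at the end of the window (default 0.1).
#' @param baseline_s pre-onset baseline length (default 0.5).
#' @return gain in mV per V.
#' @export
fit_artifact_gain <- function(control_trials, stim_onset, stim_duration,
                              stim_voltage, plateau_s = 0.1,
                              baseline_s = 0.5) {
  volts <- rep_len(stim_voltage, length(control_trials))
  gains <- vapply(seq_along(control_trials), function(i) {
    v <- control_trials[[i]]
    plateau <- mean(v$voltage[window_idx(
      v, stim_onset + stim_duration - plateau_s, stim_onset + stim_duration)])
    base <- mean(v$voltage[window_idx(v, stim_onset - baseline_s,
                                      stim_onset)])
    (plateau - base) / volts[i]
  }, numeric(1L))
  mean(gains)
}

#' Subtract the sustained stimulation artifact from a trial
#'
#' Subtracts `gain * stim_voltage` from all samples inside the stimulation
#' window. The transient edge artifacts are not modelled: samples within
#' `edge_mask_s` of the window edges are flagged in the returned trial's
#' `"artifact_mask"` attribute (a logical vector, TRUE = masked) so
#' downstream summaries can exclude them.
#'
#' @param v a [voltage_trial()].
#' @param stim_onset,stim_duration stimulation window in s.
#' @param stim_voltage stimulation voltage in V.
#' @param gain artifact gain in mV/V, from [fit_artifact_gain()].
#' @param edge_mask_s half-width of the edge mask in s (default 0.002).
#' @return the corrected [voltage_trial()].
#' @export
subtract_sustained_artifact <- function(v, stim_onset, stim_duration,
                                        stim_voltage, gain,
                                        edge_mask_s = 0.002) {
  stopifnot(inherits(v, "voltage_trial"))
  win <- window_idx(v, stim_onset, stim_onset + stim_duration)
  out <- v
  out$voltage[win] <- out$voltage[win] - gain * stim_voltage
  mask <- rep(FALSE, length(v$voltage))
  tt <- (seq_along(v$voltage) - 1L) / v$sampling_rate
  for (edge in c(stim_onset, stim_onset + stim_duration))
    mask <- mask | (abs(tt - edge) < edge_mask_s)
  attr(out, "artifact_mask") <- mask
  out
}

#' Evoked depolarization during the stimulation window
#'
#' Mean voltage over the stimulation window minus the mean over the 500 ms
#' preceding onset, on an artifact-subtracted trial. Samples flagged by the
#' artifact edge mask are excluded from the window mean.
#'
#' @param v a [voltage_trial()] (artifact-subtracted).
#' @param stim_onset,stim_duration stimulation window in s.
#' @param baseline_s pre-onset baseline length (default 0.5).
#' @return depolarization in mV.
#' @export
evoked_depolarization <- function(v, stim_onset, stim_duration,
                                  baseline_s = 0.5) {
  stopifnot(inherits(v, "voltage_trial"))
  win <- window_idx(v, stim_onset, stim_onset + stim_duration)
  base <- window_idx(v, stim_onset - baseline_s, stim_onset)
  mask <- attr(v, "artifact_mask")
  if (!is.null(mask)) win <- win[!mask[win]]
  mean(v$voltage[win]) - mean(v$voltage[base])
}

#' Synaptic latency of a stimulation-evoked response
#'
#' All traces are boxcar-filtered at a 2.2 kHz equivalent cutoff and each
#' trace is normalized by subtracting its own mean over the first 0.5 ms
#' after stimulation onset. The post-onset period is binned at 0.5 ms;
#' within each bin, the per-trial bin means for test (DA1) versus control
#' stimulation are compared with a one-tailed Wilcoxon rank-sum test
#' (exact for small samples). The latency is the start time of the earliest
#' bin from which *every* subsequent bin through the end of the stimulation
#' period stays significant at `alpha`; `NA` if no bin qualifies.
#'
#' @param pair a [stim_pair()].
#' @param alpha per-bin significance level (default 0.05, strict `<`).
#' @param bin_s bin width in s (default 5e-4).
#' @param boxcar_hz boxcar cutoff in Hz (default 2200).
#' @param summary per-trial bin summary, `"mean"` (default) or `"median"`
#'   (robust to spike contamination).
#' @return latency in ms after stimulation onset, or `NA_real_`. The
#'   per-bin p-values are attached as attribute `bin_p`.
#' @export
stimulation_latency <- function(pair, alpha = 0.05, bin_s = 5e-4,
                                boxcar_hz = 2200,
                                summary = c("mean", "median")) {
  stopifnot(inherits(pair, "stim_pair"))
  summary <- match.arg(summary)
  n_t <- length(pair$test_trials); n_c <- length(pair$control_trials)
  if (n_t < 3L || n_c < 3L)
    stop("latency estimation needs >= 3 trials per condition")
  sum_fun <- if (summary == "mean") mean else stats::median
  bin_means <- function(v) {
    sm <- boxcar_smooth(v, cutoff_hz = boxcar_hz)$voltage
    norm_win <- window_idx(v, pair$stim_onset, pair$stim_onset + 5e-4)
    sm <- sm - mean(sm[norm_win])
    idx <- window_idx(v, pair$stim_onset,
                      pair$stim_onset + pair$stim_duration)
    tt <- (idx - 1L) / v$sampling_rate - pair$stim_onset
    n_bins <- floor(pair$stim_duration / bin_s)
    bins <- floor(tt / bin_s)
    keep <- bins >= 0 & bins < n_bins
    f <- factor(bins[keep], levels = seq_len(n_bins) - 1L)
    vapply(split(sm[idx][keep], f), sum_fun, numeric(1L))
  }
  tm <- vapply(pair$test_trials, bin_means,
               numeric(floor(pair$stim_duration / bin_s)))
  cm <- vapply(pair$control_trials, bin_means,
               numeric(floor(pair$stim_duration / bin_s)))
  n_bins <- nrow(tm)
  p <- vapply(seq_len(n_bins), function(b) {
    suppressWarnings(
      stats::wilcox.test(tm[b, ], cm[b, ],
                         alternative = "greater")$p.value)
  }, numeric(1L))
  sig <- p < alpha
  # earliest bin from which significance persists to the end
  persists <- rev(cumprod(rev(sig))) > 0
  first <- which(persists)[1L]
  latency <- if (is.na(first)) NA_real_ else (first - 1L) * bin_s * 1000
  attr(latency, "bin_p") <- p
  latency
}
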