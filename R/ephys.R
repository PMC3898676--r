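#' Construct a voltage trial
#'
#' One current-clamp trace from one stimulus presentation, with its stimulus
#' metadata. Voltages are in mV, times in seconds from the start of the
#' trace.
#'
#' @param voltage numeric vector of mV samples.
#' @param sampling_rate Hz (> 0); recordings here are digitized at 11.1 kHz.
#' @param stimulus_onset valve-opening / stimulation onset in s, within the
#'   trace.
#' @param stimulus_duration stimulus length in s (odor pulses are 0.5 s).
#' @param stimulus_label odor or stimulation-target code.
#' @param cell_id cell label.
#' @return object of class `voltage_trial`.
#' @export
voltage_trial <- function(voltage, sampling_rate, stimulus_onset,
                          stimulus_duration = 0.5, stimulus_label = "",
                          cell_id = "") {
  voltage <- as.numeric(voltage)
  if (!all(is.finite(voltage))) stop("voltage must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  dur <- length(voltage) / sampling_rate
  if (stimulus_onset < 0 || stimulus_onset > dur)
    stop("stimulus_onset ", stimulus_onset,
         " s is outside the trace (duration ", signif(dur, 4), " s)")
  structure(list(voltage = voltage, sampling_rate = sampling_rate,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 stimulus_label = as.character(stimulus_label),
                 cell_id = as.character(cell_id)),
            class = "voltage_trial")
}

#' @export
print.voltage_trial <- function(x, ...) {
  cat(sprintf(
    "<voltage_trial> cell '%s' stim '%s': %.2f s at %g Hz, onset %.2f s\n",
    x$cell_id, x$stimulus_label, length(x$voltage) / x$sampling_rate,
    x$sampling_rate, x$stimulus_onset))
  invisible(x)
}

trial_duration <- function(v) length(v$voltage) / v$sampling_rate

# sample indices covering [t0, t1) in trace time (1-based, clipped)
window_idx <- function(v, t0, t1) {
  i0 <- floor(t0 * v$sampling_rate) + 1L
  i1 <- ceiling(t1 * v$sampling_rate)
  if (i0 < 1L || i1 > length(v$voltage))
    stop(sprintf("window [%.3f, %.3f] s outside trace of %.3f s",
                 t0, t1, trial_duration(v)))
  seq.int(i0, i1)
}

#' Construct a trial set
#'
#' A cell's (or several cells') repeated voltage trials grouped by stimulus,
#' plus the label of the control (mineral-oil) condition used for response
#' testing.
#'
#' @param trials list of [voltage_trial()] objects sharing a sampling rate
#'   (within 0.1 percent).
#' @param control_label stimulus code of the control condition, or `NA` when
#'   no response testing will be requested.
#' @return object of class `trial_set`.
#' @export
trial_set <- function(trials, control_label = NA_character_) {
  if (length(trials) < 1L) stop("trial_set needs at least one trial")
  stopifnot(all(vapply(trials, inherits, logical(1L), "voltage_trial")))
  rates <- vapply(trials, `[[`, numeric(1L), "sampling_rate")
  if (diff(range(rates)) / rates[1L] > 0.001)
    stop("trials must share a sampling rate within 0.1%")
  structure(list(trials = trials,
                 control_label = as.character(control_label)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  labs <- vapply(x$trials, `[[`, character(1L), "stimulus_label")
  cat(sprintf("<trial_set> %d trials, %d stimuli (control: '%s')\n",
              length(x$trials), length(unique(labs)), x$control_label))
  invisible(x)
}

#' Subset a trial set
#' @param ts a [trial_set()].
#' @param cell_id,stimulus_label optional filters.
#' @return a [trial_set()] with the matching trials.
#' @export
subset_trials <- function(ts, cell_id = NULL, stimulus_label = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  keep <- rep(TRUE, length(ts$trials))
  if (!is.null(cell_id))
    keep <- keep & vapply(ts$trials, `[[`, character(1L), "cell_id") %in%
      cell_id
  if (!is.null(stimulus_label))
    keep <- keep & vapply(ts$trials, `[[`, character(1L),
                          "stimulus_label") %in% stimulus_label
  if (!any(keep)) stop("no trials match the filter")
  trial_set(ts$trials[keep], control_label = ts$control_label)
}

#' Write a trial set to a directory of CSV traces
#'
#' One CSV per trial (single `voltage_mv` column) plus a `trials.csv`
#' sidecar with columns `trace_file, cell_id, stimulus_label, onset_s,
#' duration_s, rate_hz, control_label`. Inverse of [read_trials()].
#'
#' @param ts a [trial_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(ts, dir) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trial%04d.csv", seq_along(ts$trials))
  for (i in seq_along(ts$trials))
    utils::write.csv(data.frame(voltage_mv = ts$trials[[i]]$voltage),
                     file.path(dir, files[i]), row.names = FALSE)
  side <- data.frame(
    trace_file = files,
    cell_id = vapply(ts$trials, `[[`, character(1L), "cell_id"),
    stimulus_label = vapply(ts$trials, `[[`, character(1L),
                            "stimulus_label"),
    onset_s = vapply(ts$trials, `[[`, numeric(1L), "stimulus_onset"),
    duration_s = vapply(ts$trials, `[[`, numeric(1L), "stimulus_duration"),
    rate_hz = vapply(ts$trials, `[[`, numeric(1L), "sampling_rate"),
    control_label = ts$control_label)
  utils::write.csv(side, file.path(dir, "trials.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a trial set from a directory of CSV traces
#'
#' Expects the layout written by [write_trials()]: per-trial voltage CSVs
#' and a `trials.csv` sidecar naming each trace's cell, stimulus, onset,
#' duration and sampling rate.
#'
#' @param dir directory containing `trials.csv`.
#' @return a [trial_set()].
#' @export
read_trials <- function(dir) {
  side_path <- file.path(dir, "trials.csv")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- utils::read.csv(side_path, stringsAsFactors = FALSE)
  need <- c("trace_file", "cell_id", "stimulus_label", "onset_s",
            "duration_s", "rate_hz")
  missing_cols <- setdiff(need, names(side))
  if (length(missing_cols) > 0L)
    stop("trials.csv is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  trials <- lapply(seq_len(nrow(side)), function(i) {
    tr <- utils::read.csv(file.path(dir, side$trace_file[i]))
    voltage_trial(tr$voltage_mv, sampling_rate = side$rate_hz[i],
                  stimulus_onset = side$onset_s[i],
                  stimulus_duration = side$duration_s[i],
                  stimulus_label = side$stimulus_label[i],
                  cell_id = side$cell_id[i])
  })
  ctrl <- if ("control_label" %in% names(side)) side$control_label[1L]
          else NA_character_
  trial_set(trials, control_label = ctrl)
}

#' Binomial smoothing kernel for a given cutoff
#'
#' Normalized Pascal-row coefficients `choose(m, 0:m) / 2^m`. A kernel of
#' `m + 1` taps has magnitude response `cos(pi f / fs)^m`, so its -3 dB
#' frequency is `fs/pi * acos(2^(-1/(2 m)))`. The kernel returned is the
#' shortest odd-length one whose -3 dB frequency is at or below `cutoff`.
#'
#' @param cutoff -3 dB target in Hz (0 < cutoff < Nyquist).
#' @param sampling_rate Hz.
#' @return numeric kernel summing to 1, with attribute `f3db` (its actual
#'   -3 dB frequency in Hz).
#' @export
binomial_kernel <- function(cutoff, sampling_rate) {
  if (cutoff <= 0 || cutoff >= sampling_rate / 2)
    stop("cutoff must lie in (0, Nyquist)")
  f3db <- function(m) sampling_rate / pi * acos(2^(-1 / (2 * m)))
  m <- 2L
  while (f3db(m) > cutoff) m <- m + 2L   # odd length => even order m
  k <- choose(m, 0:m) / 2^m
  attr(k, "f3db") <- f3db(m)
  k
}

# length-preserving convolution with reflected edges
reflect_convolve <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  n <- length(x)
  if (n <= half + 1L)
    stop("trace too short (", n, " samples) for a ", length(kernel),
         "-tap kernel")
  pad <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  out <- stats::filter(pad, kernel, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Smooth a voltage trial with a binomial kernel
#'
#' Convolution with the normalized Pascal-row kernel from
#' [binomial_kernel()]; edges are handled by reflection so the output length
#' is unchanged. The kernel sums to 1, so DC level is preserved and the
#' trace's range can never grow.
#'
#' @param v a [voltage_trial()].
#' @param cutoff -3 dB frequency in Hz. Spike extraction here uses
#'   180-550 Hz depending on the cell; the default is 400 Hz.
#' @return a smoothed [voltage_trial()].
#' @export
binomial_smooth <- function(v, cutoff = 400) {
  stopifnot(inherits(v, "voltage_trial"))
  k <- binomial_kernel(cutoff, v$sampling_rate)
  out <- v
  out$voltage <- reflect_convolve(v$voltage, k)
  out
}

#' Construct a spike train
#' @param times strictly increasing spike times in s.
#' @param trial_ref optional link back to the source [voltage_trial()].
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, trial_ref = NULL) {
  times <- as.numeric(times)
  if (length(times) > 0L) {
    if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))
      stop("spike times must be finite and strictly increasing")
    if (!is.null(trial_ref) &&
        (times[1L] < 0 || times[length(times)] > trial_duration(trial_ref)))
      stop("spike times must lie within the trace")
  }
  structure(list(times = times, trial_ref = trial_ref),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes\n", length(x$times)))
  invisible(x)
}

#' Extract spike times from a current-clamp trace
#'
#' The trace is binomially smoothed, its second central difference taken,
#' and samples falling below a negative threshold are grouped into events;
#' events closer than the refractory gap are merged, and each event yields
#' one spike timed at the raw trace's voltage maximum within the event.
#'
#' In `auto` mode the threshold is `-c * MAD` of the second difference
#' (c = 8), which adapts to the trace's noise level; `fixed` mode applies
#' `threshold_value` (a negative number, in mV per sample^2) directly.
#'
#' @param v a [voltage_trial()].
#' @param smooth_cutoff binomial smoothing cutoff in Hz (180-550 Hz range in
#'   practice; default 400).
#' @param threshold_mode `"auto"` (default) or `"fixed"`.
#' @param threshold_value negative threshold for `fixed` mode.
#' @param mad_factor multiplier c for the auto threshold.
#' @param refractory_s minimum event separation in s (default 2 ms).
#' @return a [spike_train()].
#' @export
detect_spikes <- function(v, smooth_cutoff = 400,
                          threshold_mode = c("auto", "fixed"),
                          threshold_value = NULL, mad_factor = 8,
                          refractory_s = 0.002) {
  stopifnot(inherits(v, "voltage_trial"))
  threshold_mode <- match.arg(threshold_mode)
  if (length(v$voltage) <= 3L) stop("trace too short for spike detection")
  sm <- binomial_smooth(v, smooth_cutoff)$voltage
  n <- length(sm)
  d2 <- sm[3L:n] - 2 * sm[2L:(n - 1L)] + sm[1L:(n - 2L)]  # at samples 2..n-1
  thr <- if (threshold_mode == "fixed") {
    if (is.null(threshold_value))
      stop("fixed threshold mode requires threshold_value")
    if (threshold_value >= 0) stop("threshold_value must be negative")
    threshold_value
  } else {
    -mad_factor * stats::mad(d2)
  }
  below <- which(d2 < thr) + 1L          # indices into the original trace
  if (length(below) == 0L)
    return(spike_train(numeric(0), trial_ref = v))
  gap <- ceiling(refractory_s * v$sampling_rate)
  event_id <- cumsum(c(1L, diff(below) >= gap))
  times <- vapply(split(below, event_id), function(idx) {
    span <- seq.int(min(idx), max(idx))
    peak <- span[which.max(v$voltage[span])]
    (peak - 1L) / v$sampling_rate
  }, numeric(1L))
  spike_train(sort(unname(times)), trial_ref = v)
}

# odd-length moving average by cumulative sums, reflected edges; O(n)
boxcar_smooth_vec <- function(x, len) {
  len <- as.integer(len)
  if (len <= 1L) return(x)
  if (len %% 2L == 0L) len <- len + 1L
  half <- (len - 1L) %/% 2L
  n <- length(x)
  if (n <= half + 1L)
    stop("trace too short (", n, " samples) for a ", len, "-tap boxcar")
  pad <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  cs <- cumsum(c(0, pad))
  (cs[(len + 1L):(n + len)] - cs[1L:n]) / len
}

#' Boxcar-smooth a voltage trial
#'
#' Moving average with an odd kernel length chosen either directly
#' (`width_s`) or as the odd length whose -3 dB point is nearest
#' `cutoff_hz` (approximately `0.443 * fs / L`). Edges are reflected.
#'
#' @param v a [voltage_trial()].
#' @param width_s kernel width in seconds (e.g. 0.045 for the subthreshold
#'   analysis), or `NULL` to use `cutoff_hz`.
#' @param cutoff_hz -3 dB target in Hz (e.g. 2200 for latency estimation).
#' @return a smoothed [voltage_trial()].
#' @export
boxcar_smooth <- function(v, width_s = NULL, cutoff_hz = NULL) {
  stopifnot(inherits(v, "voltage_trial"))
  if (is.null(width_s) == is.null(cutoff_hz))
    stop("give exactly one of width_s or cutoff_hz")
  len <- if (!is.null(width_s)) round(width_s * v$sampling_rate)
         else round(0.443 * v$sampling_rate / cutoff_hz)
  len <- max(1L, as.integer(len))
  if (len %% 2L == 0L) len <- len + 1L
  out <- v
  out$voltage <- boxcar_smooth_vec(v$voltage, len)
  out
}
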