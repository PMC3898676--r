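#' Count spikes in a response window
#'
#' Number of spike times in the half-open window
#' `[onset + start_offset, onset + start_offset + length)`. The default
#' window — 500 ms starting 150 ms after valve opening — matches the typical
#' 150-200 ms odor-arrival latency of the delivery system.
#'
#' @param st a [spike_train()].
#' @param onset stimulus onset in s.
#' @param start_offset window start relative to onset (default 0.150 s).
#' @param length window length in s (default 0.500 s).
#' @return integer count.
#' @export
window_spike_count <- function(st, onset, start_offset = 0.150,
                               length = 0.500) {
  stopifnot(inherits(st, "spike_train"))
  if (length < 0) stop("window length must be nonnegative")
  t0 <- onset + start_offset
  sum(st$times >= t0 & st$times < t0 + length)
}

#' Odor response magnitude after control subtraction
#'
#' Mean spike count per window for the odor minus the mean for the control
#' (mineral oil) stimulus, plus the same difference expressed as a rate.
#'
#' @param odor_counts,control_counts per-trial window spike counts.
#' @param window_length window length in s used for the Hz conversion
#'   (default 0.5).
#' @return list with `mean_response` (spikes per window) and `rate_hz`.
#' @export
response_magnitude <- function(odor_counts, control_counts,
                               window_length = 0.5) {
  if (length(odor_counts) == 0L || length(control_counts) == 0L)
    stop("odor and control counts must be nonempty")
  d <- mean(odor_counts) - mean(control_counts)
  list(mean_response = d, rate_hz = d / window_length)
}

#' Exact one-sided Poisson test of odor versus control spike counts
#'
#' Conditional (binomial) form of the exact two-sample Poisson comparison:
#' with total odor count `K_o`, total control count `K_c` and
#' `N = K_o + K_c`, the one-sided p-value is `P(X >= K_o)` for
#' `X ~ Binomial(N, r / (1 + r))` where `r` is the exposure ratio (1 when
#' odor and control have equal numbers of trials, as with the standard four
#' trials per condition). `N = 0` returns p = 1.
#'
#' @param odor_counts,control_counts per-trial spike counts (nonnegative).
#' @param exposure_ratio ratio of odor to control exposure (trial count
#'   ratio); default 1.
#' @return one-sided p-value in (0, 1].
#' @export
poisson_response_test <- function(odor_counts, control_counts,
                                  exposure_ratio = 1) {
  if (any(odor_counts < 0) || any(control_counts < 0))
    stop("counts must be nonnegative")
  k_o <- sum(odor_counts)
  k_c <- sum(control_counts)
  n <- k_o + k_c
  if (n == 0) return(1)
  pr <- exposure_ratio / (1 + exposure_ratio)
  stats::pbinom(k_o - 1, size = n, prob = pr, lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()], `method = "BH"`),
#' returned in the original order.
#'
#' @param raw_p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(raw_p) {
  if (any(!is.finite(raw_p)) || any(raw_p < 0) || any(raw_p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(raw_p, method = "BH")
}

#' Peak firing rate over five post-onset windows
#'
#' Spike counts in five consecutive 200 ms windows starting 150 ms after
#' valve opening, converted to Hz; the maximum over the five windows is
#' returned.
#'
#' @param st a [spike_train()].
#' @param onset stimulus onset in s.
#' @param start_offset first window start relative to onset (default
#'   0.150 s).
#' @param window_length length of each window (default 0.200 s).
#' @param n_windows number of windows (default 5).
#' @return peak rate in Hz.
#' @export
peak_firing_rate <- function(st, onset, start_offset = 0.150,
                             window_length = 0.200, n_windows = 5L) {
  stopifnot(inherits(st, "spike_train"))
  if (!is.null(st$trial_ref)) {
    t_end <- onset + start_offset + n_windows * window_length
    if (t_end > trial_duration(st$trial_ref))
      stop("the five response windows extend past the end of the trace")
  }
  counts <- vapply(seq_len(n_windows) - 1L, function(w) {
    window_spike_count(st, onset, start_offset + w * window_length,
                       window_length)
  }, numeric(1L))
  max(counts) / window_length
}

#' Lifetime sparseness of an odor tuning curve
#'
#' Tuning-sharpness statistic
#' `S = (1 - (sum(r)/n)^2 / (sum(r^2)/n)) / (1 - 1/n)` over the per-odor
#' mean response rates `r`: 0 for a neuron responding equally to all
#' odorants, 1 for a neuron excited by exactly one. Negative (inhibitory)
#' mean responses are rectified to 0 before evaluation, since the statistic
#' is undefined for negative rates; an all-zero vector returns 0.
#'
#' @param responses per-odor mean response rates (>= 2 odorants).
#' @param rectify rectify negative responses to 0 first (default TRUE).
#' @return S in `[0, 1]`.
#' @export
lifetime_sparseness <- function(responses, rectify = TRUE) {
  n <- length(responses)
  if (n < 2L) stop("lifetime sparseness needs at least 2 odorants")
  r <- as.numeric(responses)
  if (rectify) r[r < 0] <- 0
  if (any(r < 0)) stop("responses must be nonnegative (or set rectify)")
  if (all(r == 0)) return(0)
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

#' Peak subthreshold depolarization to a stimulus
#'
#' The membrane potential is smoothed with a 45 ms boxcar; the response is
#' the smoothed maximum in a window 200-800 ms after valve opening minus
#' the mean over the second preceding onset. `offset` rigidly shifts both
#' windows (used to place pseudo-response windows in the pre-stimulus
#' period).
#'
#' @param v a [voltage_trial()].
#' @param boxcar boxcar width in s (default 0.045).
#' @param response_window response window relative to onset, s (default
#'   `c(0.2, 0.8)`).
#' @param baseline_window baseline window relative to onset, s (default
#'   `c(-1, 0)`).
#' @param offset rigid shift applied to both windows, s (default 0).
#' @param smoothed optional pre-smoothed voltage vector (to avoid
#'   re-filtering when evaluating many windows of one trace).
#' @return peak depolarization in mV.
#' @export
subthreshold_response <- function(v, boxcar = 0.045,
                                  response_window = c(0.2, 0.8),
                                  baseline_window = c(-1, 0), offset = 0,
                                  smoothed = NULL) {
  stopifnot(inherits(v, "voltage_trial"))
  if (is.null(smoothed))
    smoothed <- boxcar_smooth(v, width_s = boxcar)$voltage
  on <- v$stimulus_onset + offset
  resp <- smoothed[window_idx(v, on + response_window[1L],
                              on + response_window[2L])]
  base <- smoothed[window_idx(v, on + baseline_window[1L],
                              on + baseline_window[2L])]
  max(resp) - mean(base)
}

#' Two-sample permutation test for a shift in means
#'
#' Nonparametric two-sample test analogous to a t test: the statistic is the
#' difference in group means, and its null distribution is obtained by
#' reassigning the pooled values to the two groups. All
#' `choose(n_a + n_b, n_a)` reassignments are enumerated when there are at
#' most `max_exact`; otherwise `n_perm` seeded Monte-Carlo draws are used
#' with the observed assignment counted in both numerator and denominator.
#' Unlike a rank test, the magnitude of the values (not just their order)
#' enters the statistic.
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @param n_perm Monte-Carlo draws when exact enumeration is infeasible
#'   (default 10000).
#' @param seed optional integer seed for the Monte-Carlo branch.
#' @param alternative `"two.sided"` (default), `"greater"` (mean of a
#'   exceeds mean of b) or `"less"`.
#' @param max_exact enumeration cap (default 1e5 assignments).
#' @return permutation p-value.
#' @export
group_comparison_test <- function(values_a, values_b, n_perm = 10000L,
                                  seed = NULL,
                                  alternative = c("two.sided", "greater",
                                                  "less"),
                                  max_exact = 1e5) {
  alternative <- match.arg(alternative)
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a == 0L || n_b == 0L) stop("both groups must be nonempty")
  pooled <- c(values_a, values_b)
  n <- n_a + n_b
  # mean(a) - mean(b) as a function of sum(a): sa/n_a - (S - sa)/n_b
  stat_from_sum <- function(sa) sa / n_a - (sum(pooled) - sa) / n_b
  obs <- stat_from_sum(sum(values_a))
  tol <- 1e-10 * max(1, abs(obs))
  exceeds <- function(t_perm) {
    switch(alternative,
           two.sided = abs(t_perm) >= abs(obs) - tol,
           greater = t_perm >= obs - tol,
           less = t_perm <= obs + tol)
  }
  if (choose(n, n_a) <= max_exact) {
    combos <- utils::combn(n, n_a)
    sums <- colSums(matrix(pooled[combos], nrow = n_a))
    mean(exceeds(stat_from_sum(sums)))
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    sums <- vapply(seq_len(n_perm),
                   function(i) sum(pooled[sample.int(n, n_a)]), numeric(1L))
    (1 + sum(exceeds(stat_from_sum(sums)))) / (n_perm + 1)
  }
}

#' Subthreshold response significance against a pseudo-response null
#'
#' For each non-control stimulus of one cell: real responses are the
#' per-trial peak depolarizations from [subthreshold_response()]; the null
#' is built by applying the identical procedure to response windows shifted
#' into the pre-stimulus period of *every* trace available for the cell
#' (`n_null_windows` disjoint blocks per trace, tiled at -1.8 s strides so
#' each pseudo baseline+window block is disjoint from the real one and from
#' the others). Real versus pseudo responses are compared with the
#' two-sample permutation test and p-values are FDR-adjusted across the
#' cell's stimuli.
#'
#' @param ts a [trial_set()] holding one cell's trials (all stimuli).
#' @param n_null_windows pseudo-response blocks per trace (default 2).
#' @param n_perm Monte-Carlo draws for the permutation test when exact
#'   enumeration is infeasible.
#' @param seed integer seed for the permutation test.
#' @param alpha FDR significance level (default 0.01).
#' @param boxcar boxcar width in s (default 0.045).
#' @return data.frame with one row per non-control stimulus: `cell_id`,
#'   `stimulus_label`, `peak_depolarization` (mean over trials, mV),
#'   `raw_p`, `adjusted_p`, `significant`; the pseudo responses are attached
#'   as attribute `null_pseudo_responses`.
#' @export
subthreshold_test <- function(ts, n_null_windows = 2L, n_perm = 10000L,
                              seed = NULL, alpha = 0.01, boxcar = 0.045) {
  stopifnot(inherits(ts, "trial_set"))
  labs <- vapply(ts$trials, `[[`, character(1L), "stimulus_label")
  cells <- unique(vapply(ts$trials, `[[`, character(1L), "cell_id"))
  if (length(cells) > 1L)
    stop("subthreshold_test expects trials from a single cell")
  stride <- 1.8
  offsets <- -stride * seq_len(n_null_windows)
  # pre-stimulus room: deepest baseline start must be inside the trace
  for (v in ts$trials) {
    if (v$stimulus_onset + min(offsets) - 1 < 0)
      stop("not enough pre-stimulus context for ", n_null_windows,
           " pseudo-response windows (need ",
           1 + stride * n_null_windows, " s before onset)")
  }
  smoothed <- lapply(ts$trials, function(v)
    boxcar_smooth(v, width_s = boxcar)$voltage)
  pseudo <- unlist(lapply(seq_along(ts$trials), function(i) {
    vapply(offsets, function(off)
      subthreshold_response(ts$trials[[i]], boxcar = boxcar, offset = off,
                            smoothed = smoothed[[i]]), numeric(1L))
  }))
  test_labs <- setdiff(unique(labs), ts$control_label)
  rows <- lapply(seq_along(test_labs), function(j) {
    lab <- test_labs[j]
    sel <- which(labs == lab)
    real <- vapply(sel, function(i)
      subthreshold_response(ts$trials[[i]], boxcar = boxcar,
                            smoothed = smoothed[[i]]), numeric(1L))
    p <- group_comparison_test(real, pseudo, n_perm = n_perm,
                               seed = if (is.null(seed)) NULL else seed + j)
    data.frame(cell_id = cells, stimulus_label = lab,
               peak_depolarization = mean(real), raw_p = p)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$raw_p)
  out$significant <- out$adjusted_p < alpha
  attr(out, "null_pseudo_responses") <- pseudo
  out
}

#' Per-cell odor response table from spike trains
#'
#' Counts spikes in the response window for every trial, computes the
#' control-subtracted response magnitude and rate per stimulus, tests
#' significance with the exact one-sided Poisson test, and FDR-adjusts
#' p-values across the cell's stimuli.
#'
#' @param spike_trains list of [spike_train()] objects, one per trial (each
#'   must carry its `trial_ref` for stimulus metadata).
#' @param control_label stimulus code of the control condition.
#' @param alpha FDR significance level (default 0.01).
#' @param start_offset,window_length response window (defaults 0.150 s and
#'   0.500 s after onset).
#' @return data.frame (`response_table`): one row per cell x stimulus with
#'   `mean_response`, `rate_hz`, `raw_p`, `adjusted_p`, `significant`.
#' @export
response_table <- function(spike_trains, control_label, alpha = 0.01,
                           start_offset = 0.150, window_length = 0.500) {
  meta <- do.call(rbind, lapply(spike_trains, function(st) {
    v <- st$trial_ref
    if (is.null(v)) stop("each spike train must carry its trial_ref")
    data.frame(cell_id = v$cell_id, stimulus_label = v$stimulus_label,
               count = window_spike_count(st, v$stimulus_onset,
                                          start_offset, window_length))
  }))
  out <- do.call(rbind, lapply(split(meta, meta$cell_id), function(cm) {
    ctrl <- cm$count[cm$stimulus_label == control_label]
    if (length(ctrl) == 0L)
      stop("cell ", cm$cell_id[1L], " has no '", control_label,
           "' control trials")
    labs <- setdiff(unique(cm$stimulus_label), control_label)
    rows <- do.call(rbind, lapply(labs, function(lab) {
      odor <- cm$count[cm$stimulus_label == lab]
      mag <- response_magnitude(odor, ctrl, window_length)
      data.frame(cell_id = cm$cell_id[1L], stimulus_label = lab,
                 mean_response = mag$mean_response, rate_hz = mag$rate_hz,
                 raw_p = poisson_response_test(
                   odor, ctrl, exposure_ratio = length(odor) / length(ctrl)))
    }))
    rows$adjusted_p <- bh_adjust(rows$raw_p)
    rows$significant <- rows$adjusted_p < alpha
    rows
  }))
  rownames(out) <- NULL
  out
}
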