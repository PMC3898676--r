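# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (double loops, direct formula
# evaluation) so it stays independent of the package's implementations.

random_tree_skeleton <- function(n, seed, scale = 20) {
  set.seed(seed)
  parent <- c(NA_integer_,
              vapply(seq_len(n - 1L), function(i) sample.int(i, 1L),
                     integer(1L)))
  neuron_skeleton(data.frame(
    node_id = seq_len(n), parent_id = parent,
    x = rnorm(n, sd = scale), y = rnorm(n, sd = scale),
    z = rnorm(n, sd = scale), radius = runif(n, 0.5, 2)),
    label = sprintf("rand%d", seed))
}

random_dotprops <- function(n, seed, scale = 50) {
  set.seed(seed)
  p <- matrix(rnorm(3L * n, sd = scale), ncol = 3L)
  tg <- matrix(rnorm(3L * n), ncol = 3L)
  tg <- tg / sqrt(rowSums(tg^2))
  dotprops(p, tg, source_label = sprintf("dp%d", seed))
}

# exhaustive O(N*M) evaluation of the similarity score
naive_similarity <- function(query, target, sigma = 3) {
  n <- nrow(query$points)
  total <- 0
  for (i in seq_len(n)) {
    d2 <- colSums((t(target$points) - query$points[i, ])^2)
    j <- which.min(d2)
    total <- total +
      abs(sum(query$tangents[i, ] * target$tangents[j, ])) *
      exp(-d2[j] / (2 * sigma^2))
  }
  total / n
}

# hand-coded Benjamini-Hochberg step-up
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force binomial tail for the conditional Poisson comparison
binom_tail <- function(k_o, k_c) {
  n <- k_o + k_c
  if (n == 0) return(1)
  sum(choose(n, k_o:n)) / 2^n
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9L), 3L))
  q <- qr.Q(qr_r)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

rotate_dotprops <- function(dp, rot, shift = c(0, 0, 0)) {
  dotprops(sweep(dp$points %*% t(rot), 2L, shift, "+"),
           dp$tangents %*% t(rot),
           source_label = dp$source_label)
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

flat_trial <- function(level = -55, dur_s = 3, fs = 11100, onset = 1.5,
                       ...) {
  voltage_trial(rep(level, round(dur_s * fs)), fs, onset, ...)
}
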