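# Independent brute-force oracles used against the package implementations.

# Floyd-Warshall all-pairs shortest paths on a distance matrix (Inf = no
# edge), independent of the igraph/Dijkstra route used by the package.
fw_shortest_paths <- function(D) {
  n <- nrow(D)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_path_length <- function(W) {
  D <- -log(W)
  diag(D) <- 0
  sp <- fw_shortest_paths(D)
  mean(sp[upper.tri(sp)])
}

oracle_efficiency <- function(W) {
  D <- -log(W)
  diag(D) <- 0
  sp <- fw_shortest_paths(D)
  v <- sp[upper.tri(sp)]
  mean(ifelse(is.infinite(v), 0, 1 / pmax(v, 1e-12)))
}

# Triple-loop geometric-mean weighted clustering.
oracle_clustering <- function(W) {
  n <- nrow(W)
  diag(W) <- 0
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# Random symmetric weight matrix in [lo, hi]; zero_frac of edges removed.
rand_weight_matrix <- function(n, lo = 0.05, hi = 0.95, zero_frac = 0) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- runif(sum(ut), lo, hi)
  if (zero_frac > 0)
    w[runif(length(w)) < zero_frac] <- 0
  W[ut] <- w
  W + t(W)
}

uniform_graph <- function(n, c) {
  W <- matrix(c, n, n)
  diag(W) <- 0
  W
}

# Scaled-down generator conditions used in tests (same gains as the default
# study conditions, shorter recordings at a lower sampling rate).
quick_spec <- function(...) {
  args <- utils::modifyList(
    list(sampling_rate = 128, segment_length_range = c(20, 30),
         n_segments_range = c(2, 3)),
    list(...))
  do.call(synthetic_cohort_spec, args)
}

# |a - b| treating two infinities as equal (disconnected graphs).
safe_absdiff <- function(a, b) {
  if (is.infinite(a) && is.infinite(b) && sign(a) == sign(b)) return(0)
  abs(a - b)
}

# Amplitude of a sinusoidal component at frequency f in a vector sampled at
# fs (projection on the sin/cos pair over whole cycles).
sine_amplitude <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  ncyc <- floor(f * n / fs)
  keep <- seq_len(round(ncyc * fs / f))
  x <- x[keep]; t <- t[keep]
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}
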