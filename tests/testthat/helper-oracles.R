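# Independent direct-summation JSD oracle: explicit element loop in natural
# log converted to base 2, written before and independently of the package
# implementation it checks.
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  acc <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) acc <- acc + 0.5 * p[i] * (log(p[i]) - log(m[i])) / log(2)
    if (q[i] > 0) acc <- acc + 0.5 * q[i] * (log(q[i]) - log(m[i])) / log(2)
  }
  acc
}

# Random probability 4-vector (occasionally with structural zeros).
random_probs <- function(zeros = FALSE) {
  x <- stats::rexp(4)
  if (zeros && stats::runif(1) < 0.5) x[sample(4, sample(1:2, 1))] <- 0
  x / sum(x)
}

# Wrap explicit bin counts as the distribution object the divergence layer
# consumes (bypassing binning, for tests that start from counts).
as_bin_dist <- function(counts, label = "cond") {
  structure(list(condition_label = label, n_sections = sum(counts),
                 counts = as.integer(counts), probs = counts / sum(counts)),
            class = "bin_distribution")
}

# Blocky test image: zero background plus rectangles of given intensity.
block_image <- function(h = 40, w = 40, blocks = list(), base = 0, ...) {
  m <- matrix(base, h, w)
  for (b in blocks) m[b$rows, b$cols] <- b$value
  m
}
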