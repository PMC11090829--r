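#' Jensen-Shannon divergence between two bin distributions
#'
#' `JSD(P, Q) = 0.5 * (sum_i p_i (log2 p_i - log2 m_i) +
#' sum_i q_i (log2 q_i - log2 m_i))` with `M = 0.5 (P + Q)`. Base-2
#' logarithms bound the value in \[0, 1\]: 0 for identical distributions, 1
#' for disjoint support. Zero entries contribute nothing (`0 log 0 := 0`),
#' and bins empty in both distributions are ignored.
#'
#' @param p,q Probability vectors of equal length (here 4 bins), each
#'   non-negative and summing to 1 within `1e-9`; `bin_distribution` objects
#'   are also accepted.
#' @return The divergence, clipped to \[0, 1\] against floating-point drift.
#' @export
jsd <- function(p, q) {
  p <- as_probs(p)
  q <- as_probs(q)
  if (length(p) != length(q))
    jf_data_error("'p' and 'q' must have the same number of bins")
  m <- 0.5 * (p + q)
  term <- function(a) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(m[i])))
  }
  min(max(0.5 * (term(p) + term(q)), 0), 1)
}

as_probs <- function(x) {
  if (inherits(x, "bin_distribution")) x <- x$probs
  if (!is.numeric(x)) jf_data_error("probability vector expected")
  if (any(x < 0)) jf_data_error("probabilities must be non-negative")
  if (abs(sum(x) - 1) > 1e-9)
    jf_data_error(sprintf("probabilities must sum to 1 (got %.12f)", sum(x)))
  x
}

#' Normalize a raw JSD onto the similarity scale
#'
#' `JSD_norm = (1 - JSD / norm_constant) * 100`: identity maps to 100, the
#' most disparate comparison observed in the reference data set (raw 0.56,
#' ER+ vs TNBC starting tissue) maps to 0. Values slightly above the anchor
#' give small negative scores. Higher = more similar.
#'
#' @param raw Raw JSD value(s).
#' @param norm_constant Anchor; the default 0.56 is the reference data set's
#'   maximal observed divergence, and can be re-derived for a new data set
#'   with [calibrate_norm_constant()].
#' @return Normalized score(s).
#' @export
normalize_jsd <- function(raw, norm_constant = 0.56) {
  if (norm_constant <= 0) jf_config_error("'norm_constant' must be positive")
  (1 - raw / norm_constant) * 100
}

pool_distributions <- function(dists, labels) {
  counts <- Reduce(`+`, lapply(labels, function(l) dists[[l]]$counts))
  n <- sum(counts)
  structure(list(condition_label = paste(labels, collapse = "+"),
                 n_sections = n, counts = counts, probs = counts / n),
            class = "bin_distribution")
}

#' Group-level JSD between two sets of conditions
#'
#' Two constructions are supported. `"pooled"` concatenates the section
#' counts of each group into one distribution per group and takes a single
#' JSD — the group-level comparison. `"mean_pairwise"` averages the JSD over
#' all cross-group pairs of conditions (for a group compared against itself,
#' over all distinct within-group pairs), which quantifies typical
#' member-to-member disparity and is the construction that gives a non-zero
#' within-group score.
#'
#' @param dists Named list of `bin_distribution` objects.
#' @param group_a,group_b Character vectors of condition labels.
#' @param mode `"pooled"` or `"mean_pairwise"`.
#' @return Raw JSD (numeric scalar).
#' @export
group_jsd <- function(dists, group_a, group_b,
                      mode = c("pooled", "mean_pairwise")) {
  mode <- match.arg(mode)
  if (!length(group_a) || !length(group_b))
    jf_config_error("both groups must be non-empty")
  unknown <- setdiff(c(group_a, group_b), names(dists))
  if (length(unknown))
    jf_config_error(paste("unknown condition label(s):",
                          paste(unknown, collapse = ", ")))
  if (mode == "pooled") {
    jsd(pool_distributions(dists, group_a), pool_distributions(dists, group_b))
  } else {
    same <- setequal(group_a, group_b)
    pairs <- if (same) {
      if (length(group_a) < 2)
        jf_config_error("mean_pairwise within a group needs >= 2 members")
      utils::combn(group_a, 2, simplify = FALSE)
    } else {
      unlist(lapply(group_a, function(a) lapply(group_b, function(b) c(a, b))),
             recursive = FALSE)
    }
    mean(vapply(pairs, function(pr) jsd(dists[[pr[1]]], dists[[pr[2]]]),
                numeric(1)))
  }
}

#' Derive the normalization anchor from the data set itself
#'
#' Computes the JSD between the two most disparate groups (in the reference
#' methodology, pooled ER+ vs pooled TNBC starting tissue) for use as
#' `norm_constant`; pin it to 0.56 to stay on the published scale.
#'
#' @inheritParams group_jsd
#' @return Raw JSD to use as the normalization constant.
#' @export
calibrate_norm_constant <- function(dists, group_a, group_b,
                                    mode = c("pooled", "mean_pairwise")) {
  group_jsd(dists, group_a, group_b, mode = match.arg(mode))
}

#' Compare condition pairs by normalized JSD
#'
#' @param dists Named list of `bin_distribution` objects.
#' @param pairs List of length-2 character vectors (condition label pairs),
#'   or NULL for the full all-vs-all matrix (distinct unordered pairs plus
#'   self-comparisons).
#' @param norm_constant Anchor passed to [normalize_jsd()].
#' @param mode Recorded on the result (single conditions are compared
#'   directly; group modes apply in [group_jsd()]).
#' @return Tibble of divergence results: `label_p`, `label_q`, `jsd_raw`,
#'   `jsd_norm`, `norm_constant`, `mode`; one row per pair, in input order.
#' @export
compare_conditions <- function(dists, pairs = NULL, norm_constant = 0.56,
                               mode = "pooled") {
  labels <- names(dists)
  if (is.null(pairs)) {
    idx <- expand.grid(i = seq_along(labels), j = seq_along(labels))
    idx <- idx[idx$i <= idx$j, ]
    pairs <- Map(function(i, j) c(labels[i], labels[j]), idx$i, idx$j)
  }
  unknown <- setdiff(unlist(pairs), labels)
  if (length(unknown))
    jf_config_error(paste("unknown condition label(s):",
                          paste(unknown, collapse = ", ")))
  raw <- vapply(pairs, function(pr) jsd(dists[[pr[1]]], dists[[pr[2]]]),
                numeric(1))
  tibble::tibble(
    label_p = vapply(pairs, `[`, character(1), 1),
    label_q = vapply(pairs, `[`, character(1), 2),
    jsd_raw = raw,
    jsd_norm = normalize_jsd(raw, norm_constant),
    norm_constant = norm_constant,
    mode = mode)
}

#' All-vs-all raw JSD matrix
#'
#' @param dists Named list of `bin_distribution` objects.
#' @return Symmetric numeric matrix of raw JSD values with zero diagonal.
#' @export
jsd_matrix <- function(dists) {
  n <- length(dists)
  m <- matrix(0, n, n, dimnames = list(names(dists), names(dists)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    m[i, j] <- m[j, i] <- jsd(dists[[i]], dists[[j]])
  m
}
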