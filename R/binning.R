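#' Per-section log2(K8/K14) ratio
#'
#' Converts section quant rows into log-ratio records. When either area is
#' zero a symmetric pseudocount is added to both numerator and denominator
#' (so the correction introduces no directional bias) and the record is
#' flagged; sections with no K8, no K14 and no tissue carry no phenotype
#' information and are rejected.
#'
#' @param quants Tibble with `k8_area_px` and `k14_area_px` columns (and the
#'   usual identifier columns).
#' @param pseudocount_px Pseudocount in pixels applied to both areas when
#'   either is zero.
#' @return Tibble of log-ratio records: identifiers, `log2_ratio`,
#'   `pseudocount_applied`. Rejected rows are dropped with a message and
#'   listed in the `rejected` attribute.
#' @export
log2_ratio <- function(quants, pseudocount_px = 1) {
  stopifnot(all(c("k8_area_px", "k14_area_px") %in% names(quants)))
  k8 <- quants$k8_area_px
  k14 <- quants$k14_area_px
  tissue <- if ("tissue_area_px" %in% names(quants)) quants$tissue_area_px else k8 + k14
  reject <- k8 == 0 & k14 == 0 & tissue == 0
  pseudo <- (k8 == 0 | k14 == 0) & !reject
  eps <- ifelse(pseudo, pseudocount_px, 0)
  value <- log2((k8 + eps) / (k14 + eps))
  id_cols <- intersect(c("section_id", "patient_id", "subtype", "condition",
                         "source_kind"), names(quants))
  out <- tibble::as_tibble(quants[id_cols])
  out$log2_ratio <- value
  out$pseudocount_applied <- pseudo
  if (any(reject)) {
    message(sprintf("log2_ratio: rejected %d section(s) with no tissue", sum(reject)))
    rejected <- out[reject, , drop = FALSE]
    out <- out[!reject, , drop = FALSE]
    attr(out, "rejected") <- rejected
  }
  out
}

#' Fit the quartile bin scheme from a reference cohort
#'
#' The three boundaries are the 25th, 50th and 75th percentiles of the
#' reference log-ratios (linear interpolation between order statistics,
#' `stats::quantile` type 7). In this methodology the reference is normal
#' breast starting tissue, so the reference itself occupies all four bins
#' with probability ~1/4 each by construction.
#'
#' @param reference Tibble of log-ratio records, or a numeric vector of
#'   log-ratios; at least 4 values.
#' @param reference_label Label recorded with the scheme.
#' @param type Quantile algorithm (`stats::quantile` type); 7 is linear
#'   interpolation between order statistics.
#' @return A `bin_scheme`: `q25`, `q50`, `q75`, `reference_label`,
#'   `n_reference`.
#' @export
fit_bin_scheme <- function(reference, reference_label = "normal ST", type = 7) {
  x <- if (is.data.frame(reference)) reference$log2_ratio else reference
  x <- x[is.finite(x)]
  if (length(x) < 4)
    jf_data_error("at least 4 finite reference log-ratios are required")
  qs <- unname(quantile(x, c(0.25, 0.5, 0.75), type = type))
  if (qs[1] == qs[3])
    warning("degenerate bin scheme: all three boundaries coincide")
  structure(list(q25 = qs[1], q50 = qs[2], q75 = qs[3],
                 reference_label = reference_label, n_reference = length(x)),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf(
    "<bin_scheme> ref '%s' (n = %d): (-Inf, %.4f] (%.4f, %.4f] (%.4f, %.4f] (%.4f, Inf)\n",
    x$reference_label, x$n_reference, x$q25, x$q25, x$q50, x$q50, x$q75, x$q75))
  invisible(x)
}

#' Assign log-ratios to quartile bins
#'
#' Bins are left-open, right-closed: bin 1 = (-Inf, q25\], bin 2 =
#' (q25, q50\], bin 3 = (q50, q75\], bin 4 = (q75, Inf). One consistent
#' closure so every value maps to exactly one bin; a value sitting exactly on
#' a boundary belongs to the lower bin.
#'
#' @param values Numeric log-ratios (finite).
#' @param scheme A [fit_bin_scheme()] result.
#' @return Integer vector in 1..4.
#' @export
bin_index <- function(values, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (any(!is.finite(values))) jf_data_error("bin_index requires finite values")
  findInterval(values, c(scheme$q25, scheme$q50, scheme$q75),
               left.open = TRUE) + 1L
}

#' Build the bin distribution for one condition
#'
#' Counts sections per bin and normalizes by the condition's total; emits an
#' under-sampling warning when fewer sections are available than the active
#' minimum (see [min_sections()]).
#'
#' @param records Tibble of log-ratio records or numeric log-ratios.
#' @param scheme A [fit_bin_scheme()] result.
#' @param condition_label Label for this condition.
#' @param n_min Optional minimum section count; fewer records warns.
#' @return A `bin_distribution`: `condition_label`, `n_sections`,
#'   `counts` (integer 4-vector), `probs` (sums to 1).
#' @export
make_distribution <- function(records, scheme, condition_label = "condition",
                              n_min = NULL) {
  x <- if (is.data.frame(records)) records$log2_ratio else records
  if (!length(x)) jf_data_error(sprintf("condition '%s' has no sections", condition_label))
  counts <- tabulate(bin_index(x, scheme), nbins = 4L)
  if (!is.null(n_min) && length(x) < n_min)
    warning(sprintf("condition '%s': n = %d sections is below the minimum %d",
                    condition_label, length(x), n_min))
  structure(list(condition_label = condition_label,
                 n_sections = length(x),
                 counts = counts,
                 probs = counts / length(x)),
            class = "bin_distribution")
}

#' @export
print.bin_distribution <- function(x, ...) {
  cat(sprintf("<bin_distribution> '%s' (n = %d): %s\n", x$condition_label,
              x$n_sections, paste(sprintf("%.3f", x$probs), collapse = " ")))
  invisible(x)
}

#' Minimum number of sections to cover the rarest bin
#'
#' If the least represented bin has frequency `f`, the chance that `N`
#' sections all miss it is `(1 - f)^N`; the smallest `N` with
#' `1 - (1 - f)^N >= c` guarantees at least one section from that bin with
#' confidence `c`. With the cohort's observed least-bin frequency f = 0.08
#' and c = 0.85 this gives 23 sections.
#'
#' @param f Frequency of the least represented bin, in (0, 1\].
#' @param c Required confidence, in \[0, 1).
#' @return A `sample_size_spec` list: `least_bin_freq`, `confidence`, `n_min`.
#' @export
min_sections <- function(f = 0.08, c = 0.85) {
  if (f <= 0 || f > 1)
    jf_config_error("'f' must be in (0, 1]: a zero-frequency bin can never be covered")
  if (c < 0 || c >= 1)
    jf_config_error("'c' must be in [0, 1): certainty requires unbounded sampling")
  n <- if (f == 1) 1L else as.integer(ceiling(log(1 - c) / log(1 - f)))
  n <- max(n, 1L)
  while (1 - (1 - f)^n < c) n <- n + 1L  # guard against rounding at the edge
  structure(list(least_bin_freq = f, confidence = c, n_min = n),
            class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat(sprintf("<sample_size_spec> f = %.3g, confidence = %.3g -> n_min = %d\n",
              x$least_bin_freq, x$confidence, x$n_min))
  invisible(x)
}

#' Average frequency of the least represented bin
#'
#' Used to set `f` in [min_sections()] from observed cohort distributions.
#'
#' @param dists List of `bin_distribution` objects (or a single one).
#' @return Mean over distributions of their minimum bin probability.
#' @export
least_bin_frequency <- function(dists) {
  if (inherits(dists, "bin_distribution")) dists <- list(dists)
  if (!length(dists)) jf_data_error("at least one distribution is required")
  mean(vapply(dists, function(d) min(d$probs), numeric(1)))
}

#' Tidy table of bin distributions
#'
#' @param dists Named list of `bin_distribution` objects.
#' @return Tibble with `condition`, `bin`, `count`, `prob`, `n_sections` —
#'   the long format the heatmap and CSV outputs use.
#' @export
distribution_table <- function(dists) {
  if (inherits(dists, "bin_distribution")) dists <- list(dists)
  dplyr::bind_rows(lapply(dists, function(d) {
    tibble::tibble(condition = d$condition_label, bin = 1:4,
                   count = d$counts, prob = d$probs, n_sections = d$n_sections)
  }))
}
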