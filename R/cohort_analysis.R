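#' Marker-redundancy correlation
#'
#' Pearson product-moment correlation between paired per-section measurements
#' of two markers (areas or positive-cell counts), used to decide whether an
#' auxiliary marker (e.g. CD10, SMA, p63 vs K14; K18, ERalpha vs K8) adds
#' information beyond the core pair or is redundant with it.
#'
#' @param x,y Paired numeric measurements, one value per section.
#' @param marker_x,marker_y Role names recorded on the result.
#' @param measure `"area"` or `"count"`.
#' @return A one-row tibble: `marker_x`, `marker_y`, `measure`, `r`,
#'   `p_value` (two-sided), `n`.
#' @export
marker_correlation <- function(x, y, marker_x = "x", marker_y = "y",
                               measure = c("area", "count")) {
  measure <- match.arg(measure)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    jf_data_error("at least 3 paired finite measurements are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    jf_data_error("correlation undefined: one of the variables has zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(marker_x = marker_x, marker_y = marker_y, measure = measure,
                 r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fraction of positively stained cells
#'
#' @param positive,total Cell counts, `0 <= positive <= total`, `total >= 1`.
#' @return `positive / total`.
#' @export
positive_cell_fraction <- function(positive, total) {
  if (any(total < 1)) jf_data_error("'total' must be >= 1")
  if (any(positive < 0) || any(positive > total))
    jf_data_error("'positive' must lie in [0, total]")
  positive / total
}

#' Two-group comparison with the Mann-Whitney test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact enumeration when
#' the combined sample size is at most 16 and there are no ties, the
#' tie-corrected normal approximation with continuity correction otherwise.
#' The fold change is the ratio of group summaries, `b` over `a` (means by
#' default, medians on request).
#'
#' @param a,b Numeric measurement vectors (reference group first).
#' @param label_a,label_b Group labels recorded on the result.
#' @param center `"mean"` or `"median"` for the fold-change summary.
#' @return One-row tibble: `label_a`, `label_b`, `statistic` (rank-sum W),
#'   `p_value`, `fold_change`, `n_a`, `n_b`.
#' @export
group_compare <- function(a, b, label_a = "a", label_b = "b",
                          center = c("mean", "median")) {
  center <- match.arg(center)
  if (!length(a) || !length(b))
    jf_data_error("both groups must contain at least one measurement")
  n_a <- length(a); n_b <- length(b)
  if (length(unique(c(a, b))) == 1L) {
    warning("all measurements tied across groups; p = 1")
    w <- n_a * n_b / 2
    p <- 1
  } else {
    has_ties <- anyDuplicated(c(a, b)) > 0
    exact <- (n_a + n_b) <= 16 && !has_ties
    wt <- suppressWarnings(
      wilcox.test(b, a, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    w <- unname(wt$statistic)
    p <- min(wt$p.value, 1)
  }
  fun <- if (center == "mean") mean else stats::median
  tibble::tibble(label_a = label_a, label_b = label_b, statistic = w,
                 p_value = p, fold_change = fun(b) / fun(a),
                 n_a = n_a, n_b = n_b)
}

#' Organoid area response to treatment
#'
#' Normalizes treated organoid areas to the vehicle-control mean (so the
#' control summary is 1 by construction) and compares the groups with
#' [group_compare()]; the fold change is then the normalized-area ratio.
#'
#' @param treated,control Organoid areas under drug and vehicle.
#' @param label_treated,label_control Labels recorded on the result.
#' @return As [group_compare()], computed on control-normalized areas.
#' @export
area_response <- function(treated, control, label_treated = "treated",
                          label_control = "control") {
  if (!length(treated)) jf_data_error("'treated' group is empty")
  if (!length(control) || mean(control) <= 0)
    jf_config_error("'control' must be non-empty with positive mean area")
  scale <- mean(control)
  group_compare(control / scale, treated / scale,
                label_a = label_control, label_b = label_treated)
}
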