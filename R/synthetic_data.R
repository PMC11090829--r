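## Seed discipline: generators save and restore the caller's RNG state and
## seed locally from the spec, so identical specs give identical output
## byte-for-byte regardless of surrounding code.
with_spec_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for one synthetic two-channel section image
#'
#' Describes a ground-truthed K8/K14 immunofluorescence field: elliptical
#' stain blobs covering requested fractions of the image, constant foreground
#' and background intensities, and additive Gaussian noise.
#'
#' @param height,width Image size in pixels.
#' @param k8_area_frac,k14_area_frac Target positive-area fractions.
#' @param overlap_frac Fraction of image area where both stains are positive
#'   (double-positive cells); must not exceed either marker fraction.
#' @param blob_count Approximate number of blobs per channel.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param foreground_intensity,background_intensity Mean intensities.
#' @param seed Integer seed; identical specs generate identical images.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(height = 200, width = 200,
                                 k8_area_frac = 0.15, k14_area_frac = 0.10,
                                 overlap_frac = 0, blob_count = 8,
                                 noise_sigma = 0,
                                 foreground_intensity = 200,
                                 background_intensity = 20, seed = 1) {
  fr <- c(k8_area_frac, k14_area_frac, overlap_frac)
  if (any(fr < 0) || any(fr[1:2] > 1))
    jf_config_error("area fractions must lie in [0, 1]")
  if (overlap_frac > min(k8_area_frac, k14_area_frac))
    jf_config_error("'overlap_frac' cannot exceed either marker fraction")
  if (k8_area_frac + k14_area_frac - overlap_frac > 1)
    jf_config_error("requested stain fractions exceed the image area")
  structure(list(height = height, width = width,
                 k8_area_frac = k8_area_frac, k14_area_frac = k14_area_frac,
                 overlap_frac = overlap_frac, blob_count = blob_count,
                 noise_sigma = noise_sigma,
                 foreground_intensity = foreground_intensity,
                 background_intensity = background_intensity, seed = seed),
            class = "synthetic_image_spec")
}

## Grow a union of random ellipses to exactly `target_px` pixels, drawing
## only from `allowed` (logical matrix) when given. Returns pixel indices in
## order of addition so the caller can trim to an exact area.
grow_blob_mask <- function(h, w, target_px, blob_count, allowed = NULL) {
  if (target_px == 0) return(integer(0))
  grid_x <- matrix(rep(seq_len(w), each = h), h, w)
  grid_y <- matrix(rep(seq_len(h), w), h, w)
  mean_blob_px <- max(target_px / blob_count, 4)
  radius <- sqrt(mean_blob_px / pi)
  taken <- matrix(FALSE, h, w)
  order_idx <- integer(0)
  tries <- 0L
  while (length(order_idx) < target_px) {
    tries <- tries + 1L
    if (tries > 200L * blob_count + 200L)
      jf_error("cannot reach the requested area fraction with the allowed region",
               "jsdfidelity_generation_error")
    cx <- runif(1, 1, w); cy <- runif(1, 1, h)
    a <- radius * runif(1, 0.6, 1.6); b <- radius * runif(1, 0.6, 1.6)
    th <- runif(1, 0, pi)
    u <- (grid_x - cx) * cos(th) + (grid_y - cy) * sin(th)
    v <- -(grid_x - cx) * sin(th) + (grid_y - cy) * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!is.null(allowed)) inside <- inside & allowed
    new_px <- which(inside & !taken)
    if (!length(new_px)) next
    taken[new_px] <- TRUE
    order_idx <- c(order_idx, new_px)
  }
  order_idx[seq_len(target_px)]
}

#' Generate a synthetic section image with ground-truth masks
#'
#' Builds K8 and K14 positivity masks from random ellipses hitting the
#' requested area fractions exactly (the last blob is trimmed pixel-wise),
#' then renders each channel as background/foreground intensity plus
#' Gaussian noise, clipped at zero.
#'
#' @param spec A [synthetic_image_spec()].
#' @param ... Metadata passed to [quant_image()].
#' @return List with `image` (a 2-channel [quant_image()], roles
#'   `k8 = 1, k14 = 2`) and `masks` (logical ground-truth matrices `k8`,
#'   `k14`).
#' @export
gen_section_image <- function(spec, ...) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  with_spec_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    npx <- h * w
    k8_px <- round(spec$k8_area_frac * npx)
    k14_px <- round(spec$k14_area_frac * npx)
    ov_px <- round(spec$overlap_frac * npx)
    k8_idx <- grow_blob_mask(h, w, k8_px, spec$blob_count)
    k8_mask <- matrix(FALSE, h, w); k8_mask[k8_idx] <- TRUE
    k14_mask <- matrix(FALSE, h, w)
    if (ov_px > 0) k14_mask[k8_idx[seq_len(ov_px)]] <- TRUE
    extra <- k14_px - ov_px
    if (extra > 0) {
      k14_idx <- grow_blob_mask(h, w, extra, spec$blob_count, allowed = !k8_mask)
      k14_mask[k14_idx] <- TRUE
    }
    render <- function(mask) {
      ch <- matrix(spec$background_intensity, h, w)
      ch[mask] <- spec$foreground_intensity
      if (spec$noise_sigma > 0) ch <- ch + rnorm(npx, 0, spec$noise_sigma)
      pmax(ch, 0)
    }
    img <- quant_image(list(render(k8_mask), render(k14_mask)),
                       c(k8 = 1, k14 = 2), ...)
    list(image = img, masks = list(k8 = k8_mask, k14 = k14_mask))
  })
}

#' Specification for a synthetic section cohort
#'
#' The per-section log2(K8/K14) value is modelled as a two-component normal
#' mixture: a K14-rich component (low log-ratio) and a K8-rich component
#' (high log-ratio). Subtypes differ only in the K8-rich weight: 0.5 for
#' normal tissue (centered, equal quartile occupancy), 0.2 for TNBC
#' (left-skewed, K14-rich), 0.8 for ER+ (right-skewed, K8-rich). Each patient
#' draws a mean offset (`patient_sd`), organoid cohorts are displaced by
#' `culture_drift`, and drug selection is modelled as a mixture-weight delta
#' `treatment_shift` toward the resistant component.
#'
#' @param subtype `"normal"`, `"ER+"` or `"TNBC"`; sets the default weight
#'   and patient count.
#' @param n_patients Number of patients (default: 7 normal, 7 ER+, 6 TNBC).
#' @param sections_per_patient Sections (images) per patient.
#' @param component_means Log2-ratio means `(K14-rich, K8-rich)`.
#' @param component_sds Component standard deviations.
#' @param mixture_weight Weight of the K8-rich component.
#' @param patient_sd Between-patient jitter of the cohort mean (log2 units).
#' @param culture_drift Log2-ratio offset applied to organoid cohorts.
#' @param treatment_shift Signed delta added to `mixture_weight`
#'   (selection under treatment; positive = K8-ward).
#' @param seed Integer seed.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(subtype = c("normal", "ER+", "TNBC"),
                                  n_patients = NULL,
                                  sections_per_patient = 100,
                                  component_means = c(-1.5, 1.5),
                                  component_sds = c(1, 1),
                                  mixture_weight = NULL,
                                  patient_sd = 0.3,
                                  culture_drift = 0,
                                  treatment_shift = 0,
                                  seed = 1) {
  subtype <- match.arg(subtype)
  if (is.null(mixture_weight))
    mixture_weight <- switch(subtype, normal = 0.5, `ER+` = 0.8, TNBC = 0.2)
  if (is.null(n_patients))
    n_patients <- switch(subtype, normal = 7L, `ER+` = 7L, TNBC = 6L)
  if (mixture_weight < 0 || mixture_weight > 1)
    jf_config_error("'mixture_weight' must lie in [0, 1]")
  if (any(component_sds <= 0)) jf_config_error("'component_sds' must be positive")
  structure(list(subtype = subtype, n_patients = as.integer(n_patients),
                 sections_per_patient = as.integer(sections_per_patient),
                 component_means = component_means,
                 component_sds = component_sds,
                 mixture_weight = mixture_weight, patient_sd = patient_sd,
                 culture_drift = culture_drift,
                 treatment_shift = treatment_shift, seed = seed),
            class = "synthetic_cohort_spec")
}

effective_weight <- function(spec) {
  min(max(spec$mixture_weight + spec$treatment_shift, 0), 1)
}

#' Generate a cohort of per-section log-ratio records
#'
#' Draws patients then sections in a fixed order (patient offset first, then
#' that patient's sections), so enlarging `n_patients` leaves earlier
#' patients' sections unchanged. Organoid cohorts (`kind = "organoid"`) are
#' displaced by `culture_drift`; `treatment_shift` re-weights the mixture.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param kind `"ST"` or `"organoid"`.
#' @param condition Condition label for the records (default: `"ST"` or
#'   `"ORG"`).
#' @return Tibble of log-ratio records (same shape as [log2_ratio()] output).
#' @export
gen_cohort <- function(spec, kind = c("ST", "organoid"), condition = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  kind <- match.arg(kind)
  if (is.null(condition)) condition <- if (kind == "ST") "ST" else "ORG"
  w <- effective_weight(spec)
  drift <- if (kind == "organoid") spec$culture_drift else 0
  with_spec_seed(spec$seed, {
    per_patient <- lapply(seq_len(spec$n_patients), function(i) {
      offset <- rnorm(1, 0, spec$patient_sd)
      comp <- 1L + (runif(spec$sections_per_patient) < w)
      value <- rnorm(spec$sections_per_patient,
                     mean = spec$component_means[comp] + offset + drift,
                     sd = spec$component_sds[comp])
      tibble::tibble(
        section_id = sprintf("%s_%s_p%02d_s%03d", spec$subtype, condition, i,
                             seq_len(spec$sections_per_patient)),
        patient_id = sprintf("%s_p%02d", spec$subtype, i),
        subtype = spec$subtype, condition = condition,
        source_kind = kind, log2_ratio = value,
        pseudocount_applied = FALSE)
    })
    dplyr::bind_rows(per_patient)
  })
}

#' Closed-form bin probabilities for a cohort specification
#'
#' Exact probability mass of the generating mixture in each of the four bins
#' via the normal CDF, marginalized over the patient offset (which adds
#' `patient_sd^2` to each component variance). Serves as the independent
#' oracle for [gen_cohort()] and for expected-JSD calculations.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param scheme A [fit_bin_scheme()] result.
#' @param kind `"ST"` or `"organoid"` (applies `culture_drift`).
#' @return Probability 4-vector.
#' @export
analytic_bin_probs <- function(spec, scheme, kind = c("ST", "organoid")) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"),
            inherits(scheme, "bin_scheme"))
  kind <- match.arg(kind)
  w <- effective_weight(spec)
  drift <- if (kind == "organoid") spec$culture_drift else 0
  means <- spec$component_means + drift
  sds <- sqrt(spec$component_sds^2 + spec$patient_sd^2)
  cdf <- function(x) {
    if (all(sds == 0)) (1 - w) * (x >= means[1]) + w * (x >= means[2])
    else (1 - w) * pnorm(x, means[1], sds[1]) + w * pnorm(x, means[2], sds[2])
  }
  cuts <- c(scheme$q25, scheme$q50, scheme$q75)
  diff(c(0, cdf(cuts[1]), cdf(cuts[2]), cdf(cuts[3]), 1))
}

#' Expand log-ratio records into synthetic area measurements
#'
#' Inverts the log-ratio at a fixed tissue area so the synthetic cohort can
#' be written in the same section-quant CSV format the image pipeline emits:
#' `k14 = tissue / (1 + 2^r)`, `k8 = tissue - k14`.
#'
#' @param records Log-ratio record tibble (from [gen_cohort()]).
#' @param tissue_area_px Tissue area assigned to every section.
#' @param image_area_px Image area assigned to every section.
#' @return Section-quant tibble whose [log2_ratio()] reproduces `records`.
#' @export
cohort_as_quants <- function(records, tissue_area_px = 10000,
                             image_area_px = 62500) {
  k14 <- tissue_area_px / (1 + 2^records$log2_ratio)
  tibble::tibble(
    section_id = records$section_id, patient_id = records$patient_id,
    subtype = records$subtype, condition = records$condition,
    source_kind = records$source_kind,
    image_area_px = image_area_px, tissue_area_px = tissue_area_px,
    k8_area_px = tissue_area_px - k14, k14_area_px = k14)
}
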