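#' Multi-channel section image
#'
#' Container for one imaged tissue section (or tile): a stack of equally sized
#' single-channel intensity planes plus a role map naming which plane carries
#' which stain, and the section's identifiers.
#'
#' Recognised roles are `k8`, `k14`, `nuclear`, `tissue` and `marker:<name>`
#' for any auxiliary stain. Intensities are non-negative and kept at native
#' scale (e.g. 0-255 for 8-bit, 0-65535 for 16-bit input).
#'
#' @param pixels Numeric array `H x W x C`, or a matrix for a single channel,
#'   or a list of equally sized matrices (one per channel).
#' @param channel_roles Named integer vector mapping role name to channel
#'   index (1-based).
#' @param section_id,patient_id Opaque identifiers.
#' @param subtype One of `"normal"`, `"ER+"`, `"TNBC"`, `"synthetic"`.
#' @param condition Free condition label (e.g. `"ST"`, `"A7"`, `"PAC_1uM"`).
#' @param source_kind `"ST"` (starting tissue) or `"organoid"`.
#' @return An object of class `quant_image`.
#' @export
quant_image <- function(pixels, channel_roles,
                        section_id = "s1", patient_id = "p1",
                        subtype = c("synthetic", "normal", "ER+", "TNBC"),
                        condition = "ST",
                        source_kind = c("ST", "organoid")) {
  if (is.list(pixels)) {
    dims <- vapply(pixels, dim, integer(2))
    if (ncol(dims) > 1 && any(dims != dims[, 1]))
      jf_data_error("all channels must share the same height and width")
    pixels <- array(unlist(pixels, use.names = FALSE),
                    dim = c(dim(pixels[[1]]), length(pixels)))
  }
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L)
    jf_data_error("'pixels' must be an H x W x C array")
  if (any(pixels < 0)) jf_data_error("intensities must be non-negative")
  subtype <- match.arg(subtype)
  source_kind <- match.arg(source_kind)
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    jf_config_error("'channel_roles' must be a named vector of channel indices")
  if (any(roles < 1L | roles > dim(pixels)[3]))
    jf_config_error(sprintf(
      "channel role index out of range: image has %d channel(s), roles map to [%s]",
      dim(pixels)[3], paste(roles, collapse = ", ")))
  structure(
    list(pixels = pixels, channel_roles = roles,
         section_id = section_id, patient_id = patient_id,
         subtype = subtype, condition = condition, source_kind = source_kind),
    class = "quant_image")
}

#' @export
print.quant_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<quant_image> %s [%s/%s, %s, %s] %dx%d px, %d channel(s): %s\n",
              x$section_id, x$patient_id, x$subtype, x$condition,
              x$source_kind, d[1], d[2], d[3],
              paste(sprintf("%s=%d", names(x$channel_roles), x$channel_roles),
                    collapse = " ")))
  invisible(x)
}

#' @export
dim.quant_image <- function(x) dim(x$pixels)

channel_matrix <- function(img, role) {
  if (!role %in% names(img$channel_roles))
    jf_config_error(sprintf("role '%s' not present in channel map (%s)",
                            role, paste(names(img$channel_roles), collapse = ", ")))
  img$pixels[, , img$channel_roles[[role]]]
}

#' Read a section image from disk
#'
#' Accepts either a single multi-page TIFF (one page per channel) or a vector
#' of per-channel grayscale PNG/TIFF files. TIFF pages are read at native bit
#' depth (integer intensities); PNG intensities are rescaled from \[0, 1\] to
#' 8-bit scale.
#'
#' @param path Character: one multi-page TIFF path, or one path per channel.
#' @param channel_roles Named integer vector mapping role to page/file index.
#' @param ... Metadata passed to [quant_image()] (`section_id`, `patient_id`,
#'   `subtype`, `condition`, `source_kind`).
#' @return A [quant_image()].
#' @export
read_section_image <- function(path, channel_roles, ...) {
  missing <- path[!file.exists(path)]
  if (length(missing))
    jf_error(paste("file not found:", paste(missing, collapse = ", ")),
             "jsdfidelity_io_error")
  read_one <- function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      px <- png::readPNG(p)
      if (length(dim(px)) == 3L) px <- px[, , 1]  # grayscale written as RGB
      list(round(px * 255))
    } else {
      pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
    }
  }
  planes <- do.call(c, lapply(path, read_one))
  if (any(channel_roles > length(planes)))
    jf_config_error(sprintf(
      "channel role index out of range: %d plane(s) loaded", length(planes)))
  dims <- vapply(planes, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1]))
    jf_data_error("channel planes have mismatched dimensions")
  quant_image(planes, channel_roles, ...)
}

#' Write a section image as a multi-page TIFF
#'
#' One 16-bit page per channel; integer intensities up to 65535 round-trip
#' exactly through [read_section_image()].
#'
#' @param img A [quant_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(img, path) {
  mx <- max(img$pixels, 1)
  if (mx > 65535) jf_data_error("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(img$pixels)[3]),
                  function(k) img$pixels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Threshold one channel into a binary positivity mask
#'
#' Default is Otsu's method on a 256-level histogram of the channel (the
#' standard parameter-free choice for bimodal fluorescence); a fixed intensity
#' threshold can be supplied instead. Connected components smaller than
#' `min_object_px` are removed as speckle.
#'
#' @param img A [quant_image()].
#' @param role Channel role to threshold.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Intensity threshold, required when `method = "fixed"`.
#' @param min_object_px Minimum connected-component area kept, in pixels.
#' @return A `binary_mask`: logical matrix `pixels` plus `role`,
#'   `threshold_used`, `method`.
#' @export
threshold_channel <- function(img, role, method = c("otsu", "fixed"),
                              fixed_value = NULL, min_object_px = 25) {
  method <- match.arg(method)
  px <- channel_matrix(img, role)
  if (method == "otsu") {
    rng <- range(px)
    if (diff(rng) == 0)
      jf_data_error(sprintf(
        "channel '%s' has constant intensity; Otsu threshold is degenerate", role))
    th01 <- EBImage::otsu(EBImage::Image((px - rng[1]) / diff(rng)),
                          range = c(0, 1), levels = 256)
    threshold <- rng[1] + th01 * diff(rng)
  } else {
    if (is.null(fixed_value))
      jf_config_error("method = 'fixed' requires 'fixed_value'")
    threshold <- fixed_value
  }
  mask <- px > threshold
  if (min_object_px > 1 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow = nrow(mask))
  }
  structure(list(pixels = mask, role = role, threshold_used = threshold,
                 method = method),
            class = "binary_mask")
}

#' Positive area of a mask, in pixels
#' @param mask A `binary_mask` or logical matrix.
#' @return Integer pixel count.
#' @export
positive_area <- function(mask) {
  if (inherits(mask, "binary_mask")) mask <- mask$pixels
  sum(mask)
}

mask_pixels <- function(mask) if (inherits(mask, "binary_mask")) mask$pixels else mask

#' Reduce an image and its masks to per-section area measurements
#'
#' The tissue area defaults to the union of the K8+ and K14+ masks — the most
#' conservative definition available from the two mandatory channels; with
#' `tissue_policy = "dedicated_channel"` a mask under the `tissue` role is
#' used instead.
#'
#' @param img A [quant_image()].
#' @param masks Named list of masks; must include `k8` and `k14`. Additional
#'   entries become `area_<role>_px` columns.
#' @param tissue_policy `"union_k8_k14"` or `"dedicated_channel"`.
#' @return A one-row tibble (a *section quant* record): identifiers,
#'   `image_area_px`, `tissue_area_px`, `k8_area_px`, `k14_area_px`, and any
#'   extra marker areas.
#' @export
quantify_section <- function(img, masks,
                             tissue_policy = c("union_k8_k14", "dedicated_channel")) {
  tissue_policy <- match.arg(tissue_policy)
  if (!all(c("k8", "k14") %in% names(masks)))
    jf_config_error("'masks' must contain both 'k8' and 'k14'")
  k8 <- mask_pixels(masks$k8)
  k14 <- mask_pixels(masks$k14)
  tissue <- if (tissue_policy == "union_k8_k14") {
    k8 | k14
  } else {
    if (!"tissue" %in% names(masks))
      jf_config_error("tissue_policy = 'dedicated_channel' requires a 'tissue' mask")
    mask_pixels(masks$tissue)
  }
  out <- tibble::tibble(
    section_id = img$section_id, patient_id = img$patient_id,
    subtype = img$subtype, condition = img$condition,
    source_kind = img$source_kind,
    image_area_px = prod(dim(img$pixels)[1:2]),
    tissue_area_px = sum(tissue),
    k8_area_px = sum(k8), k14_area_px = sum(k14))
  extra <- setdiff(names(masks), c("k8", "k14", "tissue"))
  for (r in extra)
    out[[paste0("area_", gsub("[^a-zA-Z0-9]", "_", r), "_px")]] <-
      positive_area(masks[[r]])
  out
}

#' Tile a starting-tissue image into an organoid-sized grid
#'
#' Starting-tissue fields are much larger than organoid sections, which would
#' bias the K8/K14 ratio toward well-mixed averages; tiling restores
#' comparable sampling units. The image is cut into a non-overlapping grid in
#' row-major order; edge remainders are kept as smaller tiles. Organoid-source
#' images pass through untiled.
#'
#' @param img A [quant_image()].
#' @param tile_side_px Tile side length in pixels.
#' @return List of [quant_image()] tiles; each inherits the parent metadata
#'   with a `.t<k>` suffix on `section_id`.
#' @export
tile_image <- function(img, tile_side_px) {
  if (tile_side_px < 1) jf_config_error("'tile_side_px' must be >= 1")
  if (img$source_kind != "ST") return(list(img))
  d <- dim(img$pixels)
  if (tile_side_px > d[1] && tile_side_px > d[2]) {
    warning("tile_side_px exceeds both image dimensions; returning image untiled")
    return(list(img))
  }
  row_starts <- seq(1L, d[1], by = tile_side_px)
  col_starts <- seq(1L, d[2], by = tile_side_px)
  tiles <- vector("list", length(row_starts) * length(col_starts))
  k <- 0L
  for (r0 in row_starts) for (c0 in col_starts) {
    k <- k + 1L
    rows <- r0:min(r0 + tile_side_px - 1L, d[1])
    cols <- c0:min(c0 + tile_side_px - 1L, d[2])
    t_img <- img
    t_img$pixels <- img$pixels[rows, cols, , drop = FALSE]
    t_img$section_id <- sprintf("%s.t%03d", img$section_id, k)
    tiles[[k]] <- t_img
  }
  tiles
}

#' Default tile side from an organoid image set
#'
#' `round(sqrt(mean image area))` over the run's organoid images, so that
#' starting-tissue tiles match the average organoid section size.
#'
#' @param organoid_imgs List of [quant_image()] objects, or numeric vector of
#'   image areas in pixels.
#' @return Integer side length.
#' @export
default_tile_side <- function(organoid_imgs) {
  areas <- if (is.numeric(organoid_imgs)) organoid_imgs
           else vapply(organoid_imgs, function(x) prod(dim(x$pixels)[1:2]), numeric(1))
  if (!length(areas)) jf_config_error("no organoid images to derive tile size from")
  as.integer(round(sqrt(mean(areas))))
}

#' Drop tiles with too little tissue
#'
#' Keeps tiles whose tissue area strictly exceeds `min_tissue_frac` of their
#' own area (default 5%); near-empty tiles contribute ratio noise, not signal.
#'
#' @param quants Tibble of section quant rows (one per tile/section).
#' @param min_tissue_frac Retention threshold as a fraction of tile area.
#' @return The kept subset, order preserved, with a `dropped` attribute giving
#'   the section ids removed.
#' @export
filter_tiles <- function(quants, min_tissue_frac = 0.05) {
  keep <- quants$tissue_area_px / quants$image_area_px > min_tissue_frac
  out <- quants[keep, , drop = FALSE]
  attr(out, "dropped") <- quants$section_id[!keep]
  if (any(!keep))
    message(sprintf("filter_tiles: dropped %d of %d tiles below %.1f%% tissue",
                    sum(!keep), length(keep), 100 * min_tissue_frac))
  out
}

#' Count positively stained nuclei in a channel
#'
#' Thresholds the channel, labels connected components, and counts those with
#' area inside the plausible single-nucleus window. No splitting of touching
#' nuclei is attempted.
#'
#' @inheritParams threshold_channel
#' @param min_nucleus_px,max_nucleus_px Component-area window, in pixels.
#' @return Integer count.
#' @export
count_positive_nuclei <- function(img, role, min_nucleus_px = 50,
                                  max_nucleus_px = 5000,
                                  method = c("otsu", "fixed"),
                                  fixed_value = NULL) {
  method <- match.arg(method)
  px <- channel_matrix(img, role)
  if (method == "otsu" && diff(range(px)) == 0) return(0L)
  mask <- threshold_channel(img, role, method = method,
                            fixed_value = fixed_value, min_object_px = 1)
  lab <- EBImage::bwlabel(mask$pixels)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_nucleus_px & sizes <= max_nucleus_px)
}
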