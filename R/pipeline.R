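#' Default run configuration
#'
#' All tunable parameters of the pipeline in one list, serializable to
#' YAML/JSON and written into every output manifest. Override fields via
#' `...` (e.g. `default_config(norm_constant = 0.5)`).
#'
#' @param ... Named overrides of the defaults.
#' @return A validated `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    channel_roles = c(k8 = 1, k14 = 2),
    threshold = list(method = "otsu", fixed_value = NULL, min_object_px = 25),
    tile = list(side_px = NULL, filter_scope = "all"),
    min_tissue_frac = 0.05,
    pseudocount_px = 1,
    quantile_type = 7,
    norm_constant = 0.56,
    mode = "pooled",
    sample_size = list(f = 0.08, c = 0.85),
    nucleus_px = c(50, 5000),
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    jf_config_error(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#' @param cfg A config list (e.g. read from YAML with [read_config()]).
#' @return The config, classed `run_config`, or an error.
#' @export
validate_config <- function(cfg) {
  ok <- is.list(cfg) &&
    is.numeric(cfg$channel_roles) && all(c("k8", "k14") %in% names(cfg$channel_roles)) &&
    cfg$threshold$method %in% c("otsu", "fixed") &&
    is.numeric(cfg$min_tissue_frac) && cfg$min_tissue_frac >= 0 && cfg$min_tissue_frac < 1 &&
    cfg$pseudocount_px > 0 && cfg$norm_constant > 0 &&
    cfg$mode %in% c("pooled", "mean_pairwise", "both") &&
    cfg$sample_size$f > 0 && cfg$sample_size$f <= 1 &&
    cfg$sample_size$c >= 0 && cfg$sample_size$c < 1
  if (!isTRUE(ok)) jf_config_error("invalid run configuration")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with (a subset of) the [default_config()] fields.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$channel_roles)) raw$channel_roles <- unlist(raw$channel_roles)
  do.call(default_config, raw)
}

threshold_values <- function(img, roles, cfg) {
  vapply(roles, function(r) {
    if (cfg$threshold$method == "fixed") cfg$threshold$fixed_value
    else threshold_channel(img, r, method = "otsu",
                           min_object_px = 1)$threshold_used
  }, numeric(1))
}

#' Quantify a set of section images end to end
#'
#' For each image: thresholds are computed once on the full field (Otsu by
#' default), starting-tissue images are tiled to the organoid scale, the
#' fixed per-image thresholds are applied to every tile, tiles/sections are
#' reduced to area measurements, and tiles under the tissue-fraction filter
#' are dropped.
#'
#' Thresholding on the parent image rather than per tile keeps the threshold
#' well defined on near-empty tiles and makes tile measurements additive.
#'
#' @param images List of [quant_image()] objects.
#' @param config A [default_config()] list.
#' @param tile_side_px Tile side; default derives from the organoid images
#'   present via [default_tile_side()] (falling back to no tiling when the
#'   set has no organoids and no explicit side is configured).
#' @return Section-quant tibble, one row per kept tile/section.
#' @export
run_quantify <- function(images, config = default_config(), tile_side_px = NULL) {
  stopifnot(length(images) > 0)
  cfg <- validate_config(config)
  roles <- names(cfg$channel_roles)
  roles <- roles[roles %in% c("k8", "k14")]
  if (is.null(tile_side_px)) tile_side_px <- cfg$tile$side_px
  if (is.null(tile_side_px)) {
    org <- Filter(function(x) x$source_kind == "organoid", images)
    tile_side_px <- if (length(org)) default_tile_side(org) else Inf
  }
  rows <- lapply(images, function(img) {
    th <- threshold_values(img, roles, cfg)
    tiles <- if (is.finite(tile_side_px)) tile_image(img, tile_side_px) else list(img)
    dplyr::bind_rows(lapply(tiles, function(t_img) {
      masks <- lapply(roles, function(r)
        threshold_channel(t_img, r, method = "fixed", fixed_value = th[[r]],
                          min_object_px = cfg$threshold$min_object_px))
      names(masks) <- roles
      quantify_section(t_img, masks)
    }))
  })
  quants <- dplyr::bind_rows(rows)
  scope <- cfg$tile$filter_scope
  if (identical(scope, "ST")) {
    st <- quants$source_kind == "ST"
    dplyr::bind_rows(filter_tiles(quants[st, ], cfg$min_tissue_frac),
                     quants[!st, ])
  } else {
    filter_tiles(quants, cfg$min_tissue_frac)
  }
}

#' Bin, score and plot a quantified data set
#'
#' Fits the quartile scheme on the reference condition, builds one bin
#' distribution per condition, scores the requested pairs with the
#' normalized JSD, and returns the standard figures (density, violin,
#' heatmap) alongside the tables.
#'
#' @param quants Section-quant tibble (or a log-ratio record tibble, which
#'   is used as is).
#' @param reference Condition label whose sections define the bin scheme.
#' @param pairs Condition pairs for [compare_conditions()]; NULL = all-vs-all.
#' @param config A [default_config()] list.
#' @return List: `records`, `scheme`, `dists`, `results`, `sample_size`,
#'   `plots` (ggplot objects `density`, `violin`, `heatmap`).
#' @export
run_compare <- function(quants, reference, pairs = NULL,
                        config = default_config()) {
  cfg <- validate_config(config)
  records <- if ("log2_ratio" %in% names(quants)) quants
             else log2_ratio(quants, cfg$pseudocount_px)
  if (!reference %in% records$condition)
    jf_config_error(sprintf("reference condition '%s' not present", reference))
  scheme <- fit_bin_scheme(records[records$condition == reference, ],
                           reference_label = reference,
                           type = cfg$quantile_type)
  ss <- min_sections(cfg$sample_size$f, cfg$sample_size$c)
  conds <- unique(records$condition)
  dists <- lapply(conds, function(cl)
    make_distribution(records[records$condition == cl, ], scheme,
                      condition_label = cl, n_min = ss$n_min))
  names(dists) <- conds
  results <- compare_conditions(dists, pairs, cfg$norm_constant,
                                mode = if (cfg$mode == "both") "pooled" else cfg$mode)
  list(records = records, scheme = scheme, dists = dists, results = results,
       sample_size = ss,
       plots = list(density = plot_ratio_density(records),
                    violin = plot_ratio_violin(records),
                    heatmap = plot_bin_heatmap(dists)))
}

#' Generate a synthetic data set on disk
#'
#' Writes one section-quant CSV per cohort (the same format the image
#' pipeline emits, so the files are drop-in inputs for [run_compare()]) plus
#' a manifest JSON recording every generating parameter and seed.
#'
#' @param specs Named list of [synthetic_cohort_spec()] objects.
#' @param out_dir Output directory (created if needed).
#' @param kinds Character vector (`"ST"`/`"organoid"`), one per spec;
#'   defaults to all `"ST"`.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(specs, out_dir, kinds = NULL) {
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    jf_config_error("'specs' must be a named list")
  if (is.null(kinds)) kinds <- rep("ST", length(specs))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(specs)) {
    rec <- gen_cohort(specs[[i]], kind = kinds[i], condition = names(specs)[i])
    f <- file.path(out_dir, paste0(names(specs)[i], "_quants.csv"))
    write.csv(cohort_as_quants(rec), f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(generator = "jsdfidelity synthetic cohort",
                   created = format(Sys.time(), tz = "UTC"),
                   cohorts = lapply(seq_along(specs), function(i)
                     c(list(name = names(specs)[i], kind = kinds[i],
                            file = basename(files[i])),
                       unclass(specs[[i]]))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
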