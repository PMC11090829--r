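test_that("section images round-trip through multi-page TIFF and validate roles", {
  img <- quant_image(list(matrix(0:24 * 10, 5, 5), matrix(1:25, 5, 5)),
                     c(k8 = 1, k14 = 2), section_id = "rt1")
  f <- withr::local_tempfile(fileext = ".tif")
  write_section_image(img, f)
  back <- read_section_image(f, c(k8 = 1, k14 = 2), section_id = "rt1")
  expect_equal(back$pixels * 1.0, img$pixels * 1.0)
  expect_equal(dim(back), c(5L, 5L, 2L))

  expect_error(read_section_image(f, c(k8 = 1, k14 = 6)),
               class = "jsdfidelity_config_error")
  expect_error(read_section_image("no/such/file.tif", c(k8 = 1)),
               class = "jsdfidelity_io_error")
  expect_error(quant_image(matrix(1, 4, 4), c(k8 = 2)),
               class = "jsdfidelity_config_error")
  expect_error(quant_image(list(matrix(1, 4, 4), matrix(1, 5, 5)),
                           c(k8 = 1, k14 = 2)),
               class = "jsdfidelity_data_error")
})

test_that("thresholding separates bimodal intensities and honours fixed values", {
  ch <- block_image(blocks = list(list(rows = 5:14, cols = 5:14, value = 200)))
  img <- quant_image(ch, c(k8 = 1))

  otsu_mask <- threshold_channel(img, "k8", method = "otsu", min_object_px = 1)
  expect_identical(otsu_mask$pixels, ch == 200)
  expect_identical(positive_area(otsu_mask), 100L)

  fixed_mask <- threshold_channel(img, "k8", method = "fixed",
                                  fixed_value = 100, min_object_px = 1)
  expect_identical(fixed_mask$pixels, ch > 100)
  expect_equal(fixed_mask$threshold_used, 100)

  expect_error(threshold_channel(img, "k14"), class = "jsdfidelity_config_error")
  expect_error(threshold_channel(img, "k8", method = "fixed"),
               class = "jsdfidelity_config_error")
  flat <- quant_image(matrix(7, 10, 10), c(k8 = 1))
  expect_error(threshold_channel(flat, "k8", method = "otsu"),
               class = "jsdfidelity_data_error")
})

test_that("small-object removal drops speckle below min_object_px", {
  ch <- block_image(blocks = list(
    list(rows = 5:14, cols = 5:14, value = 200),     # 100 px object
    list(rows = 30:30, cols = 20:22, value = 200)))  # 3 px speckle
  img <- quant_image(ch, c(k8 = 1))
  mask <- threshold_channel(img, "k8", method = "fixed", fixed_value = 100,
                            min_object_px = 10)
  expect_identical(positive_area(mask), 100L)
  expect_false(any(mask$pixels[30, 20:22]))
})

test_that("area accounting: union tissue policy and mask conservation", {
  img <- quant_image(array(0, c(40, 40, 2)), c(k8 = 1, k14 = 2))
  k8 <- matrix(FALSE, 40, 40); k8[1:10, 1:10] <- TRUE            # 100 px
  k14d <- matrix(FALSE, 40, 40); k14d[21:30, 1:5] <- TRUE        # 50 px disjoint
  q <- quantify_section(img, list(k8 = k8, k14 = k14d))
  expect_equal(q$tissue_area_px, 150)

  # overlap case: 100 + 100 - 40 overlap = 160 (pixel-set union oracle)
  k14o <- matrix(FALSE, 40, 40); k14o[1:10, 7:16] <- TRUE
  expect_equal(length(union(which(k8), which(k14o))), 160)
  q2 <- quantify_section(img, list(k8 = k8, k14 = k14o))
  expect_equal(q2$tissue_area_px, 160)
  expect_equal(q2$k8_area_px, 100)
  expect_equal(q2$k14_area_px, 100)

  # positive + negative area partitions the image
  expect_equal(positive_area(k8) + positive_area(!k8), q$image_area_px)
  expect_error(quantify_section(img, list(k8 = k8)),
               class = "jsdfidelity_config_error")
})

test_that("tiling produces a row-major grid, keeps remainders, conserves area", {
  mk <- function(h, w, kind = "ST")
    quant_image(array(seq_len(h * w * 2), c(h, w, 2)), c(k8 = 1, k14 = 2),
                section_id = "par", source_kind = kind)

  tiles <- tile_image(mk(1000, 1000), 250)
  expect_length(tiles, 16)
  expect_true(all(vapply(tiles, function(t) all(dim(t)[1:2] == c(250, 250)),
                         logical(1))))

  # grid-arithmetic oracle: 1100 x 1000 at side 250 -> 5 x 4 = 20 tiles,
  # last row of 4 tiles is 100 x 250
  tiles2 <- tile_image(mk(1100, 1000), 250)
  expect_length(tiles2, 20)
  hs <- vapply(tiles2, function(t) dim(t)[1], integer(1))
  expect_equal(sum(hs == 100), 4)
  areas <- vapply(tiles2, function(t) prod(dim(t)[1:2]), numeric(1))
  expect_equal(sum(areas), 1100 * 1000)
  # pixel content partitions the parent exactly
  expect_equal(sum(vapply(tiles2, function(t) sum(t$pixels[, , 1]), numeric(1))),
               sum(mk(1100, 1000)$pixels[, , 1]))

  org <- mk(1000, 1000, kind = "organoid")
  expect_identical(tile_image(org, 250), list(org))
  expect_warning(small <- tile_image(mk(100, 100), 500), "untiled")
  expect_length(small, 1)
})

test_that("tile masks are additive across the grid", {
  spec <- synthetic_image_spec(height = 300, width = 300, k8_area_frac = 0.2,
                               k14_area_frac = 0.1, seed = 42)
  g <- gen_section_image(spec, source_kind = "ST")
  tiles <- tile_image(g$image, 100)
  total_k8 <- sum(vapply(tiles, function(t) {
    m <- threshold_channel(t, "k8", method = "fixed", fixed_value = 100,
                           min_object_px = 1)
    positive_area(m)
  }, numeric(1)))
  expect_equal(total_k8, sum(g$masks$k8))
})

test_that("tissue-fraction filter is strict at the 5% boundary", {
  q <- tibble::tibble(section_id = c("a", "b", "c"),
                      image_area_px = 1000,
                      tissue_area_px = c(40, 50, 60))  # 4%, 5%, 6%
  suppressMessages(kept <- filter_tiles(q, 0.05))
  expect_identical(kept$section_id, "c")
  expect_setequal(attr(kept, "dropped"), c("a", "b"))
})

test_that("nucleus counting respects the component-size window", {
  ch <- matrix(0, 60, 80)
  centers <- cbind(r = c(10, 10, 10, 30, 30, 30, 50), c = c(10, 30, 50, 10, 30, 50, 70))
  for (i in seq_len(nrow(centers)))
    ch[centers[i, 1] + (-3:3), centers[i, 2] + (-3:3)] <- 200  # 49 px each
  img <- quant_image(ch, c(nuclear = 1))
  expect_equal(count_positive_nuclei(img, "nuclear", min_nucleus_px = 10,
                                     max_nucleus_px = 100), 7)

  # component-labelling oracle: shrink 2 nuclei below the window
  ch2 <- ch
  ch2[centers[1, 1] + (-3:3), centers[1, 2] + (-3:3)] <- 0
  ch2[centers[1, 1], centers[1, 2] + 0:1] <- 200               # 2 px
  ch2[centers[2, 1] + (-3:3), centers[2, 2] + (-3:3)] <- 0
  ch2[centers[2, 1] + 0:1, centers[2, 2] + 0:1] <- 200         # 4 px
  img2 <- quant_image(ch2, c(nuclear = 1))
  expect_equal(count_positive_nuclei(img2, "nuclear", min_nucleus_px = 10,
                                     max_nucleus_px = 100), 5)

  blank <- quant_image(matrix(0, 20, 20), c(nuclear = 1))
  expect_equal(count_positive_nuclei(blank, "nuclear"), 0L)
  expect_error(count_positive_nuclei(img, "k14"),
               class = "jsdfidelity_config_error")
})

test_that("quantification is deterministic for identical inputs", {
  spec <- synthetic_image_spec(noise_sigma = 15, seed = 5)
  g <- gen_section_image(spec)
  run <- function() {
    masks <- list(k8 = threshold_channel(g$image, "k8"),
                  k14 = threshold_channel(g$image, "k14"))
    quantify_section(g$image, masks)
  }
  expect_identical(run(), run())
})
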