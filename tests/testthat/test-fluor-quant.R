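flat_mask <- function(rows, cols, H = 20, W = 20, px = 1) {
  g <- matrix(FALSE, H, W)
  g[rows, cols] <- TRUE
  raster_mask(g, px)
}

test_that("mfi is the arithmetic mean over nerve-in-roi pixels", {
  img <- matrix(0, 20, 20)
  img[5, 1:10] <- 200
  ch <- channel_image(img, "TrkA", 1)
  nerve <- flat_mask(5, 1:10)
  roi <- flat_mask(1:20, 1:20)
  rec <- mfi(ch, nerve, roi, "epidermis")
  expect_equal(rec$mfi, 200)
  expect_equal(rec$pixel_count, 10L)

  img[5, 1:5] <- 100
  img[5, 6:10] <- 300
  rec2 <- mfi(channel_image(img, "TrkA", 1), nerve, roi, "epidermis")
  expect_equal(rec2$mfi, 200)
})

test_that("mfi ignores intensity outside the nerve-roi intersection", {
  set.seed(11)
  img <- matrix(runif(400, 0, 4000), 20, 20)
  nerve <- flat_mask(3:6, 3:6)
  roi <- flat_mask(1:10, 1:10)
  base <- mfi(channel_image(img, "GAP43", 1), nerve, roi)$mfi
  img2 <- img
  img2[11:20, ] <- 65535  # blazing pixels outside the roi
  img2[1, 1] <- 65535     # in roi but outside nerve
  expect_equal(mfi(channel_image(img2, "GAP43", 1), nerve, roi)$mfi, base)
})

test_that("empty nerve-roi intersection yields missing, never zero", {
  img <- matrix(100, 20, 20)
  nerve <- flat_mask(1:2, 1:2)
  roi <- flat_mask(10:12, 10:12)
  rec <- mfi(channel_image(img, "CGRP", 1), nerve, roi)
  expect_true(is.na(rec$mfi))
  expect_equal(rec$pixel_count, 0L)

  ref <- mfi(channel_image(img, "PGP9.5", 1), nerve, roi)
  out <- normalized_mfi(rec, ref)
  expect_true(is.na(out$normalized_mfi))
})

test_that("mfi recovers the planted fiber intensity on generated sections", {
  s <- generate_section(small_section_spec(seed = 21))
  all_roi <- raster_mask(matrix(TRUE, 256, 320), s$pixel_size_um)
  rec <- mfi(s$channels[["PGP9.5"]], s$masks$nerve, all_roi)
  expect_gte(rec$pixel_count, 400L)
  se <- 50 / sqrt(rec$pixel_count)
  expect_lt(abs(rec$mfi - s$truth$fiber_mean[["PGP9.5"]]), 3 * se + 0.5)
})

test_that("normalized mfi is a plain ratio, invariant to intensity scaling", {
  img <- matrix(0, 20, 20)
  img[5, 1:10] <- 600
  ref_img <- matrix(0, 20, 20)
  ref_img[5, 1:10] <- 200
  nerve <- flat_mask(5, 1:10)
  roi <- flat_mask(1:20, 1:20)

  t_rec <- mfi(channel_image(img, "TrkA", 1), nerve, roi, "epidermis")
  r_rec <- mfi(channel_image(ref_img, "PGP9.5", 1), nerve, roi, "epidermis")
  out <- normalized_mfi(t_rec, r_rec)
  expect_equal(out$normalized_mfi, 3.0)
  expect_equal(out$normalized_to, "PGP9.5")

  # scale both channels by k: MFIs scale, ratio unchanged
  k <- 7.3
  t2 <- mfi(channel_image(img * k, "TrkA", 1), nerve, roi, "epidermis")
  r2 <- mfi(channel_image(ref_img * k, "PGP9.5", 1), nerve, roi, "epidermis")
  expect_equal(t2$mfi, k * t_rec$mfi)
  expect_equal(normalized_mfi(t2, r2)$normalized_mfi, 3.0)

  expect_equal(normalized_mfi(t_rec, t_rec)$normalized_mfi, 1.0)

  zero_ref <- mfi(channel_image(matrix(0, 20, 20), "PGP9.5", 1), nerve, roi, "epidermis")
  flagged <- normalized_mfi(t_rec, zero_ref)
  expect_true(is.na(flagged$normalized_mfi))
  expect_match(attr(flagged, "flag"), "reference")

  r_other <- mfi(channel_image(ref_img, "PGP9.5", 1), nerve, roi, "dermis")
  expect_error(normalized_mfi(t_rec, r_other), "same ROI")
})

test_that("area_ratio behaves on nested, identical, disjoint and empty masks", {
  total <- flat_mask(1:10, 1:10)
  marker <- flat_mask(1:10, 1:1)
  roi <- flat_mask(1:20, 1:20)
  expect_equal(area_ratio(marker, total, roi), 0.1)
  expect_equal(area_ratio(total, total, roi), 1.0)

  small_roi <- flat_mask(1:10, 1:10)
  off_roi <- flat_mask(15:20, 15:20)
  expect_equal(area_ratio(off_roi, total, small_roi), 0)
  # total mask absent from the roi: ratio undefined
  expect_true(is.na(area_ratio(marker, flat_mask(19, 19), small_roi)))

  # marker outside total flags a segmentation inconsistency
  expect_warning(area_ratio(flat_mask(1:12, 1:10), total, roi), "> 1")

  # monotone under marker inclusion
  bigger <- flat_mask(1:10, 1:3)
  expect_gte(area_ratio(bigger, total, roi), area_ratio(marker, total, roi))
})
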