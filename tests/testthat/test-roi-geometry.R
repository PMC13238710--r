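test_that("expand_mask handles identity, empty and exact lattice-disk cases", {
  m <- matrix(FALSE, 21, 21)
  m[11, 11] <- TRUE
  mask <- raster_mask(m, 1)

  expect_identical(expand_mask(mask, 0)$grid, mask$grid)

  empty <- raster_mask(matrix(FALSE, 21, 21), 1)
  expect_identical(expand_mask(empty, 50)$grid, empty$grid)

  # closed Euclidean ball of radius 5 px around one pixel: 81 lattice points
  disk <- expand_mask(mask, 5)
  expect_equal(sum(disk$grid), 81)
  expect_identical(disk$grid, oracle_expand(m, 5))

  expect_error(expand_mask(mask, -1), ">= 0")
})

test_that("expand_mask distance is physical: pixel size rescales the radius", {
  m <- matrix(FALSE, 21, 21)
  m[11, 11] <- TRUE
  # 5 um at 0.61 um/px is 8.196... px; oracle agrees
  got <- expand_mask(raster_mask(m, 0.61), 5)
  expect_identical(got$grid, oracle_expand(m, 5 / 0.61))
})

test_that("expand_mask matches the brute-force oracle on random masks and is monotone", {
  set.seed(42)
  for (i in 1:15) {
    g <- matrix(runif(32 * 32) < 0.05, 32, 32)
    mask <- raster_mask(g, 1)
    for (r in c(1, 3, 7.5)) {
      expect_identical(expand_mask(mask, r)$grid, oracle_expand(g, r),
                       label = sprintf("mask %d radius %g", i, r))
    }
    small <- expand_mask(mask, 2)
    big <- expand_mask(mask, 6)
    expect_true(all(big$grid[small$grid]))
  }
})

test_that("derive_subepidermis extracts the 50 um dermal band", {
  m <- band_masks(epi_rows = 10L, total_rows = 100L, width = 100L, px = 1)
  sub <- derive_subepidermis(m$epidermis, m$dermis, 50)
  # vertical geometry: exactly rows 11..60, full width
  expect_equal(mask_area(sub), 5000)
  expected <- matrix(FALSE, 100, 100)
  expected[11:60, ] <- TRUE
  expect_identical(sub$grid, expected)

  # never intersects epidermis, never exceeds dermis
  expect_equal(sum(sub$grid & m$epidermis$grid), 0)
  expect_true(all(m$dermis$grid[sub$grid]))
})

test_that("derive_subepidermis degenerate and error cases", {
  m <- band_masks()
  empty_derm <- raster_mask(matrix(FALSE, 100, 100), 1)
  expect_equal(sum(derive_subepidermis(m$epidermis, empty_derm, 50)$grid), 0)
  expect_equal(sum(derive_subepidermis(m$epidermis, m$dermis, 0)$grid), 0)

  overlapping <- raster_mask(rbind(matrix(TRUE, 11, 100), matrix(FALSE, 89, 100)), 1)
  expect_error(derive_subepidermis(overlapping, m$dermis), "overlap")
  off_scale <- raster_mask(m$dermis$grid, 2)
  expect_error(derive_subepidermis(m$epidermis, off_scale), "pixel size")
})

test_that("resolve_mask_overlap reassigns overlap pixels to the preferred class", {
  m <- band_masks()
  epi_big <- raster_mask(rbind(matrix(TRUE, 12, 100), matrix(FALSE, 88, 100)), 1)
  fixed <- resolve_mask_overlap(epi_big, m$dermis)
  expect_equal(fixed$n_overlap, 200)
  expect_equal(sum(fixed$epidermis$grid & fixed$dermis$grid), 0)
  expect_error(basement_membrane(epi_big, m$dermis), "overlap")
  expect_silent(basement_membrane(fixed$epidermis, fixed$dermis))
})

test_that("basement membrane of a straight interface has length width x pixel size", {
  m <- band_masks(epi_rows = 10L, total_rows = 100L, width = 100L, px = 1)
  bm <- basement_membrane(m$epidermis, m$dermis)
  expect_equal(bm$length_mm, 0.100)
  expect_equal(length(bm$polylines), 1L)
  # the band is the bottom epidermal row
  expect_equal(which(bm$band$grid, arr.ind = TRUE)[, "row"], rep(10L, 100),
               ignore_attr = TRUE)
})

test_that("membrane length is invariant under 90-degree rotation and translation", {
  m <- band_masks(epi_rows = 10L, total_rows = 80L, width = 60L, px = 1)
  bm <- basement_membrane(m$epidermis, m$dermis)

  rot <- function(g) t(g)[ncol(g):1, , drop = FALSE]
  bm_rot <- basement_membrane(raster_mask(rot(m$epidermis$grid), 1),
                              raster_mask(rot(m$dermis$grid), 1))
  expect_equal(bm_rot$length_mm, bm$length_mm)

  # translate both masks down by 7 rows inside a larger frame
  big <- function(g) {
    out <- matrix(FALSE, 100, 60)
    out[8:(7 + nrow(g)), ] <- g
    out
  }
  bm_tr <- basement_membrane(raster_mask(big(m$epidermis$grid), 1),
                             raster_mask(big(m$dermis$grid), 1))
  expect_equal(bm_tr$length_mm, bm$length_mm)
})

test_that("membrane length scales linearly with pixel size", {
  m1 <- band_masks(px = 1)
  m061 <- band_masks(px = 0.61)
  l1 <- basement_membrane(m1$epidermis, m1$dermis)$length_mm
  l061 <- basement_membrane(m061$epidermis, m061$dermis)$length_mm
  expect_equal(l061, 0.61 * l1)
})

test_that("non-adjacent epidermis and dermis have no membrane", {
  epi <- matrix(FALSE, 50, 50); epi[1:5, 1:5] <- TRUE
  derm <- matrix(FALSE, 50, 50); derm[40:50, 40:50] <- TRUE
  expect_error(
    basement_membrane(raster_mask(epi, 1), raster_mask(derm, 1)),
    "no basement membrane"
  )
})

test_that("mask_area counts foreground pixels in physical units", {
  g <- matrix(FALSE, 10, 10)
  g[1, 1:10] <- TRUE
  expect_equal(mask_area(raster_mask(g, 1)), 10)
  expect_equal(mask_area(raster_mask(g, 0.61)), 10 * 0.61^2)

  roi <- matrix(FALSE, 10, 10)
  roi[5:10, ] <- TRUE
  expect_equal(mask_area(raster_mask(g, 1), raster_mask(roi, 1)), 0)
})

test_that("roi_set ties the pieces together with valid invariants", {
  m <- band_masks(epi_rows = 10L, total_rows = 120L, width = 80L, px = 0.61)
  roi <- roi_set(m$epidermis, m$dermis, distance_um = 50)
  expect_s3_class(roi, "roi_set")
  expect_equal(sum(roi$subepidermis$grid & roi$epidermis$grid), 0)
  expect_true(all(roi$dermis$grid[roi$subepidermis$grid]))
  expect_gt(roi$membrane$length_mm, 0)
})
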