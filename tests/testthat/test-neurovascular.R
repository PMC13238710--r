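disk_mask <- function(cr, cc, radius_px, H = 120, W = 120, px = 1) {
  g <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    d2 <- (r - cr)^2 + (seq_len(W) - cc)^2
    g[r, d2 <= radius_px^2 + 1e-9] <- TRUE
  }
  raster_mask(g, px)
}

test_that("nerve proximity region is the 5 um closed-ball expansion", {
  empty <- raster_mask(matrix(FALSE, 50, 50), 1)
  expect_equal(sum(nerve_proximity_region(empty)$grid), 0)

  one <- raster_mask({g <- matrix(FALSE, 50, 50); g[25, 25] <- TRUE; g}, 1)
  expect_equal(sum(nerve_proximity_region(one, 5)$grid), 81)

  r5 <- nerve_proximity_region(one, 5)
  r10 <- nerve_proximity_region(one, 10)
  expect_true(all(r10$grid[r5$grid]))
  expect_error(nerve_proximity_region(one, 0), "positive")
})

test_that("interaction area respects geometric separation and containment", {
  H <- 120; W <- 120
  derm <- raster_mask(matrix(TRUE, H, W), 1)
  fiber <- raster_mask({g <- matrix(FALSE, H, W); g[, 20] <- TRUE; g}, 1)

  # vessel center 20 px from the fiber line, radius 3: nearest point 17 > 5
  far <- disk_mask(60, 40, 3)
  vm <- interaction_area(far, fiber, derm, 5)
  expect_equal(vm$interaction_area_um2, 0)
  expect_equal(vm$vessel_area_um2, mask_area(far))

  # vessel fully inside the proximity region: interaction = vessel area
  near <- disk_mask(60, 21, 2)
  vm2 <- interaction_area(near, fiber, derm, 5)
  expect_equal(vm2$interaction_area_um2, vm2$vessel_area_um2)

  # vessel centered on a fiber pixel: the whole disk interacts
  centered <- disk_mask(60, 20, 4)
  vm3 <- interaction_area(centered, fiber, derm, 5)
  expect_equal(vm3$interaction_area_um2, mask_area(centered))

  expect_error(
    interaction_area(far, fiber, raster_mask(matrix(FALSE, H, W), 1), 5),
    "empty"
  )
})

test_that("epidermal vessel pixels are excluded from both areas", {
  H <- 60; W <- 60
  derm_g <- matrix(FALSE, H, W); derm_g[31:60, ] <- TRUE
  derm <- raster_mask(derm_g, 1)
  fiber <- raster_mask({g <- matrix(FALSE, H, W); g[31:60, 30] <- TRUE; g}, 1)
  # vessel straddles the epidermis/dermis boundary
  vessel <- disk_mask(31, 30, 4, H, W)
  vm <- interaction_area(vessel, fiber, derm, 5)
  in_dermis <- sum(vessel$grid & derm_g)
  expect_equal(vm$vessel_area_um2, in_dermis)
  expect_lte(vm$interaction_area_um2, vm$vessel_area_um2)
})

test_that("interaction area is monotone in radius and vessel inclusion", {
  H <- 120; W <- 120
  derm <- raster_mask(matrix(TRUE, H, W), 1)
  fiber <- raster_mask({g <- matrix(FALSE, H, W); g[, 20] <- TRUE; g}, 1)
  vessel <- disk_mask(60, 27, 4)
  a5 <- interaction_area(vessel, fiber, derm, 5)$interaction_area_um2
  a10 <- interaction_area(vessel, fiber, derm, 10)$interaction_area_um2
  expect_gte(a10, a5)

  sub_vessel <- disk_mask(60, 27, 2)
  a_sub <- interaction_area(sub_vessel, fiber, derm, 5)$interaction_area_um2
  expect_gte(a5, a_sub)
})

test_that("rigid translation of vessels and nerves leaves areas unchanged", {
  H <- 120; W <- 120
  derm <- raster_mask(matrix(TRUE, H, W), 1)
  fiber_g <- matrix(FALSE, H, W); fiber_g[30:90, 40] <- TRUE
  vessel_g <- disk_mask(60, 47, 3)$grid
  base <- interaction_area(raster_mask(vessel_g, 1), raster_mask(fiber_g, 1), derm, 5)

  shift <- function(g, dr, dc) {
    out <- matrix(FALSE, H, W)
    src_r <- seq_len(H - dr); src_c <- seq_len(W - dc)
    out[src_r + dr, src_c + dc] <- g[src_r, src_c]
    out
  }
  moved <- interaction_area(raster_mask(shift(vessel_g, 11, 17), 1),
                            raster_mask(shift(fiber_g, 11, 17), 1), derm, 5)
  expect_equal(moved$vessel_area_um2, base$vessel_area_um2)
  expect_equal(moved$interaction_area_um2, base$interaction_area_um2)
})

test_that("planted distance sweep: interaction is positive iff the gap is within radius", {
  H <- 120; W <- 120; px <- 1
  derm <- raster_mask(matrix(TRUE, H, W), px)
  fiber <- raster_mask({g <- matrix(FALSE, H, W); g[, 20] <- TRUE; g}, px)
  r_vessel <- 3
  for (d in c(4, 6, 7.5, 9, 12, 15)) {
    vessel <- disk_mask(60, 20 + d, r_vessel)
    got <- interaction_area(vessel, fiber, derm, 5)$interaction_area_um2
    # nearest vessel pixel sits ~ d - r_vessel from the fiber (1 px discretization)
    if (d - r_vessel <= 5 - 1) {
      expect_gt(got, 0, label = sprintf("d = %g", d))
    }
    if (d - r_vessel > 5 + 1) {
      expect_equal(got, 0, label = sprintf("d = %g", d))
    }
  }
})
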