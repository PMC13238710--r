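test_that("sections are bit-identical for identical seeds, distinct otherwise", {
  s1 <- generate_section(small_section_spec(seed = 4))
  s2 <- generate_section(small_section_spec(seed = 4))
  expect_identical(s1, s2)
  s3 <- generate_section(small_section_spec(seed = 5))
  expect_false(identical(s1$masks$nerve$grid, s3$masks$nerve$grid))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(100)
  before <- runif(3)
  set.seed(100)
  invisible(generate_section(small_section_spec(seed = 9)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("planted crossing counts are recovered exactly by the pipeline", {
  for (seed in c(1, 7, 19)) {
    for (n in c(0L, 3L, 6L)) {
      s <- generate_section(small_section_spec(
        seed = seed, n_crossing_fibers = n,
        vessels = data.frame(radius_um = 3, target_dist_um = 10)
      ))
      expect_equal(s$truth$crossing_count, n)
      roi <- roi_set(s$masks$epidermis, s$masks$dermis)
      expect_equal(count_crossings(s$masks$nerve, roi)$count, n,
                   label = sprintf("seed %d, n %d", seed, n))
    }
  }
})

test_that("epidermis and dermis partition the tissue without overlap", {
  s <- generate_section(small_section_spec(seed = 2))
  expect_equal(sum(s$masks$epidermis$grid & s$masks$dermis$grid), 0)
  # CGRP+ fibers are a subset of all nerve fibers
  expect_true(all(s$masks$nerve$grid[s$masks$nerve_cgrp$grid]))
  expect_true(all(s$masks$dermis$grid[s$masks$vessels$grid]))
})

test_that("infeasible section specs are rejected", {
  expect_error(
    generate_section(section_spec(width_px = 64, height_px = 256,
                                  n_crossing_fibers = 40, seed = 1)),
    "interface too short"
  )
  expect_error(
    generate_section(section_spec(width_px = 256, height_px = 64,
                                  epi_depth_um = 50, seed = 1)),
    "infeasible"
  )
})

test_that("vessels land within one pixel of their planted fiber distance", {
  s <- generate_section(small_section_spec(
    seed = 13,
    vessels = data.frame(radius_um = c(3, 3, 4), target_dist_um = c(4, 12, 25))
  ))
  err_px <- abs(s$truth$vessel_actual_dist_um - s$truth$vessel_target_dist_um) /
    s$pixel_size_um
  expect_true(all(err_px <= 1))
})

test_that("membrane length truth matches the pipeline estimate", {
  # straight interface: the analytic length is exact
  s <- generate_section(small_section_spec(seed = 3, undulation_amp_um = 0))
  roi <- roi_set(s$masks$epidermis, s$masks$dermis)
  expect_equal(roi$membrane$length_mm, s$truth$membrane_length_mm,
               tolerance = 0.02)
  # undulating interface: digital curve length tracks the arc length
  s2 <- generate_section(small_section_spec(seed = 3))
  roi2 <- roi_set(s2$masks$epidermis, s2$masks$dermis)
  expect_equal(roi2$membrane$length_mm, s2$truth$membrane_length_mm,
               tolerance = 0.10)
})

test_that("threshold segmentation recovers the planted nerve mask", {
  s <- generate_section(small_section_spec(seed = 6))
  seg <- threshold_segment(s$channels[["PGP9.5"]], 1000)
  truth <- s$masks$nerve$grid
  jaccard <- sum(seg$grid & truth) / sum(seg$grid | truth)
  expect_gte(jaccard, 0.9)

  expect_equal(sum(threshold_segment(s$channels[["PGP9.5"]], 0)$grid),
               length(truth))
  expect_equal(sum(threshold_segment(s$channels[["PGP9.5"]], 65535)$grid), 0)
  expect_error(threshold_segment(s$channels[["PGP9.5"]], 1e6), "bit-depth")
})

test_that("true interaction area agrees with the pipeline measurement", {
  s <- generate_section(small_section_spec(seed = 17))
  vm <- interaction_area(s$masks$vessels, s$masks$nerve, s$masks$dermis, 5)
  expect_equal(vm$interaction_area_um2, s$truth$interaction_area_um2)
  expect_equal(vm$vessel_area_um2, s$truth$vessel_area_um2)
})

test_that("cohort generation is reproducible and validates group sizes", {
  spec <- cohort_spec(n_control = 3, n_painless = 3, n_painful = 3,
                      section_template = small_section_spec(seed = 1),
                      seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$ct, c2$ct)
  expect_equal(nrow(c1$subjects), 9)
  expect_equal(length(c1$image_specs), 18)

  expect_error(cohort_spec(n_control = 2), "at least 3")
  expect_error(cohort_spec(trka_multiplier = 0), "> 0")
})

test_that("cohort tables carry the planted structure", {
  spec <- cohort_spec(n_control = 4, n_painless = 4, n_painful = 4,
                      section_template = small_section_spec(seed = 1),
                      seed = 21)
  ch <- generate_cohort(spec)
  # painful subjects report pain, controls do not
  expect_true(all(ch$clinical$nrs$nrs_max_week[ch$clinical$nrs$group == "painful"] >= 4))
  expect_true(all(ch$clinical$nrs$nrs_max_week[ch$clinical$nrs$group == "control"] == 0))
  # Ct table: triplicates for three genes per subject
  expect_equal(nrow(ch$ct), 12 * 3 * 3)
  expect_true(all(ch$ct$ct > 0 & ch$ct$ct <= 40))
  # per-subject image pair: floor/ceiling of the subject rate
  counts <- vapply(ch$image_specs, function(e) e$spec$n_crossing_fibers, integer(1))
  odd <- seq(1L, length(counts) - 1L, by = 2L)
  expect_true(all(abs(counts[odd + 1L] - counts[odd]) <= 1))
})
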