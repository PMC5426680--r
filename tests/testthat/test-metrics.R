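toy_grid <- function(values, spacing = c(1, 1, 1)) {
  dose_grid(values, spacing, origin = c(0, 0, 0), frame = "phantom")
}

test_that("Dq follows the at-least-q% convention by exact sorting", {
  d <- 1:100
  expect_equal(dose_at_volume(d, 95), 6)   # >= 6 received by 95 voxels
  expect_equal(dose_at_volume(d, 5), 96)   # >= 96 received by 5 voxels
  expect_equal(dose_at_volume(d, 100), 1)
})

test_that("coverage normalization makes D95 equal 95% of prescription", {
  ph <- coarse_cylinder(5)
  g <- sffscan:::phantom_grid(ph, array(10, dim = ph$dim))
  res <- normalize_to_coverage(g, ph$masks$target, rx = 30)
  expect_equal(res$scale, 2.85)
  expect_equal(dose_at_volume(res$dose$values[ph$masks$target], 95), 28.5)
  # idempotent on an already-normalized plan
  again <- normalize_to_coverage(res$dose, ph$masks$target, rx = 30)
  expect_equal(again$scale, 1)

  # random positive field: exact sort-based coverage property
  set.seed(1)
  vals <- array(runif(prod(ph$dim), 1, 20), dim = ph$dim)
  res2 <- normalize_to_coverage(toy_grid(vals), ph$masks$target, rx = 30)
  n <- sum(ph$masks$target)
  frac <- mean(res2$dose$values[ph$masks$target] >= 28.5)
  expect_gte(frac, 0.95)
  expect_lte(frac, 0.95 + 1 / n)

  zero <- sffscan:::phantom_grid(ph)
  expect_error(normalize_to_coverage(zero, ph$masks$target, 30),
               "normalization error")
})

test_that("DVH is a valid cumulative histogram", {
  vals <- array(0, dim = c(2, 1, 1))
  vals[] <- c(1, 3)
  g <- toy_grid(vals)
  mask <- array(TRUE, dim = c(2, 1, 1))
  h <- dvh(g, mask, bin_width = 0.5)
  expect_equal(h$volume_fraction[h$dose == 0], 1)
  expect_equal(h$volume_fraction[h$dose == 1], 1)       # both voxels >= 1
  expect_equal(h$volume_fraction[h$dose == 2], 0.5)
  expect_equal(h$volume_fraction[h$dose == 3], 0.5)
  expect_equal(h$volume_fraction[h$dose == 3.5], 0)
  expect_true(all(diff(h$volume_fraction) <= 0))

  # Dq read from the DVH equals the sort-based percentile within one bin
  set.seed(2)
  vals <- array(runif(1000, 0, 40), dim = c(10, 10, 10))
  g <- toy_grid(vals)
  mask <- array(TRUE, dim = dim(vals))
  h <- dvh(g, mask, bin_width = 0.05)
  d95_dvh <- max(h$dose[h$volume_fraction >= 0.95])
  expect_lt(abs(d95_dvh - dose_at_volume(vals, 95)), 0.05 + 1e-9)

  expect_error(dvh(g, mask & FALSE), "empty")
})

test_that("conformity index counts qualifying patient voxels", {
  ph <- coarse_cylinder(5)
  vals <- array(0, dim = ph$dim)
  vals[ph$masks$target] <- 30
  g <- toy_grid(vals, spacing = ph$spacing)
  expect_equal(conformity_index(g, ph, rx = 30), 1)

  # hand-counted toy: also cover part of the body
  vals2 <- vals
  body_idx <- which(ph$masks$body)[1:100]
  vals2[body_idx] <- 29
  g2 <- toy_grid(vals2, spacing = ph$spacing)
  expect_equal(conformity_index(g2, ph, rx = 30),
               (sum(ph$masks$target) + 100) / sum(ph$masks$target))
  # bolus voxels are excluded from the numerator by default
  vals3 <- vals
  vals3[ph$masks$bolus] <- 30
  g3 <- toy_grid(vals3, spacing = ph$spacing)
  expect_equal(conformity_index(g3, ph, rx = 30), 1)
  expect_gt(conformity_index(g3, ph, rx = 30, include_bolus = TRUE), 1)
  # monotone non-increasing in rx
  expect_lte(conformity_index(g2, ph, rx = 32),
             conformity_index(g2, ph, rx = 30))
})

test_that("homogeneity index is D5/D95 and 1 for uniform dose", {
  ph <- coarse_cylinder(5)
  vals <- array(0, dim = ph$dim)
  vals[ph$masks$target] <- 12
  expect_equal(homogeneity_index(toy_grid(vals), ph$masks$target), 1)

  # 100-voxel target with doses 1..100: D5/D95 = 96/6 by direct count
  g <- toy_grid(array(1:100, dim = c(100, 1, 1)))
  mask <- array(TRUE, dim = c(100, 1, 1))
  expect_equal(homogeneity_index(g, mask), 96 / 6)

  set.seed(3)
  vals[ph$masks$target] <- runif(sum(ph$masks$target), 25, 35)
  expect_gte(homogeneity_index(toy_grid(vals), ph$masks$target), 1)
})

test_that("body mean dose averages the body structure only", {
  ph <- coarse_cylinder(5)
  vals <- array(0, dim = ph$dim)
  vals[ph$masks$target] <- 30
  expect_equal(body_mean_dose(toy_grid(vals), ph), 0)
  vals[ph$masks$body] <- 4
  expect_equal(body_mean_dose(toy_grid(vals), ph), 4)
})

test_that("CI and HI are invariant when dose and prescription double", {
  ph <- coarse_cylinder(5)
  set.seed(4)
  vals <- array(runif(prod(ph$dim), 0, 35), dim = ph$dim)
  g <- toy_grid(vals, spacing = ph$spacing)
  g2 <- toy_grid(2 * vals, spacing = ph$spacing)
  expect_equal(conformity_index(g, ph, 30), conformity_index(g2, ph, 60))
  expect_equal(homogeneity_index(g, ph$masks$target),
               homogeneity_index(g2, ph$masks$target))
})

test_that("normalized body mean uses the reference resolution", {
  sweep <- tibble::tibble(kind = "cylinder", radius = 5, field_size = 4,
                          dtheta = c(1, 5, 10), body_mean_gy = c(4, 4, 8))
  out <- normalized_body_mean(sweep, "dtheta", 1)
  expect_equal(out$normalized_body_mean, c(1, 1, 2))
  expect_error(normalized_body_mean(dplyr::filter(sweep, dtheta > 1),
                                    "dtheta", 1), "reference")
})
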