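test_that("separable kernel reproduces the PDD on axis", {
  p <- test_params(field_size = 2)
  pdd <- synth_pdd(p)
  profiles <- lapply(c(0.5, 1.5, 3), function(z) synth_profile(p, depth = z))
  k <- build_kernel_separable(pdd, profiles,
                              grid = kernel_grid(2, spacing = c(0.25, 0.25, 0.2),
                                                 depth = 5),
                              ssd = 60)
  ax <- sffscan:::grid_axes(k)
  i0 <- which(abs(ax[[1]]) < 1e-9)
  j0 <- which(abs(ax[[2]]) < 1e-9)
  expect_equal(k$values[i0, j0, ], approx(pdd$depth, pdd$dose, ax[[3]],
                                          rule = 2)$y)
})

test_that("top-hat profile and uniform PDD give a rectangular slab kernel", {
  z <- seq(0, 6, 0.1)
  pdd <- depth_dose(z, rep(100, length(z)), check = FALSE)
  k <- build_kernel_separable(pdd, tophat_profile(width = 2, depth = 1),
                              grid = kernel_grid(2, spacing = c(0.25, 0.25, 0.5),
                                                 depth = 4),
                              ssd = 1e7)  # effectively parallel beam
  ax <- sffscan:::grid_axes(k)
  inside <- abs(ax[[1]]) < 0.9
  outside <- abs(ax[[1]]) > 1.1
  mid <- which.min(abs(ax[[3]] - 2))
  slab <- k$values[, , mid]
  expect_true(all(slab[inside, inside] > 99))
  expect_true(all(slab[outside, ] < 1))
})

test_that("synthetic kernel matches the closed form at random voxel centers", {
  p <- test_params(field_size = 2)
  k <- build_kernel_synthetic(p, grid = kernel_grid(2, spacing = c(0.2, 0.2, 0.1),
                                                    depth = 5))
  ax <- sffscan:::grid_axes(k)
  set.seed(7)
  idx <- cbind(sample(length(ax[[1]]), 50, TRUE),
               sample(length(ax[[2]]), 50, TRUE),
               sample(length(ax[[3]]), 50, TRUE))
  got <- k$values[idx]
  want <- vapply(seq_len(50), function(i) {
    z <- ax[[3]][idx[i, 3]]
    p$output_scale * pdd_model(z, p) / 100 *
      profile_model(ax[[1]][idx[i, 1]], z, p) *
      profile_model(ax[[2]][idx[i, 2]], z, p)
  }, numeric(1))
  keep <- want > 1e-3 * max(k$values)  # below the lateral truncation cut
  expect_lt(max(abs(got[keep] - want[keep]) / pmax(want[keep], 1e-12)), 0.01)
})

test_that("the two kernel construction paths agree", {
  p <- test_params(field_size = 2)
  grid <- kernel_grid(2, spacing = c(0.25, 0.25, 0.2), depth = 5)
  ks <- build_kernel_synthetic(p, grid = grid)
  profiles <- lapply(seq(0, 5, by = 0.25),
                     function(z) synth_profile(p, depth = z))
  kp <- build_kernel_separable(synth_pdd(p, depths = seq(0, 5.4, 0.02)),
                               profiles, grid = grid, ssd = p$ssd)
  scale <- 100 / p$output_scale  # relative PDD vs unit output
  expect_lt(max(abs(ks$values * scale - kp$values)) / max(kp$values), 0.01)
})

test_that("kernel scales linearly and is reflection symmetric", {
  p <- test_params(field_size = 2, output_scale = 1)
  grid <- kernel_grid(2, spacing = c(0.5, 0.5, 0.5), depth = 4)
  k1 <- build_kernel_synthetic(p, grid = grid)
  k2 <- build_kernel_synthetic(test_params(field_size = 2, output_scale = 2),
                               grid = grid)
  expect_equal(k2$values, 2 * k1$values)
  expect_equal(k1$values, k1$values[rev(seq_len(dim(k1$values)[1])), , ])
  expect_equal(k1$values, k1$values[, rev(seq_len(dim(k1$values)[2])), ])
})

test_that("refining the kernel grid 2x and averaging back changes little", {
  p <- test_params(field_size = 2)
  k <- build_kernel_synthetic(p, grid = kernel_grid(2, spacing = c(0.5, 0.5, 0.5),
                                                    depth = 4))
  fine <- build_kernel_synthetic(p, grid = kernel_grid(2, spacing = c(0.25, 0.25, 0.25),
                                                       depth = 4))
  # average 2x2x2 fine blocks onto coarse centers (fine grid is offset so
  # pairs of fine voxels straddle each coarse center)
  ax_c <- sffscan:::grid_axes(k)
  pts <- as.matrix(expand.grid(ax_c[[1]], ax_c[[2]], ax_c[[3]]))
  avg <- sample_grid(fine, pts)
  dev <- abs(avg - as.vector(k$values)) / max(k$values)
  expect_lt(stats::quantile(dev, 0.99), 0.02)
})

test_that("z-slice energy is non-increasing beyond the shoulder for tail-free beams", {
  # for fields wide enough for lateral scatter equilibrium the slice energy
  # decays monotonically once the distal falloff starts
  p <- test_params(field_size = 4, tail_level = 0)
  k <- build_kernel_synthetic(p, grid = kernel_grid(4, spacing = c(0.25, 0.25, 0.2),
                                                    depth = 5))
  slice <- apply(k$values, 3, sum)
  ax <- sffscan:::grid_axes(k)
  after <- ax[[3]] > p$r50 - p$falloff_width + 0.2
  expect_true(all(diff(slice[after]) <= 1e-9 * max(slice)))
})

test_that("separable kernel from a single profile extends it plausibly", {
  p <- test_params(field_size = 2)
  pdd <- synth_pdd(p)
  ref <- synth_profile(p, depth = 1.2)
  k <- build_kernel_separable(pdd, ref,
                              grid = kernel_grid(2, spacing = c(0.25, 0.25, 0.2),
                                                 depth = 5), ssd = 60)
  ks <- build_kernel_synthetic(p, grid = kernel_grid(2, spacing = c(0.25, 0.25, 0.2),
                                                     depth = 5))
  # agreement is best near the reference depth and stays loose elsewhere
  ax <- sffscan:::grid_axes(k)
  iz <- which.min(abs(ax[[3]] - 1.2))
  rel_err <- abs(k$values[, , iz] - ks$values[, , iz] * 100 / p$output_scale) /
    max(ks$values[, , iz] * 100 / p$output_scale)
  expect_lt(max(rel_err), 0.03)

  expect_error(
    build_kernel_separable(pdd, list(ref, synth_profile(p, depth = 2)),
                           grid = kernel_grid(2, depth = 5), ssd = 60,
                           extrapolate = "error"),
    "range error")
})
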