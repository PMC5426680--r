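# Shared fixtures, all generated in code.

# linear-ramp depth-dose: 100% at 0 falling to 0 at `end`, optional flat tail
ramp_curve <- function(end = 4, tail = 0, step = 0.1, tail_to = end + 2) {
  z <- seq(0, tail_to, by = step)
  d <- pmax(100 * (1 - z / end), 0) + tail
  depth_dose(z, d, energy = 6, field_size = 2, foil = "SFF", ssd = 60)
}

# top-hat lateral profile of width `width`
tophat_profile <- function(width = 2, depth = 1.2, step = 0.05, span = 4) {
  x <- seq(-span, span, by = step)
  lateral_profile(x, as.numeric(abs(x) <= width / 2), depth = depth,
                  energy = 6, field_size = width, foil = "SFF", ssd = 60)
}

# small fast beam model for kernel/superposition tests
test_params <- function(field_size = 2, ...) {
  beam_preset("6mev-sff", field_size = field_size, ...)
}

# coarse cylinder used across superposition tests
coarse_cylinder <- function(radius = 5) {
  build_phantom("cylinder", radius, spacing = c(0.5, 0.5, 0.5))
}

# direct (no gridding) closed-form dose of every beam at every voxel center,
# mirroring the kernel's defined lateral extent and 0.1% truncation so the
# comparison isolates the rigid transform / resampling / accumulation
oracle_superpose <- function(params, placements, phantom,
                             half_width = params$field_size / 2 + 2,
                             truncate_at = 1e-3) {
  dims <- phantom$dim
  ax <- lapply(1:3, function(k)
    phantom$origin[k] + (seq_len(dims[k]) - 1) * phantom$spacing[k])
  pts <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
               rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
               rep(ax[[3]], each = dims[1] * dims[2]))
  total <- numeric(nrow(pts))
  zmax <- 8
  for (b in seq_len(nrow(placements))) {
    e <- as.numeric(placements[b, c("ex", "ey", "ez")])
    w <- as.numeric(placements[b, c("ux", "uy", "uz")])
    a <- c(0, 0, 0); a[which.min(abs(w))] <- 1
    u <- c(w[2] * a[3] - w[3] * a[2], w[3] * a[1] - w[1] * a[3],
           w[1] * a[2] - w[2] * a[1])
    u <- u / sqrt(sum(u^2))
    v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
           w[1] * u[2] - w[2] * u[1])
    rel <- sweep(pts, 2, e)
    z <- rel %*% w
    sel <- which(z >= 0 & z <= zmax)
    if (length(sel) == 0) next
    zs <- z[sel]
    xs <- rel[sel, , drop = FALSE] %*% u
    ys <- rel[sel, , drop = FALSE] %*% v
    # profile_model is elementwise in (x, z)
    pnx <- profile_model(xs, zs, params)
    pny <- profile_model(ys, zs, params)
    lat <- pnx * pny
    out_of_extent <- abs(xs) > half_width + 1e-6 | abs(ys) > half_width + 1e-6
    lat[out_of_extent | lat < truncate_at] <- 0
    dose <- pdd_model(zs, params) / 100 * lat
    total[sel] <- total[sel] + placements$weight[b] * dose
  }
  array(total * params$output_scale, dim = dims)
}

# mean/CV of interpolated dose on a midplane ring of radius r
ring_stats <- function(dose, r, z = 0, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  d <- sample_grid(dose, cbind(r * cos(th), r * sin(th), z))
  c(mean = mean(d), cv = stats::sd(d) / mean(d))
}
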