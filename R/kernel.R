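#' Kernel grid specification
#'
#' Beam-frame grid on which single-beam dose kernels are evaluated: voxel
#' spacing, lateral half-extent and depth extent. Defaults follow the plan
#' calculation grid (2.5 x 2.5 x 2 mm voxels), a lateral extent of
#' `field_size + lateral_margin` (4 cm margin accommodates the penumbra and
#' divergence) and 8 cm of depth, well beyond the practical range of a
#' 6 MeV beam.
#'
#' @param field_size Field side in cm.
#' @param spacing Voxel sizes `(dx, dy, dz)` in cm.
#' @param lateral_margin Extra lateral extent beyond the field, cm.
#' @param depth Depth extent, cm.
#' @return A list with `spacing`, `half_width`, `depth`.
#' @export
kernel_grid <- function(field_size, spacing = c(0.25, 0.25, 0.2),
                        lateral_margin = 4, depth = 8) {
  stopifnot(length(spacing) == 3, all(spacing > 0), depth > 0)
  list(spacing = as.numeric(spacing),
       half_width = (field_size + lateral_margin) / 2,
       depth = depth)
}

# beam-frame voxel-center axes for a kernel grid spec
kernel_axes <- function(grid) {
  nl1 <- floor(grid$half_width / grid$spacing[1])
  nl2 <- floor(grid$half_width / grid$spacing[2])
  nz <- max(2L, round(grid$depth / grid$spacing[3])) + 1L
  list(x = seq(-nl1, nl1) * grid$spacing[1],
       y = seq(-nl2, nl2) * grid$spacing[2],
       z = (seq_len(nz) - 1L) * grid$spacing[3])
}

# assemble a separable kernel from axial values and per-depth lateral shapes
assemble_kernel <- function(axial, px, py, ax, truncate_at = 1e-3,
                            meta = list()) {
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  vals <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    lat <- outer(px[, k], py[, k])
    lat[lat < truncate_at] <- 0
    vals[, , k] <- axial[k] * lat
  }
  dose_grid(vals, spacing = c(ax$x[2] - ax$x[1], ax$y[2] - ax$y[1],
                              ax$z[2] - ax$z[1]),
            origin = c(ax$x[1], ax$y[1], ax$z[1]),
            frame = "beam", meta = meta)
}

#' Synthetic single-beam dose kernel
#'
#' Evaluates the closed-form beam model directly on a beam-frame grid:
#' `D(x, y, z) = PDD(z) p(x; z) p(y; z)` with the axis-normalized lateral
#' shape of [profile_model()]. On-axis values equal the (continuous-maximum
#' normalized) depth-dose scaled by `params$output_scale`; the lateral
#' product is truncated to 0 below 0.1% of the axis value.
#'
#' @param params A [beam_model_params()] object.
#' @param grid A [kernel_grid()] spec (default derived from
#'   `params$field_size`).
#' @param ssd Source-to-surface distance in cm (defaults to `params$ssd`).
#' @return A beam-frame [dose_grid()].
#' @export
build_kernel_synthetic <- function(params, grid = NULL, ssd = params$ssd) {
  if (is.null(grid)) grid <- kernel_grid(params$field_size)
  if (ssd <= 0) stop("ssd must be > 0", call. = FALSE)
  params$ssd <- ssd
  ax <- kernel_axes(grid)
  axial <- params$output_scale * pdd_model(ax$z, params) / 100
  px <- vapply(ax$z, function(z) profile_model(ax$x, z, params),
               numeric(length(ax$x)))
  py <- vapply(ax$z, function(z) profile_model(ax$y, z, params),
               numeric(length(ax$y)))
  assemble_kernel(axial, px, py, ax,
                  meta = list(source = "synthetic",
                              field_size = params$field_size, ssd = ssd))
}

#' Separable kernel from tabulated beam data
#'
#' Reconstructs a 3D single-beam kernel as the separable product
#' `D(x, y, z) = PDD(z) p(x; z) p(y; z)`, where `p(.; z)` is the
#' axis-normalized lateral shape at depth `z` obtained from the supplied
#' profiles. With profiles at two or more depths, the shape at intermediate
#' depths is linearly interpolated between the bracketing profiles after
#' scaling their off-axis coordinates by the divergence factor
#' `(ssd + z) / (ssd + z_profile)`; outside the tabulated depth range the
#' nearest profile is used with the same scaling (`extrapolate = "clamp"`)
#' or an error is raised (`extrapolate = "error"`). With a single profile,
#' the erf-pair edge model is fitted to that profile (field width from the
#' FWHM, edge spread from the 80–20% penumbra) and carried to other depths
#' with the `sigma(z) = sigma0 + g z^1.5` growth law fitted through the
#' reference depth.
#'
#' On-axis kernel values reproduce the input depth-dose exactly; beyond the
#' deepest PDD sample the axial value is held at the last (tail) sample.
#' The lateral product is truncated below 0.1% of the axis value.
#'
#' @param pdd A [depth_dose()] curve.
#' @param profiles A [lateral_profile()] or list of them (distinct depths).
#' @param grid A [kernel_grid()] spec (default from the profile metadata
#'   field size).
#' @param ssd Source-to-surface distance in cm.
#' @param extrapolate `"clamp"` or `"error"` for depths outside the profile
#'   range.
#' @return A beam-frame [dose_grid()].
#' @export
build_kernel_separable <- function(pdd, profiles, grid = NULL, ssd = 60,
                                   extrapolate = c("clamp", "error")) {
  extrapolate <- match.arg(extrapolate)
  if (ssd <= 0) stop("ssd must be > 0", call. = FALSE)
  if (inherits(profiles, "lateral_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  depths <- vapply(profiles, attr, numeric(1), which = "depth")
  o <- order(depths)
  profiles <- profiles[o]; depths <- depths[o]
  if (is.null(grid)) {
    fs <- attr(profiles[[1]], "field_size")
    if (is.na(fs)) fs <- profile_fwhm(profiles[[1]])
    grid <- kernel_grid(fs)
  }
  ax <- kernel_axes(grid)

  # axial values: interpolate the PDD, flat continuation of the tail
  axial <- stats::approx(pdd$depth, pdd$dose, xout = ax$z, rule = 2)$y

  # axis-normalized sample interpolators, 0 outside the tabulated span
  shape_at <- lapply(profiles, function(pr) {
    axis_val <- stats::approx(pr$position, pr$dose, xout = 0)$y
    if (!is.finite(axis_val) || axis_val <= 0) {
      stop("profile has no positive on-axis value", call. = FALSE)
    }
    function(x) {
      y <- stats::approx(pr$position, pr$dose / axis_val, xout = x)$y
      y[is.na(y)] <- 0
      y
    }
  })

  single <- length(profiles) == 1L
  if (single) {
    fit <- fit_edge_model(profiles[[1]])
  }

  lat_shape <- function(x, z) {
    if (single) {
      zr <- depths[1]
      h <- fit$half_width * (ssd + z) / (ssd + zr)
      s <- max(fit$sigma0_fit + fit$growth * z^1.5, 1e-3)
      raw <- 0.5 * (erf((x + h) / (sqrt(2) * s)) -
                      erf((x - h) / (sqrt(2) * s)))
      return(raw / erf(h / (sqrt(2) * s)))
    }
    if (z <= depths[1] || z >= depths[length(depths)]) {
      if (extrapolate == "error" &&
          (z < depths[1] - 1e-9 || z > depths[length(depths)] + 1e-9)) {
        stop(sprintf(
          "range error: no profile brackets depth %.2f cm (tabulated %.2f-%.2f cm) and extrapolation is disabled",
          z, depths[1], depths[length(depths)]), call. = FALSE)
      }
      i <- if (z <= depths[1]) 1L else length(depths)
      return(shape_at[[i]](x * (ssd + depths[i]) / (ssd + z)))
    }
    hi <- findInterval(z, depths, rightmost.closed = TRUE) + 1L
    lo <- hi - 1L
    w <- (z - depths[lo]) / (depths[hi] - depths[lo])
    (1 - w) * shape_at[[lo]](x * (ssd + depths[lo]) / (ssd + z)) +
      w * shape_at[[hi]](x * (ssd + depths[hi]) / (ssd + z))
  }

  px <- vapply(ax$z, function(z) lat_shape(ax$x, z), numeric(length(ax$x)))
  py <- vapply(ax$z, function(z) lat_shape(ax$y, z), numeric(length(ax$y)))
  assemble_kernel(axial, px, py, ax,
                  meta = list(source = "separable", ssd = ssd,
                              profile_depths = depths))
}

# fit the erf-pair edge model to one measured profile: edge spread from the
# mean 80-20% penumbra, then the half-width that reproduces the measured
# FWHM under that spread (for broad penumbrae the FWHM exceeds the field)
fit_edge_model <- function(profile, sigma0_default = 0.15) {
  fwhm <- profile_fwhm(profile)
  rel <- profile$dose / max(profile$dose)
  x <- profile$position
  cross <- function(level, side) {
    imax <- which.max(rel)
    if (side == "right") {
      idx <- seq(imax, length(rel))
      j <- idx[rel[idx] < level][1]
      stats::approx(rel[c(j - 1L, j)], x[c(j - 1L, j)], xout = level)$y
    } else {
      idx <- seq_len(imax)
      j <- max(idx[rel[idx] < level])
      stats::approx(rel[c(j, j + 1L)], x[c(j, j + 1L)], xout = level)$y
    }
  }
  pen <- mean(c(cross(0.2, "right") - cross(0.8, "right"),
                cross(0.8, "left") - cross(0.2, "left")))
  sigma_ref <- pen / 1.683  # 80-20 width of an erf edge = 1.683 sigma
  erfpair_fwhm <- function(h) {
    axis <- erf(h / (sqrt(2) * sigma_ref))
    2 * stats::uniroot(function(x) {
      0.5 * (erf((x + h) / (sqrt(2) * sigma_ref)) -
               erf((x - h) / (sqrt(2) * sigma_ref))) - axis / 2
    }, interval = c(1e-6, h + 6 * sigma_ref), tol = 1e-9)$root
  }
  half_width <- stats::uniroot(function(h) erfpair_fwhm(h) - fwhm,
                               interval = c(fwhm / 20, fwhm),
                               extendInt = "upX", tol = 1e-8)$root
  zr <- attr(profile, "depth")
  growth <- max((sigma_ref - sigma0_default) / max(zr, 1e-6)^1.5, 0)
  sigma0_fit <- if (growth > 0) sigma0_default else sigma_ref
  list(half_width = half_width, sigma0_fit = sigma0_fit, growth = growth,
       sigma_ref = sigma_ref)
}
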