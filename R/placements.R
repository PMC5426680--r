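#' Scanned beam placements on a cylinder
#'
#' Enumerates surface-normal beam entry points on the bolus surface of a
#' cylindrical phantom: one placement per (scan angle, axial station). Scan
#' angles step by `dtheta` degrees around the full circumference; axial
#' stations step by `dz` cm, symmetric about the midplane, the outermost
#' stations within `dz / 2` of the phantom ends (extended by `overscan` cm
#' past each end when requested, so the scanned field can clear the target
#' edge). Directions point radially inward; weights are uniform.
#'
#' @param phantom A cylindrical [build_phantom()] object.
#' @param dtheta Angular scanning resolution in degrees. Must divide 360;
#'   otherwise it is truncated to the nearest divisor with a warning.
#' @param dz Longitudinal scanning resolution in cm (`0 < dz <= length`).
#' @param ssd Source-to-surface distance in cm (default 60).
#' @param overscan Extra axial span past each phantom end, cm (default 0).
#' @return A tibble of class `beam_placements` with columns `ex, ey, ez`
#'   (entry point, cm), `ux, uy, uz` (inward unit normal), `ssd`, `weight`.
#' @export
place_beams_cylinder <- function(phantom, dtheta, dz, ssd = 60, overscan = 0) {
  stopifnot(inherits(phantom, "phantom"))
  if (phantom$kind != "cylinder") {
    stop("phantom must be a cylinder", call. = FALSE)
  }
  if (dz <= 0) stop("dz must be > 0", call. = FALSE)
  if (dz > phantom$length) {
    stop("configuration error: dz exceeds the phantom length", call. = FALSE)
  }
  dtheta <- snap_to_divisor(dtheta)
  rb <- phantom$radius + phantom$bolus_thickness
  ang <- seq(0, 360 - dtheta, by = dtheta) * pi / 180
  half_span <- phantom$length / 2 + overscan
  ns <- floor(2 * half_span / dz) + 1L
  stations <- (seq_len(ns) - (ns + 1) / 2) * dz
  grid <- tidyr::expand_grid(theta = ang, s = stations)
  out <- tibble::tibble(
    ex = rb * cos(grid$theta), ey = rb * sin(grid$theta), ez = grid$s,
    ux = -cos(grid$theta), uy = -sin(grid$theta), uz = 0,
    ssd = ssd, weight = 1
  )
  tibble::new_tibble(out, class = "beam_placements",
                     dtheta = dtheta, dz = dz, surface_radius = rb)
}

snap_to_divisor <- function(dtheta) {
  div <- divisors_360()
  if (!(dtheta %in% div)) {
    snapped <- div[which.min(abs(div - dtheta))]
    warning(sprintf("dtheta %g does not divide 360; using %g", dtheta,
                    snapped), call. = FALSE)
    dtheta <- snapped
  }
  dtheta
}

#' Scanned beam placements on a sphere
#'
#' Latitude-ring scanning lattice with uniform surface density: polar rings
#' at colatitudes `0, dtheta, ..., 180` degrees (single placements at the
#' poles). A ring at colatitude `theta` carries
#' `n = ceiling(360 sin(theta) / dtheta)` evenly spaced beams (azimuthal
#' step `360 / n`), so rings close exactly, the arc separation between
#' neighbouring beams never exceeds the polar separation, and the beam
#' density per surface area is as uniform as the single resolution
#' parameter allows. Directions point radially inward; weights are uniform.
#'
#' @param phantom A spherical [build_phantom()] object.
#' @param dtheta Polar scanning resolution in degrees (`> 0`, dividing 180).
#' @param ssd Source-to-surface distance in cm (default 60).
#' @return A tibble of class `beam_placements` (see
#'   [place_beams_cylinder()]), with additional columns `colat` and `az`
#'   (degrees).
#' @export
place_beams_sphere <- function(phantom, dtheta, ssd = 60) {
  stopifnot(inherits(phantom, "phantom"))
  if (phantom$kind != "sphere") stop("phantom must be a sphere", call. = FALSE)
  if (dtheta <= 0) stop("dtheta must be > 0", call. = FALSE)
  rb <- phantom$radius + phantom$bolus_thickness
  colats <- seq(0, 180, by = dtheta)
  rows <- purrr::map(colats, function(th) {
    if (th %in% c(0, 180)) {
      return(tibble::tibble(colat = th, az = 0))
    }
    n <- ceiling(360 * sin(th * pi / 180) / dtheta)
    tibble::tibble(colat = th, az = (seq_len(n) - 1L) * 360 / n)
  })
  g <- dplyr::bind_rows(rows)
  thr <- g$colat * pi / 180; phr <- g$az * pi / 180
  nx <- sin(thr) * cos(phr); ny <- sin(thr) * sin(phr); nz <- cos(thr)
  out <- tibble::tibble(
    ex = rb * nx, ey = rb * ny, ez = rb * nz,
    ux = -nx, uy = -ny, uz = -nz,
    ssd = ssd, weight = 1, colat = g$colat, az = g$az
  )
  tibble::new_tibble(out, class = "beam_placements",
                     dtheta = dtheta, surface_radius = rb)
}

#' Superpose a beam kernel over scanned placements
#'
#' Accumulates a beam-frame kernel into the phantom frame: for each
#' placement a rigid transform maps the kernel (depth axis along the beam
#' direction, z = 0 at the entry point) into the phantom frame; every
#' phantom voxel center inside the transformed kernel support samples the
#' kernel trilinearly, scaled by the placement weight. Voxels outside all
#' kernel supports receive 0. Kernel and phantom voxel spacings may differ
#' (the kernel is resampled, without dose-mass renormalization).
#'
#' @param kernel A beam-frame [dose_grid()].
#' @param placements A `beam_placements` tibble (or any data frame with the
#'   same columns).
#' @param phantom A [build_phantom()] object.
#' @return A phantom-frame [dose_grid()].
#' @export
superpose <- function(kernel, placements, phantom) {
  stopifnot(inherits(kernel, "dose_grid"), inherits(phantom, "phantom"))
  if (kernel$frame != "beam") {
    stop("kernel must be in the beam frame", call. = FALSE)
  }
  need <- c("ex", "ey", "ez", "ux", "uy", "uz", "weight")
  if (!all(need %in% names(placements))) {
    stop("placements must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(placements) == 0L) return(phantom_grid(phantom))
  nrm <- sqrt(placements$ux^2 + placements$uy^2 + placements$uz^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("validation error: beam directions must be unit vectors",
         call. = FALSE)
  }
  if (any(placements$weight <= 0)) {
    stop("validation error: weights must be > 0", call. = FALSE)
  }
  pm <- as.matrix(placements[, need])
  vals <- superpose_cpp(kernel$values, dim(kernel$values), kernel$spacing,
                        kernel$origin, pm, phantom$dim, phantom$spacing,
                        phantom$origin)
  dose_grid(array(vals, dim = phantom$dim), phantom$spacing, phantom$origin,
            frame = "phantom",
            meta = list(n_beams = nrow(placements), kernel = kernel$meta))
}
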