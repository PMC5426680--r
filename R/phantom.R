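#' Voxelized cylindrical or spherical phantom
#'
#' Builds a water phantom with a 1 cm bolus wrap and a shallow target shell
#' (surface to 5 mm depth), the geometry used to emulate skin cancer on a
#' curved surface. Masks (boolean per voxel, pairwise disjoint):
#' * `target`: radial coordinate in `(radius - 0.5, radius]` cm,
#' * `bolus`:  `(radius, radius + bolus_thickness]`,
#' * `body`:   `[0, radius - 0.5]`.
#' For cylinders the radial coordinate is the distance to the long axis
#' (the grid z axis) and all masks are restricted to `|z| < length / 2`;
#' for spheres it is the distance to the center.
#'
#' @param kind `"cylinder"` or `"sphere"`.
#' @param radius Phantom radius in cm (`>= 2 * bolus_thickness`).
#' @param bolus_thickness Bolus thickness in cm (default 1).
#' @param length Cylinder length in cm (default 10; ignored for spheres).
#' @param spacing Voxel sizes `(dx, dy, dz)` in cm; the default
#'   `0.25 x 0.25 x 0.2` cm is the plan calculation grid.
#' @param extent Optional grid half-extents `(x, y, z)` in cm; must cover
#'   `radius + bolus_thickness` (and `length / 2` axially).
#' @return An object of class `phantom`: grid geometry, masks, voxel volume
#'   and the voxelized/analytic target volumes.
#' @examples
#' ph <- build_phantom("cylinder", radius = 5, spacing = c(0.5, 0.5, 0.5))
#' ph$target_volume_cc / ph$target_volume_analytic_cc
#' @export
build_phantom <- function(kind = c("cylinder", "sphere"), radius,
                          bolus_thickness = 1, length = 10,
                          spacing = c(0.25, 0.25, 0.2), extent = NULL) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, bolus_thickness > 0)
  if (radius < 2 * bolus_thickness) {
    stop("configuration error: radius must be >= 2 * bolus_thickness",
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  outer_r <- radius + bolus_thickness
  need <- if (kind == "cylinder") c(outer_r, outer_r, length / 2) else
    rep(outer_r, 3)
  if (is.null(extent)) extent <- need
  if (any(extent < need - 1e-9)) {
    stop("configuration error: grid extent ", paste(extent, collapse = "/"),
         " cm does not cover the phantom (needs ",
         paste(signif(need, 4), collapse = "/"), " cm)", call. = FALSE)
  }
  nhalf <- floor(extent / spacing)
  dims <- 2L * as.integer(nhalf) + 1L
  origin <- -nhalf * spacing
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * spacing[k])

  x2 <- ax[[1]]^2
  y2 <- ax[[2]]^2
  if (kind == "cylinder") {
    rc <- sqrt(outer(x2, y2, `+`))                       # dims[1] x dims[2]
    rc <- array(rep(rc, dims[3]), dim = dims)
    inz <- abs(ax[[3]]) < length / 2 - 1e-9
    inlen <- array(rep(inz, each = dims[1] * dims[2]), dim = dims)
  } else {
    rc <- array(0, dim = dims)
    rxy <- outer(x2, y2, `+`)
    for (k in seq_len(dims[3])) rc[, , k] <- sqrt(rxy + ax[[3]][k]^2)
    inlen <- array(TRUE, dim = dims)
  }
  target <- rc > radius - 0.5 & rc <= radius & inlen
  bolus <- rc > radius & rc <= outer_r & inlen
  body <- rc <= radius - 0.5 & inlen

  vox <- prod(spacing)
  target_analytic <- if (kind == "cylinder") {
    pi * (radius^2 - (radius - 0.5)^2) * length
  } else {
    4 / 3 * pi * (radius^3 - (radius - 0.5)^3)
  }
  structure(list(kind = kind, radius = radius,
                 bolus_thickness = bolus_thickness,
                 length = if (kind == "cylinder") length else NA_real_,
                 spacing = spacing, origin = origin, dim = dims,
                 masks = list(target = target, bolus = bolus, body = body),
                 voxel_volume_cc = vox,
                 target_volume_cc = sum(target) * vox,
                 target_volume_analytic_cc = target_analytic),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, radius %g cm, bolus %g cm%s\n", x$kind, x$radius,
              x$bolus_thickness,
              if (x$kind == "cylinder") sprintf(", length %g cm", x$length) else ""))
  cat(sprintf("  grid %d x %d x %d @ %s cm, target %0.1f cc (analytic %0.1f cc)\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 3), collapse = " x "),
              x$target_volume_cc, x$target_volume_analytic_cc))
  invisible(x)
}

# empty phantom-frame dose grid matching a phantom
phantom_grid <- function(phantom, values = NULL) {
  if (is.null(values)) values <- array(0, dim = phantom$dim)
  dose_grid(values, phantom$spacing, phantom$origin, frame = "phantom")
}
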