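#' 3D voxel dose grid
#'
#' A dose distribution on a regular 3D voxel grid. `values` is a 3D array;
#' `spacing` the voxel sizes `(dx, dy, dz)` in cm; `origin` the position (cm)
#' of the *center* of voxel `[1, 1, 1]`. `frame` is `"beam"` (z along the
#' beam axis, z = 0 at the entrance surface, central axis at x = y = 0) or
#' `"phantom"` (axes fixed to the phantom, origin at its center).
#'
#' @param values 3D numeric array, finite and `>= 0`.
#' @param spacing Length-3 numeric, all `> 0`, cm.
#' @param origin Length-3 numeric, cm.
#' @param frame `"beam"` or `"phantom"`.
#' @param meta Optional named list of provenance information.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin, frame = c("beam", "phantom"),
                      meta = list()) {
  frame <- match.arg(frame)
  if (length(dim(values)) != 3L) stop("values must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive voxel sizes", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be 3 finite coordinates", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dose values must be finite and >= 0", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 frame = frame, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s cm, %s frame, max %.4g\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              x$frame, max(x$values)))
  invisible(x)
}

# voxel-center coordinates along each axis
grid_axes <- function(g) {
  d <- dim(g$values)
  lapply(1:3, function(k) g$origin[k] + (seq_len(d[k]) - 1) * g$spacing[k])
}

#' Grid as a tibble of voxel centers
#'
#' @param x A [dose_grid()].
#' @param ... Unused.
#' @return Tibble with columns `x`, `y`, `z` (cm) and `dose`.
#' @export
as_tibble.dose_grid <- function(x, ...) {
  ax <- grid_axes(x)
  d <- dim(x$values)
  dose_vec <- as.vector(x$values)
  tibble::tibble(
    x = rep(ax[[1]], times = d[2] * d[3]),
    y = rep(rep(ax[[2]], each = d[1]), times = d[3]),
    z = rep(ax[[3]], each = d[1] * d[2]),
    dose = dose_vec
  )
}

#' Trilinear interpolation of a dose grid
#'
#' Samples grid values at arbitrary points by trilinear interpolation.
#' Points within half a voxel outside the grid are clamped to the boundary;
#' points farther out return 0.
#'
#' @param grid A [dose_grid()].
#' @param points Numeric matrix (n x 3) of coordinates in the grid's frame.
#' @return Numeric vector of interpolated values.
#' @export
sample_grid <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sample_grid_cpp(grid$values, dim(grid$values), grid$spacing, grid$origin,
                  points)
}

#' Persist / restore a dose grid as text
#'
#' The voxel array is written as a flat column of values (one per line, R
#' column-major order) next to a JSON sidecar holding dimensions, spacing,
#' origin, frame and provenance.
#'
#' @param grid A [dose_grid()].
#' @param path Base path; writes `<path>.json` and `<path>.dat`.
#' @return `write_dose_grid`: invisibly, the sidecar path.
#' @export
write_dose_grid <- function(grid, path) {
  sidecar <- paste0(path, ".json")
  dat <- paste0(path, ".dat")
  jsonlite::write_json(
    list(dim = dim(grid$values), spacing = grid$spacing, origin = grid$origin,
         frame = grid$frame, data = basename(dat), meta = grid$meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  writeLines(formatC(as.vector(grid$values), format = "g", digits = 9), dat)
  invisible(sidecar)
}

#' @rdname write_dose_grid
#' @return `read_dose_grid`: the restored [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  sidecar <- paste0(path, ".json")
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vals <- as.numeric(readLines(file.path(dirname(sidecar), info$data)))
  dose_grid(array(vals, dim = info$dim), info$spacing, info$origin,
            frame = info$frame, meta = as.list(info$meta))
}
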