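#' Depth-dose curve
#'
#' Construct a central-axis depth-dose curve. The curve is stored as a tibble
#' with columns `depth` (cm, strictly increasing) and `dose`, carrying the
#' beam metadata as attributes. Dose may be relative (percent of maximum,
#' `normalization = "relative_max100"`) or absolute (per-fluence units,
#' `normalization = "absolute"`).
#'
#' @param depth Numeric vector of depths in cm, strictly increasing, at least
#'   10 samples.
#' @param dose Numeric vector of doses, same length as `depth`, all `>= 0`.
#' @param energy Nominal beam energy in MeV.
#' @param field_size Square field side in cm, defined at the surface.
#' @param foil `"SF"` (with scattering foil) or `"SFF"` (scattering-foil-free).
#' @param ssd Source-to-surface distance in cm.
#' @param normalization `"relative_max100"` or `"absolute"`.
#' @param check If `TRUE` (default) enforce the type invariants, including
#'   that the sampled range extends beyond the distal 50% crossing.
#' @return A tibble of class `depth_dose`.
#' @examples
#' z <- seq(0, 5, 0.1)
#' dd <- depth_dose(z, 100 * exp(-((z - 1.2) / 1.2)^2), energy = 6,
#'                  field_size = 2, foil = "SFF", ssd = 60)
#' r50(dd)
#' @export
depth_dose <- function(depth, dose, energy = NA_real_, field_size = NA_real_,
                       foil = c("SFF", "SF"), ssd = NA_real_,
                       normalization = c("relative_max100", "absolute"),
                       check = TRUE) {
  foil <- match.arg(foil)
  normalization <- match.arg(normalization)
  x <- tibble::tibble(depth = as.numeric(depth), dose = as.numeric(dose))
  x <- tibble::new_tibble(x, class = "depth_dose",
                          energy = energy, field_size = field_size,
                          foil = foil, ssd = ssd, normalization = normalization)
  if (check) validate_depth_dose(x)
  x
}

validate_depth_dose <- function(x) {
  if (nrow(x) < 10L) {
    stop("depth-dose curve needs at least 10 samples, got ", nrow(x),
         call. = FALSE)
  }
  if (any(!is.finite(x$depth)) || any(diff(x$depth) <= 0)) {
    stop("format error in column 'depth': depths must be finite and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(x$dose)) || any(x$dose < 0)) {
    stop("format error in column 'dose': doses must be finite and >= 0",
         call. = FALSE)
  }
  rel <- 100 * x$dose / max(x$dose)
  imax <- which.max(rel)
  if (!any(rel[seq(imax, nrow(x))] < 50)) {
    stop("sampled depth range must extend beyond the distal 50% crossing",
         call. = FALSE)
  }
  invisible(x)
}

#' Off-axis lateral profile
#'
#' Construct an off-axis dose profile at a stated depth. Stored as a tibble
#' with columns `position` (cm off-axis, strictly increasing, spanning both
#' sides of the central axis) and `dose`.
#'
#' @param position Numeric vector of off-axis positions in cm.
#' @param dose Numeric vector of doses, `>= 0`.
#' @param depth Depth of the profile plane in cm.
#' @inheritParams depth_dose
#' @return A tibble of class `lateral_profile`.
#' @export
lateral_profile <- function(position, dose, depth, energy = NA_real_,
                            field_size = NA_real_, foil = c("SFF", "SF"),
                            ssd = NA_real_,
                            normalization = c("relative_max100", "absolute"),
                            check = TRUE) {
  foil <- match.arg(foil)
  normalization <- match.arg(normalization)
  x <- tibble::tibble(position = as.numeric(position), dose = as.numeric(dose))
  x <- tibble::new_tibble(x, class = "lateral_profile",
                          depth = depth, energy = energy,
                          field_size = field_size, foil = foil, ssd = ssd,
                          normalization = normalization)
  if (check) validate_lateral_profile(x)
  x
}

validate_lateral_profile <- function(x) {
  if (any(!is.finite(x$position)) || any(diff(x$position) <= 0)) {
    stop("format error in column 'position': positions must be finite and strictly increasing",
         call. = FALSE)
  }
  if (min(x$position) >= 0 || max(x$position) <= 0) {
    stop("profile positions must span both sides of the central axis",
         call. = FALSE)
  }
  if (any(!is.finite(x$dose)) || any(x$dose < 0)) {
    stop("format error in column 'dose': doses must be finite and >= 0",
         call. = FALSE)
  }
  invisible(x)
}

curve_meta <- function(x) {
  a <- attributes(x)
  a[intersect(names(a), c("depth", "energy", "field_size", "foil", "ssd",
                          "normalization"))]
}

#' @export
print.depth_dose <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf("<depth_dose> %s MeV %s, %g x %g cm field, SSD %s cm, %s\n",
              format(m$energy), m$foil, m$field_size, m$field_size,
              format(m$ssd), m$normalization))
  NextMethod()
}

#' @export
print.lateral_profile <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf("<lateral_profile> depth %g cm, %s MeV %s, %g x %g cm field, SSD %s cm\n",
              m$depth, format(m$energy), m$foil, m$field_size, m$field_size,
              format(m$ssd)))
  NextMethod()
}

# Keep class/attributes through dplyr-style subsetting of the columns we own.
#' @export
`[.depth_dose` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("depth", "dose") %in% names(out))) {
    attributes(out)[names(curve_meta(x))] <- curve_meta(x)
    class(out) <- class(x)
  }
  out
}

#' @export
`[.lateral_profile` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("position", "dose") %in% names(out))) {
    attributes(out)[names(curve_meta(x))] <- curve_meta(x)
    class(out) <- class(x)
  }
  out
}

# relative dose in percent of the curve maximum
rel_dose <- function(x) 100 * x$dose / max(x$dose)
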