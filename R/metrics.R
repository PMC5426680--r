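#' Dose at volume (Dq)
#'
#' The smallest dose `d` such that at least `q`% of the voxels receive at
#' least `d`, evaluated by exact voxel sorting (not from a binned DVH).
#'
#' @param doses Numeric vector of voxel doses.
#' @param q Volume percentage in `(0, 100]`.
#' @return Dose in the input units.
#' @export
dose_at_volume <- function(doses, q) {
  stopifnot(length(doses) > 0, q > 0, q <= 100)
  sort(doses, decreasing = TRUE)[ceiling(q / 100 * length(doses))]
}

#' Normalize a plan to the coverage rule
#'
#' Scales a dose distribution so that at least 95% of the target volume is
#' covered by 95% of the prescription dose: the scale factor is
#' `0.95 * rx / D95(target)`, making `D95(target) = 0.95 * rx` exactly
#' (sort-based percentile).
#'
#' @param dose A phantom-frame [dose_grid()].
#' @param target Logical mask of target voxels (same dimensions).
#' @param rx Prescription dose in Gy.
#' @return A list with `dose` (scaled grid) and `scale`.
#' @export
normalize_to_coverage <- function(dose, target, rx) {
  stopifnot(inherits(dose, "dose_grid"), is.logical(target))
  if (!any(target)) stop("target mask is empty", call. = FALSE)
  d95 <- dose_at_volume(dose$values[target], 95)
  if (d95 <= 0) {
    stop("normalization error: dose is zero on (at least 5% of) the target",
         call. = FALSE)
  }
  scale <- 0.95 * rx / d95
  scaled <- dose
  scaled$values <- dose$values * scale
  scaled$meta$scale <- scale
  list(dose = scaled, scale = scale)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure's voxels receiving at least each dose level,
#' on uniform bins from 0 to the structure maximum. The DVH starts at 1 at
#' zero dose, is non-increasing, and reaches 0 beyond the maximum dose.
#' Point metrics (D95 etc.) are computed from sorted voxel doses, not from
#' these bins; the DVH is for plotting and export.
#'
#' @param dose A [dose_grid()].
#' @param mask Logical voxel mask (non-empty).
#' @param bin_width Bin width in dose units (default 0.05).
#' @return A tibble of class `dvh` with columns `dose` (bin edge) and
#'   `volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_width = 0.05) {
  stopifnot(inherits(dose, "dose_grid"), is.logical(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  d <- dose$values[mask]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  frac <- 1 - stats::ecdf(d)(edges) + vapply(edges, function(e) mean(d == e),
                                             numeric(1))
  tibble::new_tibble(
    tibble::tibble(dose = edges, volume_fraction = pmin(frac, 1)),
    class = "dvh", bin_width = bin_width)
}

#' Conformity index
#'
#' `CI = (volume receiving >= 95% of the prescription) / (target volume)`.
#' The numerator counts patient voxels only (target and body); the
#' removable bolus is excluded by default since it is not tissue and would
#' otherwise dominate the spill volume.
#'
#' @param dose A normalized phantom-frame [dose_grid()].
#' @param phantom A [build_phantom()] object supplying the masks.
#' @param rx Prescription dose in Gy.
#' @param include_bolus Count bolus voxels in the numerator (default
#'   `FALSE`).
#' @return Dimensionless CI (1 is ideal; large values mean dose spill).
#' @export
conformity_index <- function(dose, phantom, rx, include_bolus = FALSE) {
  m <- phantom$masks
  if (!any(m$target)) stop("empty target mask", call. = FALSE)
  region <- m$target | m$body
  if (include_bolus) region <- region | m$bolus
  sum(dose$values >= 0.95 * rx & region) / sum(m$target)
}

#' Homogeneity index
#'
#' `HI = D5% / D95%` within the target: the ratio of the dose covering the
#' hottest 5% of the target volume to the dose covering 95% of it. 1 means
#' a perfectly uniform target dose; values above 1 indicate hot spots.
#'
#' @param dose A phantom-frame [dose_grid()].
#' @param target Logical target mask.
#' @return Dimensionless HI `>= 1`.
#' @export
homogeneity_index <- function(dose, target) {
  if (!any(target)) stop("empty target mask", call. = FALSE)
  d <- dose$values[target]
  d95 <- dose_at_volume(d, 95)
  if (d95 <= 0) stop("D95 is zero; homogeneity index undefined", call. = FALSE)
  dose_at_volume(d, 5) / d95
}

#' Mean dose to the body structure
#'
#' Arithmetic mean dose over the body mask (the phantom volume minus the
#' target shell and the bolus).
#'
#' @inheritParams conformity_index
#' @return Mean dose in Gy.
#' @export
body_mean_dose <- function(dose, phantom) {
  m <- phantom$masks$body
  if (!any(m)) stop("empty body mask", call. = FALSE)
  mean(dose$values[m])
}

#' Body mean dose normalized to a reference resolution
#'
#' Divides each sweep row's body mean dose by the body mean dose of the
#' reference scanning resolution within the same phantom/field group, so
#' the reference row gets 1.
#'
#' @param sweep A sweep tibble with columns `body_mean_gy`, a resolution
#'   column, and grouping columns.
#' @param resolution_col Name of the resolution column (e.g. `"dtheta"`).
#' @param reference Reference resolution value (e.g. `1`).
#' @param group_cols Columns defining a sweep family (default: phantom kind,
#'   radius and field size when present).
#' @return The sweep tibble with a `normalized_body_mean` column.
#' @export
normalized_body_mean <- function(sweep, resolution_col = "dtheta",
                                 reference = 1,
                                 group_cols = intersect(
                                   c("kind", "radius", "field_size"),
                                   names(sweep))) {
  stopifnot(resolution_col %in% names(sweep))
  f <- function(df) {
    ref <- df$body_mean_gy[df[[resolution_col]] == reference]
    if (length(ref) != 1L) {
      stop("missing reference resolution ", reference, " in sweep",
           call. = FALSE)
    }
    df$normalized_body_mean <- df$body_mean_gy / ref
    df
  }
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(sweep, dplyr::across(dplyr::all_of(group_cols))),
    ~ f(.x)))
}

#' Evaluate a scanned plan
#'
#' Full plan pipeline for one phantom: superpose the kernel over the
#' placements, normalize to the coverage rule, and compute the plan
#' metrics.
#'
#' @param kernel A beam-frame [dose_grid()].
#' @param placements A `beam_placements` tibble.
#' @param phantom A [build_phantom()] object.
#' @param rx Prescription dose in Gy (default 30).
#' @return An object of class `sff_plan`: normalized dose grid, scale,
#'   phantom, metrics. Use [glance()] for a one-row metric summary,
#'   [tidy()] for per-structure dose statistics, `autoplot()` for DVHs.
#' @export
plan_scan <- function(kernel, placements, phantom, rx = 30) {
  raw <- superpose(kernel, placements, phantom)
  norm <- normalize_to_coverage(raw, phantom$masks$target, rx)
  dose <- norm$dose
  structure(list(
    dose = dose, scale = norm$scale, phantom = phantom, rx = rx,
    n_beams = nrow(placements),
    ci = conformity_index(dose, phantom, rx),
    hi = homogeneity_index(dose, phantom$masks$target),
    body_mean_gy = body_mean_dose(dose, phantom),
    target_d95_gy = dose_at_volume(dose$values[phantom$masks$target], 95)
  ), class = "sff_plan")
}

#' @export
print.sff_plan <- function(x, ...) {
  ph <- x$phantom
  cat(sprintf("<sff_plan> %s R%g, %d beams, rx %g Gy\n", ph$kind, ph$radius,
              x$n_beams, x$rx))
  cat(sprintf("  CI %.3f  HI %.3f  body mean %.2f Gy  target D95 %.2f Gy\n",
              x$ci, x$hi, x$body_mean_gy, x$target_d95_gy))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a scanned plan
#'
#' @param x An `sff_plan`.
#' @param ... Unused.
#' @return A one-row tibble: phantom descriptors, number of beams, scale
#'   factor, CI, HI, body mean dose and target D95.
#' @export
glance.sff_plan <- function(x, ...) {
  ph <- x$phantom
  tibble::tibble(kind = ph$kind, radius = ph$radius, rx_gy = x$rx,
                 n_beams = x$n_beams, scale = x$scale, ci = x$ci, hi = x$hi,
                 body_mean_gy = x$body_mean_gy,
                 target_d95_gy = x$target_d95_gy)
}

#' Per-structure dose statistics of a scanned plan
#'
#' @param x An `sff_plan`.
#' @param ... Unused.
#' @return A tibble with one row per structure (target, body, bolus):
#'   volume, mean/min/max dose, D5 and D95.
#' @export
tidy.sff_plan <- function(x, ...) {
  purrr::map_dfr(c("target", "body", "bolus"), function(s) {
    d <- x$dose$values[x$phantom$masks[[s]]]
    tibble::tibble(structure = s,
                   volume_cc = length(d) * x$phantom$voxel_volume_cc,
                   mean_gy = mean(d), min_gy = min(d), max_gy = max(d),
                   d5_gy = dose_at_volume(d, 5),
                   d95_gy = dose_at_volume(d, 95))
  })
}

#' Serialize a plan report to JSON
#'
#' @param x An `sff_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_plan_report <- function(x, path) {
  jsonlite::write_json(as.list(glance.sff_plan(x)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
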