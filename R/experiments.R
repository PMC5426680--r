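#' Experiment configuration for scanning studies
#'
#' Bundles the study conditions for resolution sweeps and finest-resolution
#' plan summaries: the phantoms (cylinders and/or spheres of radii 5, 7.5,
#' 10, 15 cm), scanning field sizes, angular resolutions (1–20 degrees),
#' longitudinal resolutions (0.3–2 cm), the beam model, and the 30 Gy
#' prescription.
#'
#' `resolution = "full"` uses the 2.5 x 2.5 x 2 mm calculation grid;
#' `"coarse"` a 5 mm preview grid for fast trend studies. `overscan` (cm)
#' extends cylinder axial stations past the phantom ends so the scanned
#' field clears the target edge; the default `field/2 + 2` cm covers the
#' field half-width plus a penumbra margin, keeping the axial target
#' coverage flat.
#'
#' @param phantoms Tibble (or data frame) with columns `kind`
#'   (`"cylinder"`/`"sphere"`) and `radius` (cm).
#' @param field_sizes Field sides in cm (subset of 1, 2, 4 by default).
#' @param dtheta_values Angular resolutions in degrees.
#' @param dz_values Longitudinal resolutions in cm (cylinders).
#' @param dtheta_ref,dz_ref Reference (finest) resolutions used while the
#'   other direction is swept, and by [run_table2_sff()].
#' @param beam A [beam_model_params()] object, or a function
#'   `function(field_size)` returning one.
#' @param rx Prescription dose in Gy.
#' @param ssd Source-to-surface distance in cm.
#' @param resolution `"full"` (2.5 x 2.5 x 2 mm) or `"coarse"` (5 mm).
#' @param overscan Axial overscan in cm, or `NULL` for `field/2 + 2`.
#' @param seed Integer seed recorded in provenance.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantoms = tibble::tibble(
                                kind = rep(c("cylinder", "sphere"), each = 4),
                                radius = rep(c(5, 7.5, 10, 15), 2)),
                              field_sizes = c(1, 4),
                              dtheta_values = c(1, 2, 3, 4, 5, 10, 15, 20),
                              dz_values = c(0.3, 0.6, 1, 1.3, 1.6, 2),
                              dtheta_ref = 1, dz_ref = 0.3,
                              beam = function(field_size)
                                beam_preset("6mev-sff",
                                            field_size = field_size),
                              rx = 30, ssd = 60,
                              resolution = c("full", "coarse"),
                              overscan = NULL, seed = 1L) {
  resolution <- match.arg(resolution)
  phantoms <- tibble::as_tibble(phantoms)
  stopifnot(all(c("kind", "radius") %in% names(phantoms)),
            all(phantoms$kind %in% c("cylinder", "sphere")),
            all(phantoms$radius > 0),
            all(dtheta_values > 0), all(dz_values > 0), rx > 0)
  structure(list(phantoms = phantoms, field_sizes = field_sizes,
                 dtheta_values = sort(dtheta_values),
                 dz_values = sort(dz_values),
                 dtheta_ref = dtheta_ref, dz_ref = dz_ref, beam = beam,
                 rx = rx, ssd = ssd, resolution = resolution,
                 overscan = overscan, seed = as.integer(seed)),
            class = "experiment_config")
}

config_spacing <- function(config) {
  if (config$resolution == "full") c(0.25, 0.25, 0.2) else c(0.5, 0.5, 0.5)
}

config_beam <- function(config, field_size) {
  if (is.function(config$beam)) config$beam(field_size)
  else utils::modifyList(config$beam, list(field_size = field_size))
}

config_kernel <- function(config, field_size) {
  params <- config_beam(config, field_size)
  build_kernel_synthetic(params,
                         grid = kernel_grid(field_size,
                                            spacing = config_spacing(config)),
                         ssd = config$ssd)
}

config_overscan <- function(config, field_size) {
  config$overscan %||% (field_size / 2 + 2)
}

run_one_plan <- function(config, kernel, kind, radius, field_size, dtheta,
                         dz) {
  ph <- build_phantom(kind, radius, spacing = config_spacing(config))
  pl <- if (kind == "cylinder") {
    place_beams_cylinder(ph, dtheta = dtheta, dz = dz, ssd = config$ssd,
                         overscan = config_overscan(config, field_size))
  } else {
    place_beams_sphere(ph, dtheta = dtheta, ssd = config$ssd)
  }
  plan_scan(kernel, pl, ph, rx = config$rx)
}

#' Scanning-resolution sweep
#'
#' Runs one normalized plan per combination of phantom, field size and
#' scanning resolution and collects the plan-quality metrics. For
#' cylinders both sweeps are run: angular resolutions at the reference
#' longitudinal resolution, and longitudinal resolutions at the reference
#' angular resolution; spheres sweep the angular resolution only. Body
#' mean doses are also reported normalized to the finest angular (or
#' longitudinal) resolution of the same family. A failing combination is
#' recorded with `NA` metrics and an `error` message rather than aborting
#' the sweep.
#'
#' @param config An [experiment_config()].
#' @param progress Log one line per plan to `stderr` (default `FALSE`).
#' @return A tibble with one row per plan: `kind`, `radius`, `field_size`,
#'   `sweep` (`"angular"` or `"longitudinal"`), `dtheta`, `dz`, `n_beams`,
#'   `ci`, `hi`, `body_mean_gy`, `normalized_body_mean`, `elapsed_s`,
#'   `error`.
#' @export
run_resolution_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  combos <- dplyr::bind_rows(
    tidyr::expand_grid(config$phantoms, field_size = config$field_sizes,
                       sweep = "angular", dtheta = config$dtheta_values,
                       dz = config$dz_ref),
    tidyr::expand_grid(
      dplyr::filter(config$phantoms, .data$kind == "cylinder"),
      field_size = config$field_sizes, sweep = "longitudinal",
      dtheta = config$dtheta_ref,
      dz = setdiff(config$dz_values, config$dz_ref))
  )
  combos$dz[combos$kind == "sphere"] <- NA_real_
  kernels <- lapply(stats::setNames(nm = config$field_sizes),
                    function(f) config_kernel(config, f))
  rows <- purrr::pmap(combos, function(kind, radius, field_size, sweep,
                                       dtheta, dz) {
    t0 <- proc.time()["elapsed"]
    res <- tryCatch({
      plan <- run_one_plan(config, kernels[[as.character(field_size)]],
                           kind, radius, field_size, dtheta,
                           if (is.na(dz)) config$dz_ref else dz)
      tibble::tibble(n_beams = plan$n_beams, ci = plan$ci, hi = plan$hi,
                     body_mean_gy = plan$body_mean_gy, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(n_beams = NA_integer_, ci = NA_real_, hi = NA_real_,
                     body_mean_gy = NA_real_, error = conditionMessage(e))
    })
    el <- unname(proc.time()["elapsed"] - t0)
    if (progress) {
      message(sprintf(
        "[sweep] %s R%g field %g %s dtheta %g dz %s: CI %.3f HI %.3f body %.2f Gy (%.1fs)%s",
        kind, radius, field_size, sweep, dtheta, format(dz), res$ci, res$hi,
        res$body_mean_gy, el,
        if (is.na(res$error)) "" else paste0(" ERROR: ", res$error)))
    }
    dplyr::bind_cols(
      tibble::tibble(kind = kind, radius = radius, field_size = field_size,
                     sweep = sweep, dtheta = dtheta, dz = dz),
      res, tibble::tibble(elapsed_s = el))
  })
  out <- dplyr::bind_rows(rows)
  ang <- dplyr::filter(out, .data$sweep == "angular")
  if (nrow(ang) > 0 && config$dtheta_ref %in% ang$dtheta) {
    ang <- normalized_body_mean(ang, "dtheta", config$dtheta_ref)
  } else {
    ang$normalized_body_mean <- NA_real_
  }
  lon <- dplyr::filter(out, .data$sweep == "longitudinal")
  if (nrow(lon) > 0) {
    # reference row for the longitudinal sweep is the angular-sweep plan at
    # (dtheta_ref, dz_ref); splice it in, normalize, drop it again
    refrows <- dplyr::filter(ang, .data$dtheta == config$dtheta_ref,
                             .data$kind == "cylinder")
    refrows$sweep <- "longitudinal"
    lon2 <- dplyr::bind_rows(lon, refrows)
    lon2 <- normalized_body_mean(lon2, "dz", config$dz_ref)
    lon <- dplyr::filter(lon2, !(.data$dz == config$dz_ref))
  }
  dplyr::arrange(dplyr::bind_rows(ang, lon), .data$kind, .data$radius,
                 .data$field_size, .data$sweep, .data$dtheta, .data$dz)
}

#' Finest-resolution plan summaries
#'
#' Generates, for each configured phantom, the plan at the finest scanning
#' resolution (by default 4 x 4 cm field, 1 degree angular and 3 mm
#' longitudinal resolution) and returns its dose-volumetric parameters.
#'
#' @param config An [experiment_config()].
#' @param field_size Field side in cm for the summary plans (default 4).
#' @param progress Log one line per plan to `stderr`.
#' @return A tibble with one row per phantom: `kind`, `radius`, `n_beams`,
#'   `scale`, `ci`, `hi`, `body_mean_gy`, `target_d95_gy`, plus provenance
#'   columns `field_size`, `dtheta`, `dz`, `resolution`, `seed`.
#' @export
run_table2_sff <- function(config, field_size = 4, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  kernel <- config_kernel(config, field_size)
  rows <- purrr::pmap(config$phantoms, function(kind, radius) {
    t0 <- proc.time()["elapsed"]
    plan <- run_one_plan(config, kernel, kind, radius, field_size,
                         config$dtheta_ref, config$dz_ref)
    g <- glance.sff_plan(plan)
    if (progress) {
      message(sprintf("[table2] %s R%g: CI %.3f HI %.3f body %.2f Gy (%.1fs)",
                      kind, radius, g$ci, g$hi, g$body_mean_gy,
                      unname(proc.time()["elapsed"] - t0)))
    }
    g
  })
  out <- dplyr::bind_rows(rows)
  out$field_size <- field_size
  out$dtheta <- config$dtheta_ref
  out$dz <- ifelse(out$kind == "cylinder", config$dz_ref, NA_real_)
  out$resolution <- config$resolution
  out$seed <- config$seed
  out
}

#' Surface beam separation of a scanning resolution
#'
#' Arc separation between neighbouring scan positions on the bolus surface:
#' `(radius + bolus) * dtheta * pi / 180` for the angular direction, `dz`
#' for the longitudinal direction.
#'
#' @param radius Phantom radius in cm.
#' @param dtheta Angular resolution in degrees.
#' @param bolus_thickness Bolus thickness in cm (default 1).
#' @return Separation in cm.
#' @export
beam_separation <- function(radius, dtheta, bolus_thickness = 1) {
  (radius + bolus_thickness) * dtheta * pi / 180
}

#' Locate the plan-quality breakpoint of a sweep
#'
#' Plan quality degrades once the separation between scanned beams exceeds
#' the field size. For one phantom/field family of a sweep table this
#' identifies the smallest swept resolution whose surface beam separation
#' exceeds the field size, and reports whether the conformity index at that
#' resolution exceeds the finest-resolution CI by more than 10%.
#'
#' @param sweep A [run_resolution_sweep()] table.
#' @param field_size Field side in cm.
#' @param kind,radius Phantom selector.
#' @param direction `"angular"` or `"longitudinal"`.
#' @return A list with `breakpoint` (resolution value, `NA` if separation
#'   never exceeds the field within the sweep), `separation_cm`, and
#'   `degraded` (`TRUE` if CI at the breakpoint exceeds CI at the finest
#'   resolution by > 10%).
#' @export
breakpoint_check <- function(sweep, field_size, kind, radius,
                             direction = c("angular", "longitudinal")) {
  direction <- match.arg(direction)
  rows <- dplyr::filter(sweep, .data$kind == !!kind,
                        .data$radius == !!radius,
                        .data$field_size == !!field_size,
                        .data$sweep == direction, is.na(.data$error))
  if (nrow(rows) < 2L) {
    stop("insufficient sweep coverage for breakpoint check", call. = FALSE)
  }
  res <- if (direction == "angular") rows$dtheta else rows$dz
  sep <- if (direction == "angular") {
    beam_separation(radius, res)
  } else {
    res
  }
  o <- order(res)
  res <- res[o]; sep <- sep[o]; ci <- rows$ci[o]
  over <- which(sep > field_size)
  if (length(over) == 0L) {
    return(list(breakpoint = NA_real_, separation_cm = NA_real_,
                degraded = FALSE))
  }
  bp <- over[1]
  list(breakpoint = res[bp], separation_cm = sep[bp],
       degraded = ci[bp] > 1.1 * ci[1])
}
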