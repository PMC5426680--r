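#' Distal 50% depth (R50)
#'
#' Depth at which the central-axis dose, normalized to its maximum (= 100),
#' first falls through 50% on the distal side of the maximum, linearly
#' interpolated between the bracketing samples. R50 is the standard
#' beam-quality surrogate for electron beams.
#'
#' @param curve A [depth_dose()] curve.
#' @return Depth in cm.
#' @export
r50 <- function(curve) {
  distal_crossing(curve, 50)
}

# depth of the first distal crossing of `level` % of max
distal_crossing <- function(curve, level) {
  rel <- rel_dose(curve)
  z <- curve$depth
  imax <- which.max(rel)
  idx <- seq(imax, length(rel))
  below <- idx[rel[idx] < level]
  if (length(below) == 0L) {
    stop("range error: no distal crossing of ", level,
         "% of maximum within the sampled depths", call. = FALSE)
  }
  j <- below[1L]
  if (j == imax) return(z[j])
  stats::approx(rel[c(j - 1L, j)], z[c(j - 1L, j)], xout = level)$y
}

#' Practical range (Rp)
#'
#' Intersection depth of the tangent at the steepest point of the distal
#' falloff with the horizontal line at the bremsstrahlung-tail level (taken
#' as the mean of the last three samples). All doses are normalized to the
#' curve maximum before the construction, so the result is invariant under
#' uniform rescaling.
#'
#' @inheritParams r50
#' @return Depth in cm.
#' @export
practical_range <- function(curve) {
  rel <- rel_dose(curve)
  z <- curve$depth
  n <- length(z)
  imax <- which.max(rel)
  if (imax >= n - 1L) {
    stop("range error: no descending distal limb after the maximum",
         call. = FALSE)
  }
  tail_level <- mean(rel[(n - 2L):n])
  # finite-difference slope on the distal limb; central where possible
  idx <- seq(imax, n)
  zi <- z[idx]; di <- rel[idx]
  m <- length(idx)
  slope <- numeric(m)
  slope[1] <- (di[2] - di[1]) / (zi[2] - zi[1])
  slope[m] <- (di[m] - di[m - 1]) / (zi[m] - zi[m - 1])
  if (m > 2) {
    slope[2:(m - 1)] <- (di[3:m] - di[1:(m - 2)]) / (zi[3:m] - zi[1:(m - 2)])
  }
  # steepest descent above the tail region only
  cand <- which(di > tail_level + 1e-9)
  if (length(cand) == 0L || min(slope[cand]) >= 0) {
    stop("range error: distal falloff has no descending tangent", call. = FALSE)
  }
  s <- cand[which.min(slope[cand])]
  zs <- zi[s]; ds <- di[s]; g <- slope[s]
  zs + (ds - tail_level) / (-g)
}

#' Bremsstrahlung (photon) contamination
#'
#' Mean normalized dose over the depth window `[Rp + 0.5, Rp + 1.5]` cm
#' beyond the practical range, expressed in percent of the curve maximum.
#' This windowed mean quantifies the flat photon tail that survives past the
#' electron range; removing the scattering foil lowers it by roughly an
#' order of magnitude.
#'
#' The sampled depths must reach at least `Rp + 1` cm; the window is clipped
#' at the last sample if the curve stops before `Rp + 1.5` cm.
#'
#' @inheritParams r50
#' @return Contamination in percent of the maximum dose.
#' @export
photon_contamination <- function(curve) {
  rp <- practical_range(curve)
  zmax <- max(curve$depth)
  if (zmax < rp + 1) {
    stop(sprintf(
      "range error: insufficient tail sampling, depths must reach %.2f cm (Rp + 1), got %.2f cm",
      rp + 1, zmax), call. = FALSE)
  }
  lo <- rp + 0.5
  hi <- min(rp + 1.5, zmax)
  zz <- seq(lo, hi, length.out = 51L)
  mean(stats::approx(curve$depth, rel_dose(curve), xout = zz)$y)
}

#' Output ratio of two absolute curves
#'
#' Ratio of the dose maxima of two absolutely normalized depth-dose curves,
#' by convention scattering-foil-free over with-foil. Used to quantify the
#' output increase from removing the scattering foil.
#'
#' @param sff,sf Absolute [depth_dose()] curves for the same energy and
#'   field size.
#' @return Dimensionless ratio `max(sff) / max(sf)`.
#' @export
output_ratio <- function(sff, sf) {
  if (attr(sff, "normalization") != "absolute" ||
      attr(sf, "normalization") != "absolute") {
    stop("unit error: output_ratio requires absolute-normalized curves on both sides",
         call. = FALSE)
  }
  max(sff$dose) / max(sf$dose)
}

#' Full width at half maximum of a lateral profile
#'
#' Distance between the two 50%-of-maximum crossings of the profile,
#' linearly interpolated between bracketing samples.
#'
#' @param profile A [lateral_profile()].
#' @return Width in cm.
#' @export
profile_fwhm <- function(profile) {
  rel <- 100 * profile$dose / max(profile$dose)
  x <- profile$position
  imax <- which.max(rel)
  left <- which(rel[seq_len(imax)] < 50)
  right_idx <- seq(imax, length(rel))
  right <- right_idx[rel[right_idx] < 50]
  if (length(left) == 0L || length(right) == 0L) {
    stop("range error: profile does not cross 50% of maximum on both sides",
         call. = FALSE)
  }
  l <- max(left)
  xl <- stats::approx(rel[c(l, l + 1L)], x[c(l, l + 1L)], xout = 50)$y
  r <- min(right)
  xr <- stats::approx(rel[c(r - 1L, r)], x[c(r - 1L, r)], xout = 50)$y
  xr - xl
}

#' Dose-difference / distance-to-agreement curve comparison
#'
#' Composite agreement index between a reference and an evaluated 1D dose
#' curve, the standard benchmarking figure of merit for dose-curve
#' comparisons. For each reference sample the index is the minimum over the
#' (densely resampled) evaluated curve of
#' `sqrt((ddose / dd)^2 + (dpos / dta)^2)`, with dose differences expressed
#' in percent of the reference curve maximum (global normalization). A
#' sample agrees if its index is `<= 1`; the defaults `dd = 2`, `dta = 0.1`
#' encode the usual 2%/1 mm criterion.
#'
#' @param reference,evaluated Two curves (either [depth_dose()] or
#'   [lateral_profile()]) on overlapping abscissa ranges.
#' @param dd Dose-difference tolerance, percent of the reference maximum.
#' @param dta Distance-to-agreement tolerance in cm (0.1 cm = 1 mm).
#' @return A list with `pass_fraction` (fraction of reference samples with
#'   index `<= 1`) and `max_index`.
#' @export
curve_agreement <- function(reference, evaluated, dd = 2, dta = 0.1) {
  ax <- function(x) if ("depth" %in% names(x)) x$depth else x$position
  xr <- ax(reference); xe <- ax(evaluated)
  if (max(xe) < min(xr) || min(xe) > max(xr)) {
    stop("range error: curves have non-overlapping abscissa ranges",
         call. = FALSE)
  }
  ref_max <- max(reference$dose)
  dr <- 100 * reference$dose / ref_max
  de <- 100 * evaluated$dose / ref_max
  # dense resampling of the evaluated curve so DTA is resolved well below dta
  xf <- seq(min(xe), max(xe), by = dta / 20)
  df <- stats::approx(xe, de, xout = xf)$y
  keep <- xr >= min(xe) & xr <= max(xe)
  idx <- vapply(which(keep), function(i) {
    sqrt(min(((df - dr[i]) / dd)^2 + ((xf - xr[i]) / dta)^2))
  }, numeric(1))
  list(pass_fraction = mean(idx <= 1), max_index = max(idx))
}

#' Beam-characteristic metrics for a set of curves
#'
#' Convenience wrapper computing R50, practical range and photon
#' contamination for every depth-dose curve in a set (as returned by
#' [read_beam_table()]), plus the SFF/SF output ratio where paired absolute
#' curves are present.
#'
#' @param curves A list of [depth_dose()] / [lateral_profile()] objects.
#' @return A tibble with one row per depth-dose curve: `energy`,
#'   `field_size`, `foil`, `normalization`, `r50_cm`, `rp_cm`,
#'   `photon_contamination_pct`, `output_ratio` (`NA` where undefined).
#' @export
beam_metrics <- function(curves) {
  pdds <- purrr::keep(curves, inherits, "depth_dose")
  if (length(pdds) == 0L) stop("no depth-dose curves in input", call. = FALSE)
  rows <- purrr::map(pdds, function(cv) {
    m <- curve_meta(cv)
    tibble::tibble(
      energy = m$energy, field_size = m$field_size, foil = m$foil,
      normalization = m$normalization,
      r50_cm = r50(cv), rp_cm = practical_range(cv),
      photon_contamination_pct = photon_contamination(cv)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$output_ratio <- NA_real_
  abs_pdds <- purrr::keep(pdds, ~ attr(.x, "normalization") == "absolute")
  if (length(abs_pdds) >= 2L) {
    key <- function(cv) paste(attr(cv, "energy"), attr(cv, "field_size"))
    for (k in unique(vapply(abs_pdds, key, character(1)))) {
      grp <- purrr::keep(abs_pdds, ~ key(.x) == k)
      foils <- vapply(grp, attr, character(1), which = "foil")
      if (all(c("SF", "SFF") %in% foils)) {
        ratio <- output_ratio(grp[[match("SFF", foils)]],
                              grp[[match("SF", foils)]])
        sel <- out$normalization == "absolute" &
          paste(out$energy, out$field_size) == k
        out$output_ratio[sel] <- ratio
      }
    }
  }
  out
}
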