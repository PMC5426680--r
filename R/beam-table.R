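#' Read a tabulated beam data file
#'
#' Reads depth-dose curves and off-axis profiles from a tabular beam file
#' (CSV, or xlsx when the readxl package is available). Because published
#' beam-table layouts vary, the column meaning is described by a *dialect*:
#' a YAML (or JSON) file, or an equivalent R list, mapping the abscissa
#' column and each dose column to curve metadata.
#'
#' A single-table dialect looks like
#' ```yaml
#' abscissa: {column: depth_cm, kind: depth, unit: cm}
#' series:
#'   sff_rel:
#'     curve: pdd            # or "profile"
#'     foil: SFF             # SF or SFF
#'     energy_mev: 6
#'     field_size_cm: 2
#'     ssd_cm: 60
#'     normalization: relative_max100   # or "absolute"
#'     # depth_cm: 1.2       # profiles only
#' ```
#' A multi-table dialect wraps several of these under `tables:` keyed by
#' file name, so one dialect can describe a depth-dose file and its
#' companion profile file ([synth_beam_table()] writes this form).
#' Abscissa units `cm` and `mm` are supported; `mm` values are converted.
#'
#' @param path Path to the table file.
#' @param dialect Path to a YAML/JSON dialect file, or a list.
#' @return A named list of [depth_dose()] and [lateral_profile()] objects
#'   (names = dose column names).
#' @export
read_beam_table <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(dialect)) {
    dialect <- if (grepl("\\.json$", dialect, ignore.case = TRUE)) {
      jsonlite::read_json(dialect, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(dialect)
    }
  }
  if (!is.null(dialect$tables)) {
    dialect <- dialect$tables[[basename(path)]]
    if (is.null(dialect)) {
      stop("format error: dialect has no entry for table '", basename(path),
           "'", call. = FALSE)
    }
  }
  absc <- dialect$abscissa
  if (is.null(absc$column) || is.null(absc$kind)) {
    stop("format error: dialect abscissa must give 'column' and 'kind'",
         call. = FALSE)
  }
  tab <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    readxl::read_excel(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!absc$column %in% names(tab)) {
    stop("format error: abscissa column '", absc$column, "' not found",
         call. = FALSE)
  }
  xs <- as.numeric(tab[[absc$column]])
  unit <- absc$unit %||% "cm"
  if (identical(unit, "mm")) xs <- xs / 10
  else if (!identical(unit, "cm")) {
    stop("format error: unsupported abscissa unit '", unit, "'",
         call. = FALSE)
  }
  if (any(!is.finite(xs)) || any(diff(xs) <= 0)) {
    stop("format error in column '", absc$column,
         "': values must be finite and strictly increasing", call. = FALSE)
  }
  series <- dialect$series
  if (is.null(names(series))) {
    # allow list-of-lists with $column entries
    names(series) <- vapply(series, function(s) s$column, character(1))
  }
  out <- lapply(names(series), function(col) {
    s <- series[[col]]
    if (!col %in% names(tab)) {
      stop("format error: dose column '", col, "' not found", call. = FALSE)
    }
    dose <- as.numeric(tab[[col]])
    if (all(is.na(dose))) {
      stop("format error: dose column '", col, "' is empty", call. = FALSE)
    }
    kind <- s$curve %||% if (identical(absc$kind, "depth")) "pdd" else "profile"
    norm <- s$normalization %||% "relative_max100"
    if (kind == "pdd") {
      depth_dose(xs, dose, energy = s$energy_mev %||% NA_real_,
                 field_size = s$field_size_cm %||% NA_real_,
                 foil = s$foil %||% "SFF", ssd = s$ssd_cm %||% NA_real_,
                 normalization = norm)
    } else {
      if (is.null(s$depth_cm)) {
        stop("format error: profile column '", col,
             "' has no depth_cm in the dialect", call. = FALSE)
      }
      lateral_profile(xs, dose, depth = s$depth_cm,
                      energy = s$energy_mev %||% NA_real_,
                      field_size = s$field_size_cm %||% NA_real_,
                      foil = s$foil %||% "SFF", ssd = s$ssd_cm %||% NA_real_,
                      normalization = norm)
    }
  })
  stats::setNames(out, names(series))
}
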