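#' Biomarker report for one eye / volume
#'
#' All scalars and sector tables extracted from one acquisition, plus
#' provenance (input id, tool version, parameters). Serializable to JSON
#' (lossless full-precision round trip) and CSV.
#'
#' @param bmo [bmo_ellipse()] or `NULL` (not measurable on this acquisition).
#' @param cprnfl named list of [sector_summary()] keyed by diameter (e.g.
#'   `"3.4"`, `"3.5"`).
#' @param mrw `mrw_result` or `NULL`.
#' @param cup `cup_result` or `NULL`.
#' @param provenance list: `input`, `tool_version`, `parameters`, optional
#'   `input_md5`, `warnings`.
#' @return object of class `biomarker_report`.
#' @export
biomarker_report <- function(bmo = NULL, cprnfl = list(), mrw = NULL,
                             cup = NULL, provenance = list()) {
  provenance$tool_version <- as.character(utils::packageVersion("onhmark"))
  structure(list(bmo = bmo, cprnfl = cprnfl, mrw = mrw, cup = cup,
                 provenance = provenance),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("<biomarker_report>\n")
  if (!is.null(x$bmo))
    cat(sprintf("  BMO area: %.4f mm^2, center (%.0f, %.0f) um\n",
                x$bmo$area_mm2, x$bmo$center_um[1], x$bmo$center_um[2]))
  for (d in names(x$cprnfl))
    cat(sprintf("  cpRNFL %s mm: global %.1f um\n", d,
                x$cprnfl[[d]]$global_mean_um))
  if (!is.null(x$mrw))
    cat(sprintf("  MRW: global %.1f um (%d/%d meridians)\n",
                x$mrw$global_mean_um,
                x$mrw$n_meridians - x$mrw$n_missing, x$mrw$n_meridians))
  if (!is.null(x$cup))
    cat(sprintf("  cup volume: %.4f mm^3\n", x$cup$volume_mm3))
  invisible(x)
}

#' Extract all biomarkers from a segmentation input
#'
#' The full pipeline. For cube acquisitions: BMO detection
#' ([detect_bmo()]) -> vessel resolution -> cpRNFL at each requested diameter
#' ([cprnfl()]) -> MRW from synthesized radials ([compute_mrw()]) -> cup
#' volume ([cup_volume()]). For radial/circular acquisitions: cpRNFL from the
#' circular scans and MRW from the acquired radials; BMO area, heatmap and
#' cup volume are flagged unavailable (they need the full en-face raster).
#'
#' @param input a [label_volume()] (cube) or [radial_circular_set()].
#' @param diameters_mm cpRNFL circle diameters (default 3.4 and 3.5 mm).
#' @param n_radials radial slices for MRW on cube input.
#' @param closing_radius_px BMO closing radius.
#' @param input_id character tag recorded in provenance.
#' @return a [biomarker_report()].
#' @export
extract_biomarkers <- function(input, diameters_mm = c(3.4, 3.5),
                               n_radials = 24L, closing_radius_px = 3L,
                               input_id = "in-memory") {
  params <- list(diameters_mm = diameters_mm, n_radials = n_radials,
                 closing_radius_px = closing_radius_px)
  warnings <- character(0)
  if (inherits(input, "label_volume") && input$acquisition == "cube") {
    ell <- detect_bmo(input, closing_radius_px)
    warnings <- c(warnings, attr(ell, "warnings"))
    tr <- tsnit_angle_transform(input$laterality, ell$center_um,
                                input$fovea_enface_um)
    if (!tr$tilt_applied)
      warnings <- c(warnings, "no_fovea_tilt_fallback")
    resolved <- resolve_vessels(input)
    thick <- thickness_map(resolved, resolve = FALSE)
    cp <- list()
    for (d in diameters_mm)
      cp[[format(d)]] <- cprnfl(resolved, ell, d, thickness = thick,
                                transform = tr)$summary
    mrw <- compute_mrw(input, ell, n_radials = n_radials, transform = tr)
    cup <- cup_volume(input, ell)
    biomarker_report(bmo = ell, cprnfl = cp, mrw = mrw, cup = cup,
                     provenance = list(input = input_id, parameters = params,
                                       warnings = warnings))
  } else if (inherits(input, "radial_circular_set")) {
    cp <- list()
    for (cs in input$circular_slices) {
      res <- cprnfl_from_circular(cs, input$scheme)
      cp[[format(cs$diameter_mm)]] <- res$summary
    }
    mrw <- compute_mrw(input)
    warnings <- c(warnings, "cube_only_outputs_unavailable")
    biomarker_report(bmo = NULL, cprnfl = cp, mrw = mrw, cup = NULL,
                     provenance = list(input = input_id, parameters = params,
                                       warnings = warnings))
  } else {
    stop("unsupported input type for biomarker extraction", call. = FALSE)
  }
}

# flatten a report into a named list of numeric fields (for CSV / comparison)
.report_fields <- function(report) {
  out <- list()
  if (!is.null(report$bmo)) {
    out$bmo_area_mm2 <- report$bmo$area_mm2
    out$bmo_center_x_um <- report$bmo$center_um[1]
    out$bmo_center_y_um <- report$bmo$center_um[2]
    out$bmo_semi_major_um <- report$bmo$semi_major_um
    out$bmo_semi_minor_um <- report$bmo$semi_minor_um
    out$bmo_rotation_deg <- report$bmo$rotation_deg
  }
  for (d in names(report$cprnfl)) {
    s <- report$cprnfl[[d]]
    key <- gsub("\\.", "_", d)
    out[[paste0("cprnfl_", key, "_global_um")]] <- s$global_mean_um
    for (nm in names(s$tsnit))
      out[[paste0("cprnfl_", key, "_", nm, "_um")]] <- unname(s$tsnit[nm])
    for (h in seq_along(s$clock_hours))
      out[[paste0("cprnfl_", key, "_h", h, "_um")]] <- unname(s$clock_hours[h])
  }
  if (!is.null(report$mrw)) {
    out$mrw_global_um <- report$mrw$global_mean_um
    for (nm in names(report$mrw$tsnit))
      out[[paste0("mrw_", nm, "_um")]] <- unname(report$mrw$tsnit[nm])
  }
  if (!is.null(report$cup))
    out$cup_volume_mm3 <- report$cup$volume_mm3
  out
}

#' Write a biomarker report to JSON or CSV
#'
#' JSON keeps the full structure (including per-meridian MRW values) at full
#' numeric precision; CSV is a flat `field,value` table with missing values
#' rendered as the literal `NA` token.
#'
#' @param report a [biomarker_report()].
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "biomarker_report"))
  if (length(format) == 1 && !format %in% c("json", "csv"))
    stop("unsupported report format: ", format, call. = FALSE)
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      bmo = if (!is.null(report$bmo)) unclass(report$bmo),
      cprnfl = lapply(report$cprnfl, function(s)
        list(global_mean_um = s$global_mean_um,
             tsnit = as.list(s$tsnit),
             clock_hours = as.list(s$clock_hours),
             diameter_mm = s$diameter_mm,
             tilt_applied = s$tilt_applied,
             missing_sectors = as.list(s$missing_sectors))),
      mrw = if (!is.null(report$mrw))
        list(global_mean_um = report$mrw$global_mean_um,
             tsnit = as.list(report$mrw$tsnit),
             per_meridian = list(angles_deg = report$mrw$per_meridian$angles_deg,
                                 mrw_um = report$mrw$per_meridian$values),
             n_meridians = report$mrw$n_meridians,
             n_missing = report$mrw$n_missing),
      cup = if (!is.null(report$cup))
        list(volume_mm3 = report$cup$volume_mm3,
             n_bscans_contributing = report$cup$n_bscans_contributing,
             per_bscan = report$cup$per_bscan),
      provenance = report$provenance)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", dataframe = "columns")
  } else {
    f <- .report_fields(report)
    df <- data.frame(field = names(f),
                     value = vapply(f, function(v) v[1], numeric(1)))
    utils::write.csv(df, path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a JSON biomarker report
#'
#' Inverse of [write_report()] (JSON format): every numeric field is restored
#' exactly.
#'
#' @param path JSON report path.
#' @return a [biomarker_report()].
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  bmo <- if (!is.null(obj$bmo))
    bmo_ellipse(unlist(obj$bmo$center_um), obj$bmo$semi_major_um,
                obj$bmo$semi_minor_um, obj$bmo$rotation_deg)
  cp <- lapply(obj$cprnfl, function(s) {
    structure(list(global_mean_um = .null2na(s$global_mean_um),
                   tsnit = unlist(lapply(s$tsnit, .null2na)),
                   clock_hours = unlist(lapply(s$clock_hours, .null2na)),
                   diameter_mm = s$diameter_mm,
                   tilt_applied = isTRUE(s$tilt_applied),
                   missing_sectors = unlist(s$missing_sectors) %||% character(0)),
              class = "sector_summary")
  })
  mrw <- if (!is.null(obj$mrw)) {
    vals <- vapply(obj$mrw$per_meridian$mrw_um, .null2na, numeric(1))
    structure(list(
      per_meridian = angular_profile(unlist(obj$mrw$per_meridian$angles_deg),
                                     vals),
      global_mean_um = .null2na(obj$mrw$global_mean_um),
      tsnit = unlist(lapply(obj$mrw$tsnit, .null2na)),
      n_meridians = obj$mrw$n_meridians,
      n_missing = obj$mrw$n_missing), class = "mrw_result")
  }
  cup <- if (!is.null(obj$cup))
    structure(list(
      per_bscan = data.frame(
        bscan_index = unlist(obj$cup$per_bscan$bscan_index),
        area_mm2 = unlist(obj$cup$per_bscan$area_mm2)),
      volume_mm3 = obj$cup$volume_mm3,
      n_bscans_contributing = obj$cup$n_bscans_contributing),
      class = "cup_result")
  rep <- biomarker_report(bmo = bmo, cprnfl = cp, mrw = mrw, cup = cup,
                          provenance = obj$provenance)
  rep
}

.null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
`%||%` <- function(a, b) if (is.null(a)) b else a
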