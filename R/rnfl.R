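#' Resolve vessel voxels into RNFL or background
#'
#' Retinal vessels interrupt the RNFL band; for thickness measurement every
#' vessel voxel is re-assigned to either `rnfl` or `background`, whichever
#' non-vessel annotation is nearest in the physical (anisotropic, um) metric
#' within its own B-scan plane. Exact ties go to `rnfl`, so continuous tissue
#' is never punched open. All other labels are unchanged, and voxel counts
#' are conserved.
#'
#' @param volume a [label_volume()] whose scheme has `vessel`.
#' @return a [label_volume()] with no remaining vessel voxels.
#' @export
resolve_vessels <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  code_v <- .scheme_codes(volume$scheme, "vessel")
  code_r <- .scheme_codes(volume$scheme, "rnfl")
  code_b <- .scheme_codes(volume$scheme, "background")
  lab <- volume$labels
  has_vessel <- which(rowSums(array(lab == code_v, dim(lab)), dims = 1L) > 0)
  for (i in has_vessel) {
    sl <- lab[i, , ]   # (ascan, axial)
    lab[i, , ] <- .resolve_vessels_slice(sl, code_r, code_b, code_v,
                                         volume$spacing_ascan_um,
                                         volume$spacing_axial_um)
  }
  out <- volume
  out$labels <- lab
  out
}

# vessel resolution on a single 2D slice (lateral x axial)
.resolve_vessels_slice <- function(sl, code_r, code_b, code_v,
                                   spacing_lateral_um, spacing_axial_um) {
  idx <- which(sl == code_v)
  if (!length(idx)) return(sl)
  d_r <- edt_sq(sl == code_r, spacing_lateral_um, spacing_axial_um)
  d_b <- edt_sq(sl == code_b, spacing_lateral_um, spacing_axial_um)
  sl[idx] <- ifelse(d_r[idx] <= d_b[idx], code_r, code_b)
  sl
}

#' Per-A-scan RNFL thickness map
#'
#' Thickness of each A-scan as (number of `rnfl` voxels) x axial spacing, in
#' micrometres. Vessels must already be resolved ([resolve_vessels()]); with
#' `resolve = TRUE` (default) this is done on the fly when vessel voxels are
#' present.
#'
#' @param volume a cube [label_volume()].
#' @param resolve resolve vessel voxels first (default `TRUE`).
#' @return scalar [enface_map()] of thickness in um.
#' @export
thickness_map <- function(volume, resolve = TRUE) {
  stopifnot(inherits(volume, "label_volume"))
  code_v <- .scheme_codes(volume$scheme, "vessel")
  if (resolve && any(volume$labels == code_v))
    volume <- resolve_vessels(volume)
  code_r <- .scheme_codes(volume$scheme, "rnfl")
  hit <- array(volume$labels == code_r, dim = dim(volume$labels))
  counts <- rowSums(hit, dims = 2L)
  enface_map(counts * volume$spacing_axial_um,
             spacing_x_um = volume$spacing_ascan_um,
             spacing_y_um = volume$spacing_bscan_um)
}

#' RNFL thickness heatmap
#'
#' The en-face thickness map itself (identical values to [thickness_map()]),
#' exportable as a PNG with a fixed color scale for qualitative review.
#'
#' @inheritParams thickness_map
#' @return scalar [enface_map()].
#' @export
heatmap_rnfl <- function(volume, resolve = TRUE) thickness_map(volume, resolve)

#' Export an en-face map as a PNG image
#'
#' Values are mapped linearly onto a fixed color scale from 0 to `max_um`
#' (clamped), so images from different eyes/devices are directly comparable.
#'
#' @param map scalar [enface_map()].
#' @param path output PNG path.
#' @param max_um top of the color scale (default 300 um).
#' @return invisibly, `path`.
#' @export
write_heatmap_png <- function(map, path, max_um = 300) {
  stopifnot(inherits(map, "enface_map"))
  v <- pmin(pmax(map$values / max_um, 0), 1)
  ramp <- grDevices::colorRamp(c("black", "blue", "cyan", "green",
                                 "yellow", "red"))
  rgb <- ramp(as.vector(v)) / 255
  img <- array(rgb, dim = c(dim(v), 3L))
  png::writePNG(img, path)
  invisible(path)
}

# TSNIT sector bins centered on the anatomical axes (degrees, half-open)
.tsnit_bins <- list(
  T  = c(-45,  45),
  TS = c( 45,  85),
  NS = c( 85, 125),
  N  = c(125, 235),
  NI = c(235, 275),
  TI = c(275, 315)
)

# sector name for each TSNIT angle
.tsnit_sector <- function(theta) {
  th <- theta %% 360
  th[th >= 315] <- th[th >= 315] - 360   # T wraps around 0
  out <- character(length(th))
  for (nm in names(.tsnit_bins)) {
    b <- .tsnit_bins[[nm]]
    out[th >= b[1] & th < b[2]] <- nm
  }
  out
}

# clock hour for each TSNIT angle: hour 12 centered at superior (90 deg),
# numbering proceeds nasally; half-open 30-degree bins so every angle falls
# in exactly one hour
.clock_hour <- function(theta) {
  h <- floor(((theta %% 360) - 75) / 30) %% 12
  ifelse(h == 0, 12L, as.integer(h))
}

#' Summarize an angular profile into TSNIT sectors and clock hours
#'
#' Unweighted means of the profile samples per angular bin. TSNIT sector
#' widths: temporal superior 40, nasal superior 40, nasal 110, nasal
#' inferior 40, temporal inferior 40, temporal 90 degrees (bins centered on
#' the T/S/N/I axes); clock hours are 12 bins of 30 degrees with hour 12
#' centered superiorly. Sectors with no defined sample are `NA` and listed in
#' `missing_sectors`.
#'
#' @param profile an [angular_profile()].
#' @param diameter_mm circle diameter the profile was sampled at (carried as
#'   metadata).
#' @param tilt_applied whether the TSNIT axes were tilt-corrected via the
#'   fovea (metadata).
#' @return object of class `sector_summary`: list with `global_mean_um`,
#'   `tsnit` (named numeric, TS/NS/N/NI/TI/T), `clock_hours` (numeric of 12),
#'   `diameter_mm`, `tilt_applied`, `missing_sectors`.
#' @export
sector_summary <- function(profile, diameter_mm = NA_real_,
                           tilt_applied = FALSE) {
  stopifnot(inherits(profile, "angular_profile"))
  th <- profile$angles_deg
  v <- profile$values
  ok <- is.finite(v)
  gm <- if (any(ok)) mean(v[ok]) else NA_real_
  sec <- .tsnit_sector(th)
  tsnit <- vapply(names(.tsnit_bins), function(nm) {
    sel <- sec == nm & ok
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1))
  hr <- .clock_hour(th)
  clock <- vapply(1:12, function(h) {
    sel <- hr == h & ok
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1))
  structure(list(global_mean_um = gm,
                 tsnit = tsnit[c("TS", "NS", "N", "NI", "TI", "T")],
                 clock_hours = stats::setNames(clock, paste0("h", 1:12)),
                 diameter_mm = diameter_mm,
                 tilt_applied = tilt_applied,
                 missing_sectors = names(tsnit)[!is.finite(tsnit)]),
            class = "sector_summary")
}

#' @export
print.sector_summary <- function(x, ...) {
  cat(sprintf("<sector_summary> diameter %.2f mm, global mean %.2f um%s\n",
              x$diameter_mm, x$global_mean_um,
              if (x$tilt_applied) ", tilt-corrected" else ""))
  cat("  TSNIT:",
      paste(sprintf("%s %.1f", names(x$tsnit), x$tsnit), collapse = "  "), "\n")
  invisible(x)
}

#' Circumpapillary RNFL thickness from a cube acquisition
#'
#' Samples the per-A-scan thickness map on a circle of the requested diameter
#' centered on the BMO, and aggregates into TSNIT sector, clock-hour and
#' global means. Typical diameters are 3.4 and 3.5 mm, matching the circles
#' used by raster- and circle-scan devices respectively; both can be
#' requested independently on the same volume.
#'
#' @param volume a cube [label_volume()].
#' @param ellipse the [bmo_ellipse()] (its center anchors the circle).
#' @param diameter_mm circle diameter, mm.
#' @param n_samples samples on the circle (default 720).
#' @param thickness optionally, a precomputed [thickness_map()] to reuse
#'   across diameters.
#' @param transform optional [tsnit_angle_transform()]; defaults to the one
#'   implied by the volume's laterality and fovea metadata.
#' @return list with `profile` ([angular_profile()]) and `summary`
#'   ([sector_summary()]).
#' @export
cprnfl <- function(volume, ellipse, diameter_mm = 3.5, n_samples = 720L,
                   thickness = NULL, transform = NULL) {
  stopifnot(inherits(volume, "label_volume"), inherits(ellipse, "bmo_ellipse"))
  if (volume$acquisition != "cube")
    stop("cprnfl requires a cube acquisition; use cprnfl_from_circular for circle scans",
         call. = FALSE)
  if (is.null(thickness)) thickness <- thickness_map(volume)
  if (is.null(transform))
    transform <- tsnit_angle_transform(volume$laterality, ellipse$center_um,
                                       volume$fovea_enface_um)
  prof <- sample_circle(thickness, ellipse$center_um, diameter_mm,
                        n_samples = n_samples, transform = transform)
  list(profile = prof,
       summary = sector_summary(prof, diameter_mm, transform$tilt_applied))
}

#' Circumpapillary RNFL thickness from a circular B-scan
#'
#' For circle-scan devices the cpRNFL is measured directly on the acquired
#' circular B-scan: per-A-scan thickness (vessels resolved in the slice
#' plane) mapped to TSNIT angles via the scan's start angle and direction
#' metadata, then aggregated exactly like the cube route.
#'
#' @param scan a [circular_slice()].
#' @param scheme the [label_scheme()] of the slice.
#' @param tilt_applied flag carried into the summary metadata.
#' @return list with `profile` and `summary` as in [cprnfl()].
#' @export
cprnfl_from_circular <- function(scan, scheme = default_scheme(),
                                 tilt_applied = FALSE) {
  stopifnot(inherits(scan, "circular_slice"))
  if (is.null(scan$start_angle_deg))
    stop("configuration error: circular scan lacks start-angle metadata",
         call. = FALSE)
  scheme <- .assert_scheme(scheme)
  code_r <- .scheme_codes(scheme, "rnfl")
  code_b <- .scheme_codes(scheme, "background")
  code_v <- .scheme_codes(scheme, "vessel")
  n <- nrow(scan$labels)
  arc_step <- pi * scan$diameter_mm * 1000 / n
  sl <- .resolve_vessels_slice(scan$labels, code_r, code_b, code_v,
                               arc_step, scan$spacing_axial_um)
  thick <- rowSums(sl == code_r) * scan$spacing_axial_um
  theta <- (scan$start_angle_deg + scan$direction * (seq_len(n) - 1) * 360 / n) %% 360
  o <- order(theta)
  prof <- angular_profile(theta[o], thick[o])
  list(profile = prof,
       summary = sector_summary(prof, scan$diameter_mm, tilt_applied))
}

#' Write an angular profile to CSV
#'
#' Columns `angle_deg, value`; `NA` for undefined samples.
#'
#' @param profile an [angular_profile()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "angular_profile"))
  utils::write.csv(data.frame(angle_deg = profile$angles_deg,
                              value = profile$values),
                   path, row.names = FALSE)
  invisible(path)
}
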