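#' BM endpoints of a single B-scan
#'
#' Where a B-scan crosses the BMO, the Bruch's membrane segmentation shows a
#' gap; the endpoints are the innermost BM-bearing columns flanking that gap
#' (the largest interior gap if the segmentation has several), with axial
#' position the mean of the RPE--BM complex extent in the column. Returns
#' `NULL` when the BM band is continuous or present on one side only (no cup
#' contribution).
#'
#' @param bscan_labels 2D integer matrix `(ascan, axial)`.
#' @param scheme the [label_scheme()].
#' @param spacing_ascan_um,spacing_axial_um spacings, um.
#' @return `NULL`, or a list with `left`/`right`, each
#'   `(column, lateral_um, axial_um)`.
#' @export
bm_endpoints <- function(bscan_labels, scheme, spacing_ascan_um,
                         spacing_axial_um) {
  scheme <- .assert_scheme(scheme)
  code_bm <- .scheme_codes(scheme, "rpe_bm")
  has_bm <- rowSums(bscan_labels == code_bm) > 0
  cols <- which(has_bm)
  if (length(cols) < 2L) return(NULL)
  lo <- cols[1L]; hi <- cols[length(cols)]
  inner <- has_bm[lo:hi]
  if (all(inner)) return(NULL)  # continuous band, no gap
  # largest interior run of BM-free columns
  r <- rle(inner)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- which(!r$values)
  g <- gaps[which.max(r$lengths[gaps])]
  left_col <- lo + starts[g] - 2L   # innermost BM column before the gap
  right_col <- lo + ends[g]         # innermost BM column after the gap
  ep <- function(col) {
    kz <- which(bscan_labels[col, ] == code_bm)
    list(column = col, lateral_um = (col - 1) * spacing_ascan_um,
         axial_um = mean((kz - 1) * spacing_axial_um))
  }
  list(left = ep(left_col), right = ep(right_col))
}

#' Cup cross-sectional area of a single B-scan
#'
#' The area enclosed between the chord through the two BM endpoints and the
#' inner tissue surface (ILM over `rnfl`/`vessel`/`prelaminar`): for each
#' column strictly between the endpoints, `max(0, tissue_top - chord)` times
#' the lateral spacing. Tissue shallower than the chord contributes zero (the
#' cup is a volume, not a signed integral); columns with no tissue contribute
#' zero.
#'
#' @param bscan_labels 2D integer matrix `(ascan, axial)`.
#' @param endpoints from [bm_endpoints()].
#' @inheritParams bm_endpoints
#' @return area in mm^2.
#' @export
cup_area <- function(bscan_labels, endpoints, scheme, spacing_ascan_um,
                     spacing_axial_um) {
  if (is.null(endpoints)) return(0)
  scheme <- .assert_scheme(scheme)
  l <- endpoints$left; r <- endpoints$right
  cols <- seq(l$column + 1L, length.out = r$column - l$column - 1L)
  if (!length(cols)) return(0)
  ilm <- ilm_curve(bscan_labels, scheme, spacing_axial_um)[cols]
  lat <- (cols - 1) * spacing_ascan_um
  chord <- l$axial_um + (r$axial_um - l$axial_um) *
    (lat - l$lateral_um) / (r$lateral_um - l$lateral_um)
  depth <- pmax(0, ilm - chord)
  depth[!is.finite(depth)] <- 0
  sum(depth) * spacing_ascan_um * 1e-6   # um^2 -> mm^2
}

#' Cup volume of a cube acquisition
#'
#' Sums the per-B-scan cup areas across the volume:
#' `volume = sum(area_i) * spacing_bscan`. B-scans without a detectable BM
#' gap (outside the BMO, or with obscured endpoints) contribute zero and are
#' counted.
#'
#' @param volume a cube [label_volume()] (vessels need not be resolved; the
#'   tissue-top surface treats vessels as tissue).
#' @param ellipse [bmo_ellipse()]; used only to restrict the search to
#'   B-scans intersecting the BMO (with a margin), so spurious BM gaps far
#'   from the disc are ignored. Optional.
#' @return object of class `cup_result`: `per_bscan` data frame
#'   `(bscan_index, area_mm2)`, `volume_mm3`, `n_bscans_contributing`.
#' @export
cup_volume <- function(volume, ellipse = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  if (volume$acquisition != "cube")
    stop("cup_volume requires a cube acquisition", call. = FALSE)
  d <- dim(volume$labels)
  rows <- seq_len(d[1])
  if (!is.null(ellipse)) {
    y <- (rows - 1) * volume$spacing_bscan_um
    within <- abs(y - ellipse$center_um[2]) <=
      ellipse$semi_major_um + 2 * volume$spacing_bscan_um
    rows <- rows[within]
  }
  areas <- numeric(length(rows))
  for (ii in seq_along(rows)) {
    sl <- volume$labels[rows[ii], , ]
    ep <- bm_endpoints(sl, volume$scheme, volume$spacing_ascan_um,
                       volume$spacing_axial_um)
    areas[ii] <- cup_area(sl, ep, volume$scheme, volume$spacing_ascan_um,
                          volume$spacing_axial_um)
  }
  structure(list(
    per_bscan = data.frame(bscan_index = rows, area_mm2 = areas),
    volume_mm3 = sum(areas) * volume$spacing_bscan_um * 1e-3,  # mm^2 * um -> mm^3
    n_bscans_contributing = sum(areas > 0)
  ), class = "cup_result")
}

#' @export
print.cup_result <- function(x, ...) {
  cat(sprintf("<cup_result> volume %.4f mm^3 from %d contributing B-scans\n",
              x$volume_mm3, x$n_bscans_contributing))
  invisible(x)
}

#' Write per-B-scan cup areas to CSV
#'
#' @param result a `cup_result` from [cup_volume()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cup_csv <- function(result, path) {
  stopifnot(inherits(result, "cup_result"))
  utils::write.csv(result$per_bscan, path, row.names = FALSE)
  invisible(path)
}
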