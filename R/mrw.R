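#' Inner limiting membrane curve of a B-scan slice
#'
#' Per lateral column (A-scan), the shallowest axial position (um) carrying a
#' neural-tissue label (`rnfl`, `vessel` or `prelaminar`): the ILM surface the
#' rim width is measured to. Columns without such a voxel are `NA`.
#'
#' @param labels 2D integer matrix `(lateral, axial)`.
#' @param scheme the [label_scheme()].
#' @param spacing_axial_um axial spacing, um.
#' @return numeric vector of axial positions (um), `NA` where undefined.
#' @export
ilm_curve <- function(labels, scheme, spacing_axial_um) {
  scheme <- .assert_scheme(scheme)
  codes <- .scheme_codes(scheme, c("rnfl", "vessel", "prelaminar"))
  m <- matrix(labels %in% codes, nrow = nrow(labels))
  k <- max.col(m, ties.method = "first")
  found <- m[cbind(seq_len(nrow(m)), k)]
  ifelse(found, (k - 1) * spacing_axial_um, NA_real_)
}

#' BM edge point of a radial slice
#'
#' The Bruch's membrane opening edge on one side of the center column: the
#' innermost (closest to center) lateral column containing the RPE--BM
#' complex, with axial position the mean of the complex's axial extent in
#' that column (the complex is several voxels thick; the edge is taken on the
#' complex, not a sub-layer).
#'
#' @param slice a [radial_slice()].
#' @param side `"left"` (lateral index below center) or `"right"`.
#' @param scheme the [label_scheme()].
#' @return list `(lateral_um, axial_um, column)` with `lateral_um` signed
#'   relative to the center column, or `NULL` when no BM is present on that
#'   side (missing-edge).
#' @export
bm_edge_point <- function(slice, side = c("left", "right"),
                          scheme = default_scheme()) {
  side <- match.arg(side)
  scheme <- .assert_scheme(scheme)
  code_bm <- .scheme_codes(scheme, "rpe_bm")
  n <- nrow(slice$labels)
  cols <- if (side == "left") rev(seq_len(slice$center_offset - 1L))
          else seq(slice$center_offset + 1L, length.out = n - slice$center_offset)
  has_bm <- rowSums(slice$labels == code_bm) > 0
  hit <- cols[has_bm[cols]]
  if (!length(hit)) return(NULL)
  col <- hit[1L]
  kz <- which(slice$labels[col, ] == code_bm)
  list(lateral_um = (col - slice$center_offset) * slice$lateral_step_um,
       axial_um = mean((kz - 1) * slice$spacing_axial_um),
       column = col)
}

#' Minimum rim width for one half-meridian
#'
#' Minimum Euclidean distance, in physical micrometres, from the BM edge
#' point to any defined ILM point on the same side of the slice (the ILM
#' directly above and beyond the edge included).
#'
#' @param edge edge point from [bm_edge_point()].
#' @param ilm ILM curve from [ilm_curve()] (um per lateral column).
#' @param slice the [radial_slice()] both belong to.
#' @param side `"left"` or `"right"`.
#' @return width in um, or `NA` if the ILM is undefined everywhere on the
#'   side.
#' @export
mrw_meridian <- function(edge, ilm, slice, side = c("left", "right")) {
  side <- match.arg(side)
  if (is.null(edge)) return(NA_real_)
  n <- length(ilm)
  cols <- if (side == "left") seq_len(slice$center_offset)
          else seq(slice$center_offset, n)
  lat <- (cols - slice$center_offset) * slice$lateral_step_um
  z <- ilm[cols]
  ok <- is.finite(z)
  if (!any(ok)) return(NA_real_)
  min(sqrt((lat[ok] - edge$lateral_um)^2 + (z[ok] - edge$axial_um)^2))
}

#' BMO minimum rim width
#'
#' Computes the MRW on every half-meridian of a set of radial scans: for cube
#' acquisitions, 24 radial slices are first synthesized through the BMO
#' center ([synthesize_radials()]); for radial/circular acquisitions the
#' acquired radial slices are used directly. Each radial slice yields two
#' half-meridians (at its TSNIT angle and at angle + 180), so the default is
#' 48 width measurements. Half-meridians whose BM edge is not visible are
#' excluded from the means and reported.
#'
#' @param input a cube [label_volume()] or a [radial_circular_set()].
#' @param ellipse [bmo_ellipse()]; required for cube input (measurement
#'   center).
#' @param n_radials radials to synthesize for cube input (default 24).
#' @param transform optional [tsnit_angle_transform()] (cube input).
#' @return object of class `mrw_result`: `per_meridian`
#'   ([angular_profile()], `NA` for missing), `global_mean_um`, `tsnit`
#'   sector means, `n_meridians`, `n_missing`.
#' @export
compute_mrw <- function(input, ellipse = NULL, n_radials = 24L,
                        transform = NULL) {
  if (inherits(input, "label_volume")) {
    if (input$acquisition != "cube")
      stop("label_volume input must be a cube acquisition", call. = FALSE)
    if (is.null(ellipse))
      stop("cube input requires the BMO ellipse (measurement center)",
           call. = FALSE)
    if (is.null(transform))
      transform <- tsnit_angle_transform(input$laterality, ellipse$center_um,
                                         input$fovea_enface_um)
    slices <- synthesize_radials(input, ellipse$center_um, n_radials,
                                 transform = transform)
    scheme <- input$scheme
  } else if (inherits(input, "radial_circular_set")) {
    slices <- input$radial_slices
    scheme <- input$scheme
  } else {
    stop("input must be a label_volume or radial_circular_set", call. = FALSE)
  }

  angles <- numeric(0)
  widths <- numeric(0)
  for (sl in slices) {
    ilm <- ilm_curve(sl$labels, scheme, sl$spacing_axial_um)
    for (side in c("right", "left")) {
      edge <- bm_edge_point(sl, side, scheme)
      w <- mrw_meridian(edge, ilm, sl, side)
      th <- if (side == "right") sl$angle_deg else (sl$angle_deg + 180) %% 360
      angles <- c(angles, th)
      widths <- c(widths, w)
    }
  }
  o <- order(angles)
  prof <- angular_profile(angles[o], widths[o])
  n_missing <- sum(!is.finite(widths))
  if (n_missing > length(widths) / 2)
    stop(structure(class = c("onhmark_quality_error", "error", "condition"),
                   list(message = sprintf(
                     "quality error: %d of %d MRW half-meridians missing",
                     n_missing, length(widths)), call = NULL)))
  ok <- is.finite(widths)
  sec <- .tsnit_sector(angles)
  tsnit <- vapply(names(.tsnit_bins), function(nm) {
    sel <- sec == nm & ok
    if (any(sel)) mean(widths[sel]) else NA_real_
  }, numeric(1))
  structure(list(per_meridian = prof,
                 global_mean_um = mean(widths[ok]),
                 tsnit = tsnit[c("TS", "NS", "N", "NI", "TI", "T")],
                 n_meridians = length(widths),
                 n_missing = n_missing),
            class = "mrw_result")
}

#' @export
print.mrw_result <- function(x, ...) {
  cat(sprintf("<mrw_result> %d half-meridians (%d missing), global mean %.1f um\n",
              x$n_meridians, x$n_missing, x$global_mean_um))
  cat("  TSNIT:",
      paste(sprintf("%s %.1f", names(x$tsnit), x$tsnit), collapse = "  "), "\n")
  invisible(x)
}

#' Write per-meridian MRW widths to CSV
#'
#' Columns `angle_deg, mrw_um, defined`.
#'
#' @param result an `mrw_result` from [compute_mrw()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_mrw_csv <- function(result, path) {
  stopifnot(inherits(result, "mrw_result"))
  utils::write.csv(data.frame(angle_deg = result$per_meridian$angles_deg,
                              mrw_um = result$per_meridian$values,
                              defined = is.finite(result$per_meridian$values)),
                   path, row.names = FALSE)
  invisible(path)
}
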