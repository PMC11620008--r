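#' En-face maps
#'
#' A 2D scalar or binary grid in the fundus plane, indexed
#' `(bscan_index, ascan_index)` like the parent volume, with physical pixel
#' spacings in micrometres and an optional mask of undefined pixels.
#'
#' @param values numeric or logical matrix `(bscan, ascan)`.
#' @param spacing_x_um spacing along ascan (x) direction.
#' @param spacing_y_um spacing along bscan (y) direction.
#' @param undefined optional logical matrix flagging undefined pixels.
#' @return object of class `enface_map`.
#' @export
enface_map <- function(values, spacing_x_um, spacing_y_um, undefined = NULL) {
  stopifnot(is.matrix(values), spacing_x_um > 0, spacing_y_um > 0)
  if (!is.null(undefined)) stopifnot(identical(dim(undefined), dim(values)))
  structure(list(values = values, spacing_x_um = spacing_x_um,
                 spacing_y_um = spacing_y_um, undefined = undefined),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<enface_map> %d x %d (bscan x ascan), %.4g x %.4g um/px, %s\n",
              d[1], d[2], x$spacing_y_um, x$spacing_x_um,
              if (is.logical(x$values)) "binary" else "scalar"))
  invisible(x)
}

#' En-face presence projection
#'
#' Projects a label volume onto the fundus plane: a pixel is `TRUE` iff at
#' least one voxel of its A-scan carries one of the requested labels. This is
#' how the Bruch's membrane footprint (and hence the BMO) is located.
#'
#' @param volume a [label_volume()].
#' @param label_set character vector of class names from the volume's scheme.
#' @return binary [enface_map()].
#' @export
enface_presence <- function(volume, label_set) {
  stopifnot(inherits(volume, "label_volume"))
  codes <- .scheme_codes(volume$scheme, label_set)
  hit <- array(volume$labels %in% codes, dim = dim(volume$labels))
  vals <- rowSums(hit, dims = 2L) > 0
  enface_map(vals, spacing_x_um = volume$spacing_ascan_um,
             spacing_y_um = volume$spacing_bscan_um)
}

#' Angular profiles in TSNIT degrees
#'
#' Values indexed by angle on the circular TSNIT domain: 0 = temporal,
#' 90 = superior, 180 = nasal, 270 = inferior, for either eye.
#'
#' @param angles_deg strictly increasing angles in `[0, 360)`.
#' @param values same length; `NA` where undefined.
#' @return object of class `angular_profile`.
#' @export
angular_profile <- function(angles_deg, values) {
  stopifnot(length(angles_deg) == length(values))
  if (any(angles_deg < 0 | angles_deg >= 360) || is.unsorted(angles_deg, strictly = TRUE))
    stop("angles must be strictly increasing in [0, 360)", call. = FALSE)
  structure(list(angles_deg = as.numeric(angles_deg),
                 values = as.numeric(values)),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("<angular_profile> %d samples, %d defined, mean %.2f\n",
              length(x$values), sum(ok),
              if (any(ok)) mean(x$values[ok]) else NA_real_))
  invisible(x)
}

#' TSNIT angle transform
#'
#' Builds the mapping between en-face geometry and the TSNIT degree
#' convention (0 = temporal, 90 = superior, 180 = nasal, 270 = inferior for
#' both eyes; geometrically counterclockwise in the en-face view for OD,
#' clockwise for OS, so that profiles are directly comparable across eyes).
#'
#' If a fovea position is supplied, the temporal (0 deg) axis is tilted to
#' point along the BMO-center-to-fovea axis, correcting for disc tilt the way
#' radial-scan devices do. Without a fovea the temporal axis falls back to
#' the laterality-implied horizontal and the returned object is flagged.
#'
#' @param laterality `"OD"` or `"OS"`.
#' @param center_um en-face (x, y) of the BMO center, um.
#' @param fovea_um optional en-face (x, y) of the fovea, um.
#' @return a list of class `tsnit_transform` with functions
#'   `to_tsnit(dx, dy)` mapping en-face direction components to TSNIT degrees
#'   and `direction(theta_deg)` mapping TSNIT angles to en-face unit vectors,
#'   plus `tilt_applied`.
#' @export
tsnit_angle_transform <- function(laterality = c("OD", "OS"), center_um,
                                  fovea_um = NULL) {
  laterality <- match.arg(laterality)
  # geometric angle phi: counterclockwise from +x with "up" (-y) at 90 deg
  phi0 <- if (laterality == "OD") 0 else 180  # temporal horizontal
  tilt_applied <- FALSE
  if (!is.null(fovea_um)) {
    dxf <- fovea_um[1] - center_um[1]
    dyf <- fovea_um[2] - center_um[2]
    if (dxf == 0 && dyf == 0)
      stop("degenerate axis: fovea coincides with BMO center", call. = FALSE)
    phi0 <- atan2(-dyf, dxf) * 180 / pi
    tilt_applied <- TRUE
  }
  sgn <- if (laterality == "OD") 1 else -1
  to_tsnit <- function(dx, dy) {
    phi <- atan2(-dy, dx) * 180 / pi
    (sgn * (phi - phi0)) %% 360
  }
  direction <- function(theta_deg) {
    phi <- (phi0 + sgn * theta_deg) * pi / 180
    cbind(dx = cos(phi), dy = -sin(phi))
  }
  structure(list(to_tsnit = to_tsnit, direction = direction,
                 laterality = laterality, center_um = as.numeric(center_um),
                 tilt_applied = tilt_applied),
            class = "tsnit_transform")
}

#' Sample a scalar en-face map on a circle
#'
#' Bilinearly interpolates the map at `n_samples` equally spaced TSNIT angles
#' on the circle of the given diameter around `center_um`. Bilinear
#' interpolation is exact for affine fields. Samples whose interpolation
#' stencil touches an undefined pixel are returned as `NA`.
#'
#' @param map scalar [enface_map()].
#' @param center_um en-face (x, y) circle center, um.
#' @param diameter_mm circle diameter in millimetres.
#' @param n_samples number of samples (>= 8), default 720 (0.5 deg step).
#' @param transform a [tsnit_angle_transform()]; defaults to the identity
#'   (OD, no tilt) transform about `center_um`.
#' @return [angular_profile()] of interpolated values.
#' @export
sample_circle <- function(map, center_um, diameter_mm, n_samples = 720L,
                          transform = NULL) {
  stopifnot(inherits(map, "enface_map"), n_samples >= 8L)
  if (is.null(transform))
    transform <- tsnit_angle_transform("OD", center_um)
  theta <- seq(0, 360, length.out = n_samples + 1L)[seq_len(n_samples)]
  dir <- transform$direction(theta)
  r <- diameter_mm * 1000 / 2
  px <- center_um[1] + r * dir[, "dx"]
  py <- center_um[2] + r * dir[, "dy"]
  vals <- .bilinear(map, px, py, diameter_mm)
  angular_profile(theta, vals)
}

# bilinear interpolation of an enface_map at en-face um positions
.bilinear <- function(map, px, py, diameter_mm = NA) {
  d <- dim(map$values)
  fx <- px / map$spacing_x_um   # 0-based fractional ascan index
  fy <- py / map$spacing_y_um
  if (any(fx < 0 | fx > d[2] - 1 | fy < 0 | fy > d[1] - 1))
    stop(sprintf("circle (diameter %s mm) exits the en-face extent",
                 format(diameter_mm)), call. = FALSE)
  x0 <- pmin(floor(fx), d[2] - 2); x1 <- x0 + 1
  y0 <- pmin(floor(fy), d[1] - 2); y1 <- y0 + 1
  wx <- fx - x0; wy <- fy - y0
  v <- map$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]  # (bscan=y, ascan=x), 1-based
  out <- (1 - wy) * ((1 - wx) * idx(y0, x0) + wx * idx(y0, x1)) +
         wy * ((1 - wx) * idx(y1, x0) + wx * idx(y1, x1))
  if (!is.null(map$undefined)) {
    u <- map$undefined
    bad <- u[cbind(y0 + 1L, x0 + 1L)] | u[cbind(y0 + 1L, x1 + 1L)] |
           u[cbind(y1 + 1L, x0 + 1L)] | u[cbind(y1 + 1L, x1 + 1L)]
    out[bad] <- NA_real_
  }
  out
}

#' Synthesize radial B-scans from a cube acquisition
#'
#' Resamples a raster cube into `n_radials` radial slices through a center
#' point, emulating the radial acquisition pattern of circle/radial devices
#' so that rim-width measurements are taken identically on every device.
#' Slice `k` lies at TSNIT angle `(k - 1) * 180 / n_radials`; labels are
#' sampled by nearest neighbor in the en-face plane (labels are categorical),
#' with lateral step `min(spacing_ascan_um, spacing_bscan_um)`.
#'
#' @param volume a cube [label_volume()].
#' @param center_um en-face (x, y) of the BMO center, um.
#' @param n_radials number of radial slices (default 24).
#' @param transform optional [tsnit_angle_transform()]; defaults to the
#'   laterality-horizontal transform about `center_um`.
#' @param half_length_um half-length of each slice; defaults to the largest
#'   radius keeping all slices inside the en-face extent.
#' @return list of [radial_slice()] objects.
#' @export
synthesize_radials <- function(volume, center_um, n_radials = 24L,
                               transform = NULL, half_length_um = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  ext_x <- (d[2] - 1) * volume$spacing_ascan_um
  ext_y <- (d[1] - 1) * volume$spacing_bscan_um
  if (center_um[1] < 0 || center_um[1] > ext_x ||
      center_um[2] < 0 || center_um[2] > ext_y)
    stop("center outside the en-face extent", call. = FALSE)
  if (is.null(transform))
    transform <- tsnit_angle_transform(volume$laterality, center_um)
  step <- min(volume$spacing_ascan_um, volume$spacing_bscan_um)
  if (is.null(half_length_um))
    half_length_um <- min(center_um[1], ext_x - center_um[1],
                          center_um[2], ext_y - center_um[2])
  m <- floor(half_length_um / step)
  s <- seq(-m, m) * step
  angles <- (seq_len(n_radials) - 1) * 180 / n_radials
  lapply(angles, function(th) {
    dir <- transform$direction(th)
    px <- center_um[1] + s * dir[1, "dx"]
    py <- center_um[2] + s * dir[1, "dy"]
    j <- round(px / volume$spacing_ascan_um) + 1L
    i <- round(py / volume$spacing_bscan_um) + 1L
    j <- pmin(pmax(j, 1L), d[2]); i <- pmin(pmax(i, 1L), d[1])
    sl <- matrix(volume$labels[cbind(rep(i, d[3]), rep(j, d[3]),
                                     rep(seq_len(d[3]), each = length(s)))],
                 nrow = length(s), ncol = d[3])
    radial_slice(th, sl, lateral_step_um = step,
                 spacing_axial_um = volume$spacing_axial_um,
                 center_offset = m + 1L, provenance = "synthesized")
  })
}
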