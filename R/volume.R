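#' Segmentation label volumes
#'
#' The universal input of the pipeline: a 3D integer array of tissue-class
#' codes indexed `(bscan, ascan, axial)` with axial index increasing with
#' depth (vitreous toward choroid), plus the physical voxel spacings in
#' micrometres, the eye laterality and the acquisition pattern.
#'
#' All geometry downstream is done in physical micrometres because OCT voxels
#' are strongly anisotropic (typical cube scans: 30 um laterally, ~3 um
#' axially). En-face coordinates are `x = (ascan_index - 1) * spacing_ascan_um`
#' and `y = (bscan_index - 1) * spacing_bscan_um`, origin at voxel (1,1);
#' axial depth `z = (axial_index - 1) * spacing_axial_um`.
#'
#' @param labels 3D integer array `(bscan, ascan, axial)`.
#' @param spacing_bscan_um,spacing_ascan_um,spacing_axial_um positive voxel
#'   spacings in micrometres.
#' @param laterality `"OD"` (right) or `"OS"` (left eye).
#' @param acquisition `"cube"` (raster volume) or `"radial_circular"`.
#' @param scheme a [label_scheme()]; defaults to [default_scheme()].
#' @param fovea_enface_um optional length-2 numeric, en-face (x, y) position
#'   of the fovea in micrometres, used for disc-tilt correction of the TSNIT
#'   axes.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_bscan_um, spacing_ascan_um,
                         spacing_axial_um, laterality = c("OD", "OS"),
                         acquisition = c("cube", "radial_circular"),
                         scheme = default_scheme(), fovea_enface_um = NULL) {
  laterality <- match.arg(laterality)
  acquisition <- match.arg(acquisition)
  scheme <- .assert_scheme(scheme)
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array (bscan, ascan, axial)", call. = FALSE)
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("format error: non-integer voxel data", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  sp <- c(spacing_bscan_um, spacing_ascan_um, spacing_axial_um)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("all spacings must be positive and finite", call. = FALSE)
  codes <- sort(unique(as.vector(labels)))
  unknown <- setdiff(codes, as.integer(scheme))
  if (length(unknown))
    stop("format error: voxel code(s) not in scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(fovea_enface_um)) {
    fovea_enface_um <- as.numeric(fovea_enface_um)
    if (length(fovea_enface_um) != 2L || any(!is.finite(fovea_enface_um)))
      stop("fovea_enface_um must be a finite (x, y) pair", call. = FALSE)
  }
  structure(list(
    labels = labels,
    spacing_bscan_um = spacing_bscan_um,
    spacing_ascan_um = spacing_ascan_um,
    spacing_axial_um = spacing_axial_um,
    laterality = laterality,
    acquisition = acquisition,
    scheme = scheme,
    fovea_enface_um = fovea_enface_um
  ), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<label_volume> %d x %d x %d (bscan x ascan x axial), %s, %s\n",
    d[1], d[2], d[3], x$laterality, x$acquisition))
  cat(sprintf("  spacings (um): bscan %.4g, ascan %.4g, axial %.4g\n",
              x$spacing_bscan_um, x$spacing_ascan_um, x$spacing_axial_um))
  cat(sprintf("  en-face extent: %.2f x %.2f mm, depth %.2f mm\n",
              (d[2] - 1) * x$spacing_ascan_um / 1000,
              (d[1] - 1) * x$spacing_bscan_um / 1000,
              (d[3] - 1) * x$spacing_axial_um / 1000))
  if (!is.null(x$fovea_enface_um))
    cat(sprintf("  fovea at (%.0f, %.0f) um\n",
                x$fovea_enface_um[1], x$fovea_enface_um[2]))
  invisible(x)
}

.sidecar_required <- c("spacing_bscan_um", "spacing_ascan_um",
                       "spacing_axial_um", "laterality", "acquisition")

#' Read a label volume and its JSON metadata sidecar
#'
#' Accepts NIfTI (`.nii` / `.nii.gz`) or multipage TIFF volumes. TIFF pages
#' are B-scans stored as (axial rows x ascan columns) images of integer codes.
#' The sidecar declares the voxel spacings, laterality, acquisition type and
#' (optionally) a non-default label scheme and fovea position:
#' `{"spacing_bscan_um": ..., "spacing_ascan_um": ..., "spacing_axial_um": ...,
#'   "laterality": "OD", "acquisition": "cube", "labels": {"background": 0, ...},
#'   "fovea_enface_um": [x, y]}`.
#'
#' @param path volume file (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param sidecar_path JSON sidecar; defaults to `path` with the extension
#'   replaced by `.json`.
#' @return a validated [label_volume()].
#' @export
read_label_volume <- function(path, sidecar_path = NULL) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.(nii(\\.gz)?|tiff?)$", "", path), ".json")
  if (!file.exists(sidecar_path))
    stop("configuration error: sidecar not found: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar_path)
  missing <- setdiff(.sidecar_required, names(meta))
  if (length(missing))
    stop("configuration error: sidecar missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  scheme <- if (!is.null(meta$labels))
    label_scheme(unlist(meta$labels)) else default_scheme()

  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- as.array(RNifti::readNifti(path))
    if (length(dim(img)) != 3L)
      stop("format error: expected a 3D NIfTI volume", call. = FALSE)
    arr <- array(as.vector(img), dim = dim(img))  # plain array, no NIfTI attrs
  } else if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # page = B-scan image, rows = axial (top of image = vitreous), cols = ascan
    arr <- array(0L, dim = c(length(pages), ncol(pages[[1]]), nrow(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- t(pages[[i]])
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  if (any(arr != round(arr)))
    stop("format error: non-integer voxel data", call. = FALSE)
  storage.mode(arr) <- "integer"

  vol <- label_volume(
    arr,
    spacing_bscan_um = as.numeric(meta$spacing_bscan_um),
    spacing_ascan_um = as.numeric(meta$spacing_ascan_um),
    spacing_axial_um = as.numeric(meta$spacing_axial_um),
    laterality = meta$laterality,
    acquisition = meta$acquisition,
    scheme = scheme,
    fovea_enface_um = if (!is.null(meta$fovea_enface_um))
      as.numeric(meta$fovea_enface_um) else NULL
  )
  attr(vol, "source") <- path
  vol
}

#' Write a label volume plus its JSON sidecar
#'
#' @param volume a [label_volume()].
#' @param path output file; format chosen from the extension (`.nii`,
#'   `.nii.gz` or `.tif`/`.tiff`).
#' @param sidecar_path JSON sidecar path; defaults to `path` with `.json`.
#' @return invisibly, the volume path.
#' @export
write_label_volume <- function(volume, path, sidecar_path = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.(nii(\\.gz)?|tiff?)$", "", path), ".json")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(volume$labels, path)
  } else if (grepl("\\.tiff?$", path)) {
    d <- dim(volume$labels)
    # 16-bit container; codes are small non-negative integers
    pages <- lapply(seq_len(d[1]), function(i)
      t(volume$labels[i, , ]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  meta <- list(
    spacing_bscan_um = volume$spacing_bscan_um,
    spacing_ascan_um = volume$spacing_ascan_um,
    spacing_axial_um = volume$spacing_axial_um,
    laterality = volume$laterality,
    acquisition = volume$acquisition,
    labels = as.list(stats::setNames(as.integer(volume$scheme),
                                     names(volume$scheme)))
  )
  if (!is.null(volume$fovea_enface_um))
    meta$fovea_enface_um <- volume$fovea_enface_um
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Radial + circular acquisition sets
#'
#' Container for devices that acquire radial B-scans through the disc center
#' plus circular B-scans at fixed diameters (e.g. 24 radials and circles at
#' 3.5 / 4.1 / 4.7 mm), instead of a raster cube.
#'
#' @param radial_slices list of [radial_slice()] objects, angles distinct in
#'   `[0, 180)`.
#' @param circular_slices list of circular slices as returned by
#'   [circular_slice()].
#' @param laterality `"OD"` or `"OS"`.
#' @param scheme a [label_scheme()].
#' @return an object of class `radial_circular_set`.
#' @export
radial_circular_set <- function(radial_slices, circular_slices = list(),
                                laterality = c("OD", "OS"),
                                scheme = default_scheme()) {
  laterality <- match.arg(laterality)
  scheme <- .assert_scheme(scheme)
  ang <- vapply(radial_slices, function(s) s$angle_deg, numeric(1))
  if (anyDuplicated(ang) || any(ang < 0 | ang >= 180))
    stop("radial angles must be distinct and in [0, 180)", call. = FALSE)
  dm <- vapply(circular_slices, function(s) s$diameter_mm, numeric(1))
  if (length(dm) && any(dm <= 0))
    stop("circular diameters must be positive", call. = FALSE)
  structure(list(radial_slices = radial_slices,
                 circular_slices = circular_slices,
                 laterality = laterality, scheme = scheme),
            class = "radial_circular_set")
}

#' Radial B-scan slice
#'
#' A single radial B-scan through (or near) the BMO center: a 2D label array
#' indexed `(radial_position, axial)` with the lateral sampling step and the
#' column index of the center.
#'
#' @param angle_deg TSNIT angle of the positive lateral direction, in
#'   `[0, 180)`.
#' @param labels 2D integer matrix `(radial_position, axial)`.
#' @param lateral_step_um,spacing_axial_um positive spacings (um).
#' @param center_offset column index (1-based) of the BMO-center column.
#' @param provenance `"synthesized"` or `"acquired"`.
#' @return an object of class `radial_slice`.
#' @export
radial_slice <- function(angle_deg, labels, lateral_step_um, spacing_axial_um,
                         center_offset, provenance = c("synthesized", "acquired")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(labels), lateral_step_um > 0, spacing_axial_um > 0)
  if (center_offset < 1 || center_offset > nrow(labels))
    stop("center_offset outside the slice", call. = FALSE)
  structure(list(angle_deg = angle_deg, labels = labels,
                 lateral_step_um = lateral_step_um,
                 spacing_axial_um = spacing_axial_um,
                 center_offset = center_offset, provenance = provenance),
            class = "radial_slice")
}

#' Circular B-scan slice
#'
#' A circular B-scan around the disc center, unrolled into a 2D label array
#' indexed `(position_along_circle, axial)`. Columns map to TSNIT angles via
#' `start_angle_deg` and `direction`.
#'
#' @param diameter_mm circle diameter.
#' @param labels 2D integer matrix `(position, axial)`.
#' @param spacing_axial_um axial spacing (um).
#' @param start_angle_deg TSNIT angle of the first column.
#' @param direction `+1` for increasing TSNIT angle along columns, `-1` for
#'   decreasing.
#' @return an object of class `circular_slice`.
#' @export
circular_slice <- function(diameter_mm, labels, spacing_axial_um,
                           start_angle_deg = 0, direction = 1L) {
  stopifnot(is.matrix(labels), diameter_mm > 0, spacing_axial_um > 0,
            direction %in% c(-1L, 1L))
  structure(list(diameter_mm = diameter_mm, labels = labels,
                 spacing_axial_um = spacing_axial_um,
                 start_angle_deg = start_angle_deg,
                 direction = as.integer(direction)),
            class = "circular_slice")
}
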