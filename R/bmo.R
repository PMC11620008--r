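#' Fitted BMO ellipse
#'
#' The Bruch's membrane opening is summarized by the ellipse fitted to its
#' en-face boundary: center (the anchor of all circumpapillary and radial
#' measurements), semi-axes, rotation, and area `pi * a * b` in mm^2.
#'
#' @param center_um (x, y) en-face center, um.
#' @param semi_major_um,semi_minor_um semi-axes, um (`major >= minor > 0`).
#' @param rotation_deg major-axis angle in `[0, 180)`, en-face degrees.
#' @return object of class `bmo_ellipse`.
#' @export
bmo_ellipse <- function(center_um, semi_major_um, semi_minor_um, rotation_deg) {
  if (!(semi_major_um >= semi_minor_um && semi_minor_um > 0))
    stop("require semi_major >= semi_minor > 0", call. = FALSE)
  structure(list(center_um = as.numeric(center_um),
                 semi_major_um = semi_major_um,
                 semi_minor_um = semi_minor_um,
                 rotation_deg = rotation_deg %% 180,
                 area_mm2 = pi * semi_major_um * semi_minor_um * 1e-6),
            class = "bmo_ellipse")
}

#' @export
print.bmo_ellipse <- function(x, ...) {
  cat(sprintf(
    "<bmo_ellipse> center (%.1f, %.1f) um, a %.1f um, b %.1f um, rot %.1f deg, area %.4f mm^2\n",
    x$center_um[1], x$center_um[2], x$semi_major_um, x$semi_minor_um,
    x$rotation_deg, x$area_mm2))
  invisible(x)
}

#' Bruch's membrane presence map
#'
#' En-face footprint used to delineate the BMO: presence of the RPE--BM
#' complex *including* alpha- and beta-zone peripapillary atrophy (where those
#' labels exist in the scheme). Gamma-zone PPA, which lies inside the opening,
#' counts as absence.
#'
#' @param volume a [label_volume()].
#' @return binary [enface_map()].
#' @export
bm_presence_map <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  set <- c("rpe_bm",
           intersect(c("ppa_alpha", "ppa_beta"), names(volume$scheme)))
  enface_presence(volume, set)
}

#' Close the BM map and extract the BMO boundary
#'
#' Applies a morphological closing (disk structuring element) to the binary
#' BM presence map to correct minor segmentation errors, finds the interior
#' hole (= the BMO), and returns its boundary as an ordered sub-pixel contour
#' in en-face micrometres (marching-squares 0.5-level isocontour, so the
#' boundary runs midway between the last hole pixel and the first BM pixel).
#'
#' Foreground (BM) components smaller than the structuring element are
#' removed before the closing: the disk radius defines the scale of "minor
#' errors", and isolated specks below that scale would otherwise be inflated
#' by the dilation step instead of corrected. If several interior holes
#' remain after closing, the largest is kept and a `"multiple_holes"` warning
#' flag is attached.
#'
#' @param map binary [enface_map()] (BM presence).
#' @param closing_radius_px disk radius in en-face pixels (default 3).
#' @return two-column matrix `(x_um, y_um)` of ordered boundary points, with
#'   attribute `warnings` (character vector).
#' @export
close_and_boundary <- function(map, closing_radius_px = 3L) {
  stopifnot(inherits(map, "enface_map"), is.logical(map$values))
  warn <- character(0)
  m <- map$values
  if (closing_radius_px > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
    # drop BM specks below the correction scale before the closing
    fg <- EBImage::bwlabel(m)
    sz <- tabulate(fg[fg > 0])
    keep <- which(sz >= sum(kern))
    m <- matrix(fg %in% keep, nrow(m))
    m <- EBImage::closing(m * 1, kern) > 0.5
  }
  # interior holes: background components not touching the map border
  comp <- EBImage::bwlabel(!m)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  ids <- setdiff(unique(as.vector(comp)), c(0, border_ids))
  if (!length(ids))
    stop("no BMO found: BM projection has no interior hole", call. = FALSE)
  sizes <- vapply(ids, function(id) sum(comp == id), numeric(1))
  if (length(ids) > 1L)
    warn <- c(warn, "multiple_holes")
  hole <- comp == ids[which.max(sizes)]

  nr <- nrow(hole); nc <- ncol(hole)
  # contourLines: z[i, j] is the value at x[i], y[j]; our rows are bscan (y)
  cl <- grDevices::contourLines(
    x = (seq_len(nr) - 1) * map$spacing_y_um,
    y = (seq_len(nc) - 1) * map$spacing_x_um,
    z = hole * 1, levels = 0.5)
  if (!length(cl))
    stop("no BMO found: hole has no traceable boundary", call. = FALSE)
  shoelace <- function(x, y)
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  areas <- vapply(cl, function(g) shoelace(g$x, g$y), numeric(1))
  g <- cl[[which.max(areas)]]
  pts <- cbind(x_um = g$y, y_um = g$x)
  attr(pts, "warnings") <- warn
  pts
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D boundary points by the algebraic direct
#' least-squares method with the built-in ellipse constraint
#' (`4ac - b^2 = 1`), using the numerically stable block decomposition of
#' Halir & Flusser. Unlike an unconstrained conic fit, the result is
#' guaranteed to be an ellipse. The fit is exact on noise-free ellipse points
#' and equivariant under scaling of the coordinates.
#'
#' @param points two-column matrix `(x, y)`, at least 6 non-collinear points.
#' @return a [bmo_ellipse()].
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6L)
    stop("ellipse fit requires at least 6 points", call. = FALSE)
  if (any(!is.finite(points)))
    stop("ellipse fit: non-finite points", call. = FALSE)
  # normalize for conditioning; the fit is equivariant so this is lossless
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  sc <- mean(sqrt((points[, 1] - mx)^2 + (points[, 2] - my)^2))
  if (sc == 0) stop("degenerate point configuration", call. = FALSE)
  x <- (points[, 1] - mx) / sc
  y <- (points[, 2] - my) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration (collinear points?)", call. = FALSE))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)  # inv(C) %*% M
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok))
    stop("ellipse fit failed: no admissible solution", call. = FALSE)
  a1 <- evec[, ok[1]]
  coefs <- c(a1, as.vector(Tm %*% a1))  # (a, b, c, d, e, f) in normalized frame

  # back to original coordinates: substitute x -> (x - mx)/sc, y -> (y - my)/sc
  A <- coefs[1] / sc^2
  B <- coefs[2] / sc^2
  C <- coefs[3] / sc^2
  D <- coefs[4] / sc - 2 * coefs[1] * mx / sc^2 - coefs[2] * my / sc^2
  E <- coefs[5] / sc - 2 * coefs[3] * my / sc^2 - coefs[2] * mx / sc^2
  F <- coefs[1] * mx^2 / sc^2 + coefs[2] * mx * my / sc^2 +
    coefs[3] * my^2 / sc^2 - coefs[4] * mx / sc - coefs[5] * my / sc + coefs[6]

  den <- 4 * A * C - B^2
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  Fc <- F + (D * cx + E * cy) / 2
  Mq <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Mq, symmetric = TRUE)
  ax2 <- -Fc / eq$values
  if (any(ax2 <= 0))
    stop("ellipse fit failed: degenerate conic", call. = FALSE)
  semi <- sqrt(ax2)             # eigen returns decreasing values -> semi increasing? no:
  # larger eigenvalue -> smaller axis; eq$values is decreasing, so semi is increasing
  i_major <- which.max(semi)
  vmaj <- eq$vectors[, i_major]
  rot <- (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180
  bmo_ellipse(center_um = c(cx, cy),
              semi_major_um = max(semi), semi_minor_um = min(semi),
              rotation_deg = rot)
}

#' Detect the Bruch's membrane opening
#'
#' Composition of [bm_presence_map()], [close_and_boundary()] and
#' [fit_ellipse()]: the fitted ellipse defines the disc margin, its area the
#' BMO area, and its center anchors all circumpapillary and radial
#' measurements downstream.
#'
#' @param volume a cube-acquisition [label_volume()].
#' @param closing_radius_px disk radius for the morphological closing.
#' @return a [bmo_ellipse()] with attribute `warnings`.
#' @export
detect_bmo <- function(volume, closing_radius_px = 3L) {
  stopifnot(inherits(volume, "label_volume"))
  map <- bm_presence_map(volume)
  if (!any(map$values))
    stop("no BMO found: volume contains no RPE-BM complex", call. = FALSE)
  pts <- close_and_boundary(map, closing_radius_px)
  ell <- fit_ellipse(pts)
  attr(ell, "warnings") <- attr(pts, "warnings")
  ell
}
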