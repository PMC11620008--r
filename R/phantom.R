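#' Synthetic ONH phantom specification
#'
#' Parametric description of a synthetic optic-nerve-head segmentation
#' volume with analytically known biomarkers. The default mimics a raster
#' cube protocol over 6 x 6 mm (200 x 200 A-scans) with 2 mm depth at
#' 3.125 um axial spacing, an elliptical BMO, a sinusoidal RNFL thickness
#' field, a flat BM complex, a paraboloid cup and vessel tubes inside the
#' RNFL band.
#'
#' Continuous geometry (all depths in um, z increasing toward the choroid):
#' * outer retina (outside the BMO ellipse): RNFL from `ilm_um` down to
#'   `ilm_um + t(theta)` with `t(theta) = rnfl_t0_um + rnfl_amp_um *
#'   sin(2 theta)` in TSNIT degrees; BM complex from `bm_um` to
#'   `bm_um + bm_thickness_um`.
#' * inside the BMO: prelaminar tissue whose top continues the ILM plane
#'   over the rim annulus and drops into an elliptic-paraboloid cup (semi-axes
#'   `cup_frac` times the BMO's, depth `cup_depth_um` below the BM-center
#'   chord), so the cup volume is `pi * a_c * b_c * h / 2` in closed form.
#' * optional alpha/beta/gamma PPA annuli just inside the BM edge, as ring
#'   fractions of the normalized elliptical radius.
#'
#' Ground truth is computed from these continuous parameters, never from the
#' raster, so extraction error can be separated from discretization error.
#' The default ILM and BM depths sit at half-voxel phase of the reference
#' axial grid (k + 0.5 times 3.125 um): a voxel sampled at its position
#' represents the interval extending half a spacing to either side, so
#' half-phase surfaces make voxel counting an unbiased measure of slab
#' extent at the reference resolution.
#'
#' @param n_bscans,n_ascans,n_axial grid size.
#' @param spacing_bscan_um,spacing_ascan_um,spacing_axial_um voxel spacings.
#' @param laterality `"OD"` or `"OS"`.
#' @param center_um BMO ellipse center (x, y), um.
#' @param semi_major_um,semi_minor_um,rotation_deg BMO ellipse.
#' @param ilm_um outer ILM depth.
#' @param rnfl_t0_um,rnfl_amp_um RNFL thickness field parameters.
#' @param bm_um,bm_thickness_um BM complex slab.
#' @param cup_frac,cup_depth_um cup semi-axis fraction and depth below chord.
#' @param prelaminar_bottom_um bottom of the prelaminar tissue.
#' @param vessels list of vessel tubes; each
#'   `list(angle_deg, r_start_um, radius_lateral_um, radius_axial_um)` with
#'   `angle_deg` geometric en-face degrees. `NULL` for the default four
#'   arcade-like tubes; `list()` for none.
#' @param ppa_alpha_frac,ppa_beta_frac,ppa_gamma_frac PPA annulus widths as
#'   fractions of normalized elliptical radius (0 = absent).
#' @param label_flip_rate voxel-level label-flip noise rate.
#' @param bm_projection_flip_rate en-face BM-pattern flip rate.
#' @param boundary_jitter_px BMO boundary jitter SD in en-face pixels.
#' @param fovea_um optional fovea position (x, y), um.
#' @param seed RNG seed for the noise components.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_bscans = 200L, n_ascans = 200L, n_axial = 640L,
                         spacing_bscan_um = 6000 / 200,
                         spacing_ascan_um = 6000 / 200,
                         spacing_axial_um = 2000 / 640,
                         laterality = "OD",
                         center_um = c(3000, 3000),
                         semi_major_um = 900, semi_minor_um = 600,
                         rotation_deg = 30,
                         ilm_um = 601.5625,
                         rnfl_t0_um = 100, rnfl_amp_um = 30,
                         bm_um = 848.4375, bm_thickness_um = 25,
                         cup_frac = 0.35, cup_depth_um = 400,
                         prelaminar_bottom_um = 1500,
                         vessels = NULL,
                         ppa_alpha_frac = 0, ppa_beta_frac = 0,
                         ppa_gamma_frac = 0,
                         label_flip_rate = 0, bm_projection_flip_rate = 0,
                         boundary_jitter_px = 0,
                         fovea_um = NULL, seed = 1L) {
  if (is.null(vessels))
    vessels <- lapply(c(70, 110, 250, 290), function(a)
      list(angle_deg = a, r_start_um = 1.1 * semi_major_um,
           radius_lateral_um = 60, radius_axial_um = 25))
  spec <- list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    n_axial = as.integer(n_axial),
    spacing_bscan_um = spacing_bscan_um, spacing_ascan_um = spacing_ascan_um,
    spacing_axial_um = spacing_axial_um,
    laterality = laterality, center_um = as.numeric(center_um),
    semi_major_um = semi_major_um, semi_minor_um = semi_minor_um,
    rotation_deg = rotation_deg, ilm_um = ilm_um,
    rnfl_t0_um = rnfl_t0_um, rnfl_amp_um = rnfl_amp_um,
    bm_um = bm_um, bm_thickness_um = bm_thickness_um,
    cup_frac = cup_frac, cup_depth_um = cup_depth_um,
    prelaminar_bottom_um = prelaminar_bottom_um,
    vessels = vessels,
    ppa_alpha_frac = ppa_alpha_frac, ppa_beta_frac = ppa_beta_frac,
    ppa_gamma_frac = ppa_gamma_frac,
    label_flip_rate = label_flip_rate,
    bm_projection_flip_rate = bm_projection_flip_rate,
    boundary_jitter_px = boundary_jitter_px,
    fovea_um = if (!is.null(fovea_um)) as.numeric(fovea_um) else NULL,
    seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  ext_x <- (spec$n_ascans - 1) * spec$spacing_ascan_um
  ext_y <- (spec$n_bscans - 1) * spec$spacing_bscan_um
  ext_z <- (spec$n_axial - 1) * spec$spacing_axial_um
  a <- spec$semi_major_um
  if (spec$center_um[1] - a < 0 || spec$center_um[1] + a > ext_x ||
      spec$center_um[2] - a < 0 || spec$center_um[2] + a > ext_y)
    stop("phantom spec error: BMO ellipse exceeds the en-face extent",
         call. = FALSE)
  zmax <- max(spec$ilm_um + spec$rnfl_t0_um + abs(spec$rnfl_amp_um),
              spec$bm_um + spec$bm_thickness_um,
              spec$bm_um + spec$bm_thickness_um / 2 + spec$cup_depth_um,
              spec$prelaminar_bottom_um)
  if (spec$ilm_um <= 0 || zmax >= ext_z)
    stop("phantom spec error: surfaces exceed the axial extent", call. = FALSE)
  if (spec$semi_minor_um <= 0 || spec$semi_major_um < spec$semi_minor_um)
    stop("phantom spec error: require semi_major >= semi_minor > 0",
         call. = FALSE)
  rates <- c(spec$label_flip_rate, spec$bm_projection_flip_rate)
  if (any(rates < 0 | rates >= 1))
    stop("phantom spec error: noise rates must be in [0, 1)", call. = FALSE)
  invisible(spec)
}

# per-column continuous fields at en-face positions (x, y) in um
.phantom_fields <- function(spec, x, y) {
  tr <- tsnit_angle_transform(spec$laterality, spec$center_um, spec$fovea_um)
  dx <- x - spec$center_um[1]; dy <- y - spec$center_um[2]
  phi <- spec$rotation_deg * pi / 180
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  q <- (u / spec$semi_major_um)^2 + (v / spec$semi_minor_um)^2
  rho <- sqrt(q)
  ac <- spec$cup_frac * spec$semi_major_um
  bc <- spec$cup_frac * spec$semi_minor_um
  qc <- (u / ac)^2 + (v / bc)^2
  theta <- tr$to_tsnit(dx, dy)
  t_rnfl <- spec$rnfl_t0_um + spec$rnfl_amp_um * sin(2 * theta * pi / 180)
  z_chord <- spec$bm_um + spec$bm_thickness_um / 2
  cup_top <- z_chord + spec$cup_depth_um * pmax(0, 1 - qc)
  # vessel tubes: per-column lateral offset from each tube axis
  vessel_halfwidth <- NULL
  if (length(spec$vessels)) {
    vessel_halfwidth <- matrix(0, nrow = length(x), ncol = length(spec$vessels))
    rad <- sqrt(dx^2 + dy^2)
    for (vi in seq_along(spec$vessels)) {
      vv <- spec$vessels[[vi]]
      av <- vv$angle_deg * pi / 180
      ex <- cos(av); ey <- -sin(av)     # geometric angle, "up" = -y
      along <- dx * ex + dy * ey
      perp <- abs(-dx * ey + dy * ex)
      inside <- along >= vv$r_start_um & perp < vv$radius_lateral_um
      hw <- rep(0, length(x))
      hw[inside] <- vv$radius_axial_um *
        sqrt(1 - (perp[inside] / vv$radius_lateral_um)^2)
      vessel_halfwidth[, vi] <- hw
    }
  }
  list(q = q, rho = rho, qc = qc, theta = theta, t_rnfl = t_rnfl,
       cup_top = cup_top, z_chord = z_chord,
       vessel_halfwidth = vessel_halfwidth,
       z_mid = spec$ilm_um + t_rnfl / 2)
}

# rasterize columns: label matrix (n_columns x n_axial); voxel k carries the
# label of the continuous field at depth z = (k - 1) * spacing_axial_um
.fill_labels <- function(spec, fields, scheme = default_scheme()) {
  nzi <- spec$n_axial
  sz <- spec$spacing_axial_um
  ncol_ <- length(fields$q)
  out <- matrix(scheme[["background"]], nrow = ncol_, ncol = nzi)
  outside <- fields$q >= 1
  rim <- !outside & fields$qc >= 1
  cup <- fields$qc < 1
  rho_e <- 1 - spec$ppa_alpha_frac - spec$ppa_beta_frac
  rho_g <- rho_e - spec$ppa_gamma_frac
  in_alpha <- !outside & fields$rho >= 1 - spec$ppa_alpha_frac
  in_beta <- !outside & !in_alpha & fields$rho >= rho_e
  in_gamma <- !outside & !in_alpha & !in_beta & fields$rho >= rho_g
  rnfl_top <- spec$ilm_um; bm_top <- spec$bm_um
  bm_bot <- spec$bm_um + spec$bm_thickness_um
  nv <- if (is.null(fields$vessel_halfwidth)) 0L else ncol(fields$vessel_halfwidth)
  for (k in seq_len(nzi)) {
    z <- (k - 1) * sz
    lab <- rep.int(scheme[["background"]], ncol_)
    in_band <- outside & z >= rnfl_top & z < rnfl_top + fields$t_rnfl
    lab[in_band] <- scheme[["rnfl"]]
    if (nv) {
      for (vi in seq_len(nv)) {
        hw <- fields$vessel_halfwidth[, vi]
        vs <- in_band & hw > 0 & abs(z - fields$z_mid) <= hw
        lab[vs] <- scheme[["vessel"]]
      }
    }
    in_bm <- z >= bm_top & z < bm_bot
    if (any(in_bm)) {
      lab[outside & in_bm] <- scheme[["rpe_bm"]]
      if (spec$ppa_alpha_frac > 0) lab[in_alpha & in_bm] <- scheme[["ppa_alpha"]]
      if (spec$ppa_beta_frac > 0) lab[in_beta & in_bm] <- scheme[["ppa_beta"]]
      if (spec$ppa_gamma_frac > 0) lab[in_gamma & in_bm] <- scheme[["ppa_gamma"]]
    }
    pl <- (rim & z >= spec$ilm_um | cup & z >= fields$cup_top) &
      z < spec$prelaminar_bottom_um
    lab[pl] <- scheme[["prelaminar"]]
    out[, k] <- lab
  }
  out
}

#' Generate a synthetic ONH phantom volume
#'
#' Rasterizes the continuous phantom geometry onto the requested grid and
#' returns both the [label_volume()] and the analytic [phantom_truth()]
#' object. Deterministic given the spec (noise components use the spec's
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([label_volume()]) and `truth`
#'   (see [phantom_truth()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .validate_phantom_spec(spec)
  scheme <- default_scheme()
  i <- rep(seq_len(spec$n_bscans), times = spec$n_ascans)
  j <- rep(seq_len(spec$n_ascans), each = spec$n_bscans)
  x <- (j - 1) * spec$spacing_ascan_um
  y <- (i - 1) * spec$spacing_bscan_um
  fields <- .phantom_fields(spec, x, y)
  m <- .fill_labels(spec, fields, scheme)
  arr <- array(m, dim = c(spec$n_bscans, spec$n_ascans, spec$n_axial))
  vol <- label_volume(arr,
                      spacing_bscan_um = spec$spacing_bscan_um,
                      spacing_ascan_um = spec$spacing_ascan_um,
                      spacing_axial_um = spec$spacing_axial_um,
                      laterality = spec$laterality, acquisition = "cube",
                      scheme = scheme, fovea_enface_um = spec$fovea_um)
  if (spec$label_flip_rate > 0 || spec$bm_projection_flip_rate > 0 ||
      spec$boundary_jitter_px > 0)
    vol <- perturb(vol, label_flip_rate = spec$label_flip_rate,
                   bm_projection_flip_rate = spec$bm_projection_flip_rate,
                   boundary_jitter_px = spec$boundary_jitter_px,
                   seed = spec$seed)
  list(volume = vol, truth = phantom_truth(spec))
}

#' Analytic ground truth of a phantom
#'
#' Biomarker values computed from the continuous phantom parameters (never
#' from the raster):
#' * `bmo_area_mm2 = pi * a * b * rho_e^2` where `rho_e` shrinks the
#'   effective boundary when alpha/beta PPA annuli are present (they count as
#'   BM for the opening);
#' * `cprnfl_global_um = t0` and `cprnfl_sector_um(theta_lo, theta_hi)`, the
#'   exact bin average of the sinusoidal thickness field;
#' * `mrw_um(theta)`, brute-force certified over a dense sampling of the
#'   continuous ILM along each meridian (for the default geometry this equals
#'   the BM-center depth minus the ILM depth, independent of meridian);
#' * `cup_volume_mm3 = pi * a_c * b_c * h / 2` (paraboloid volume).
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_truth`.
#' @export
phantom_truth <- function(spec) {
  rho_e <- 1 - spec$ppa_alpha_frac - spec$ppa_beta_frac
  a <- spec$semi_major_um; b <- spec$semi_minor_um
  z_chord <- spec$bm_um + spec$bm_thickness_um / 2
  cprnfl_sector_um <- function(theta_lo, theta_hi) {
    al <- theta_lo * pi / 180; bh <- theta_hi * pi / 180
    spec$rnfl_t0_um + spec$rnfl_amp_um * (cos(2 * al) - cos(2 * bh)) /
      (2 * (bh - al))
  }
  mrw_um <- function(theta_deg, ds_um = 0.5) {
    vapply(theta_deg, function(th) {
      # meridian geometry in the radial plane through the BMO center
      tr <- tsnit_angle_transform(spec$laterality, spec$center_um,
                                  spec$fovea_um)
      dir <- tr$direction(th)
      phi <- spec$rotation_deg * pi / 180
      du <- dir[1, "dx"] * cos(phi) + dir[1, "dy"] * sin(phi)
      dv <- -dir[1, "dx"] * sin(phi) + dir[1, "dy"] * cos(phi)
      r1 <- 1 / sqrt((du / a)^2 + (dv / b)^2)  # boundary radius (rho = 1)
      redge <- rho_e * r1
      rc <- spec$cup_frac * r1
      s <- seq(0, 1.5 * r1, by = ds_um)
      qc <- (s / rc)^2
      top <- ifelse(qc < 1, z_chord + spec$cup_depth_um * (1 - qc),
                    spec$ilm_um)
      min(sqrt((s - redge)^2 + (top - z_chord)^2))
    }, numeric(1))
  }
  structure(list(
    bmo_area_mm2 = pi * a * b * rho_e^2 * 1e-6,
    bmo_center_um = spec$center_um,
    cprnfl_global_um = spec$rnfl_t0_um,
    cprnfl_sector_um = cprnfl_sector_um,
    mrw_um = mrw_um,
    mrw_global_um = mean(mrw_um(seq(0, 352.5, by = 7.5))),
    cup_volume_mm3 = pi * (spec$cup_frac^2 * a * b) * spec$cup_depth_um / 2 * 1e-9,
    z_chord_um = z_chord,
    spec = spec
  ), class = "phantom_truth")
}

#' Derive a radial + circular acquisition from the continuous phantom
#'
#' Emulates a radial/circle-scan device viewing the same eye as the cube
#' protocol: slices are sampled from the continuous phantom definition (not
#' from the cube raster), so the two acquisition routes share geometry but
#' not discretization.
#'
#' @param spec a [phantom_spec()].
#' @param n_radials number of radial slices (default 24).
#' @param diameters_mm circular scan diameters (default 3.5, 4.1, 4.7 mm).
#' @param n_circle_ascans A-scans per circular B-scan (default 720).
#' @param half_length_um radial slice half-length (default 2500 um).
#' @return a [radial_circular_set()].
#' @export
derive_radial_set <- function(spec, n_radials = 24L,
                              diameters_mm = c(3.5, 4.1, 4.7),
                              n_circle_ascans = 720L,
                              half_length_um = 2500) {
  stopifnot(inherits(spec, "phantom_spec"))
  scheme <- default_scheme()
  tr <- tsnit_angle_transform(spec$laterality, spec$center_um, spec$fovea_um)
  step <- min(spec$spacing_ascan_um, spec$spacing_bscan_um)
  m <- floor(half_length_um / step)
  s <- seq(-m, m) * step
  ext_x <- (spec$n_ascans - 1) * spec$spacing_ascan_um
  ext_y <- (spec$n_bscans - 1) * spec$spacing_bscan_um
  radials <- lapply((seq_len(n_radials) - 1) * 180 / n_radials, function(th) {
    dir <- tr$direction(th)
    x <- spec$center_um[1] + s * dir[1, "dx"]
    y <- spec$center_um[2] + s * dir[1, "dy"]
    fields <- .phantom_fields(spec, x, y)
    radial_slice(th, .fill_labels(spec, fields, scheme),
                 lateral_step_um = step,
                 spacing_axial_um = spec$spacing_axial_um,
                 center_offset = m + 1L, provenance = "acquired")
  })
  circles <- lapply(diameters_mm, function(d) {
    r <- d * 1000 / 2
    theta <- (seq_len(n_circle_ascans) - 1) * 360 / n_circle_ascans
    dir <- tr$direction(theta)
    x <- spec$center_um[1] + r * dir[, "dx"]
    y <- spec$center_um[2] + r * dir[, "dy"]
    if (any(x < 0 | x > ext_x | y < 0 | y > ext_y))
      stop(sprintf("circle (diameter %g mm) outside the grid", d),
           call. = FALSE)
    fields <- .phantom_fields(spec, x, y)
    circular_slice(d, .fill_labels(spec, fields, scheme),
                   spacing_axial_um = spec$spacing_axial_um,
                   start_angle_deg = 0, direction = 1L)
  })
  radial_circular_set(radials, circles, laterality = spec$laterality,
                      scheme = scheme)
}

#' Apply seeded noise to a label volume
#'
#' Three independent, reproducible noise components:
#' * `label_flip_rate`: each voxel is replaced, with this probability, by a
#'   label drawn uniformly from the other labels of the scheme's required
#'   set (voxel-level annotation noise);
#' * `bm_projection_flip_rate`: each en-face pixel of the filled BM footprint
#'   toggles its BM presence with this probability (spurious BM inside the
#'   opening, pinholes in the BM band) -- the error mode the morphological
#'   closing corrects;
#' * `boundary_jitter_px`: the BMO boundary is displaced by per-pixel
#'   Gaussian noise on the signed distance to the boundary (SD in en-face
#'   pixels).
#'
#' @param volume a [label_volume()].
#' @param label_flip_rate,bm_projection_flip_rate rates in `[0, 1)`.
#' @param boundary_jitter_px SD in pixels.
#' @param seed RNG seed.
#' @return a perturbed [label_volume()].
#' @export
perturb <- function(volume, label_flip_rate = 0, bm_projection_flip_rate = 0,
                    boundary_jitter_px = 0, seed = 1L) {
  stopifnot(inherits(volume, "label_volume"))
  if (any(c(label_flip_rate, bm_projection_flip_rate) < 0) ||
      any(c(label_flip_rate, bm_projection_flip_rate) >= 1))
    stop("noise rates must be in [0, 1)", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lab <- volume$labels
  scheme <- volume$scheme

  if (label_flip_rate > 0) {
    n <- length(lab)
    idx <- which(stats::runif(n) < label_flip_rate)
    if (length(idx)) {
      # replace by a uniformly drawn *different* label from the required set
      codes <- unname(scheme[.required_labels])
      rank_cur <- match(lab[idx], codes)
      rank_cur[is.na(rank_cur)] <- 1L   # optional-label voxels: any other code
      pick_idx <- sample.int(length(codes) - 1L, length(idx), replace = TRUE)
      new_idx <- pick_idx + (pick_idx >= rank_cur)
      lab[idx] <- codes[new_idx]
    }
  }

  if (bm_projection_flip_rate > 0 || boundary_jitter_px > 0) {
    vol_tmp <- volume; vol_tmp$labels <- lab
    pm <- bm_presence_map(vol_tmp)$values
    comp <- EBImage::bwlabel(!pm)
    border_ids <- unique(c(comp[1, ], comp[nrow(comp), ],
                           comp[, 1], comp[, ncol(comp)]))
    hole <- matrix(comp > 0 & !(comp %in% border_ids), nrow(comp))
    domain <- pm | hole
    target <- pm
    if (boundary_jitter_px > 0) {
      d_to_bm <- sqrt(edt_sq(domain & !hole, 1, 1))
      d_to_hole <- sqrt(edt_sq(hole, 1, 1))
      sgn_dist <- ifelse(hole, d_to_bm, -d_to_hole)   # >0 inside the hole
      noise <- matrix(stats::rnorm(length(pm), 0, boundary_jitter_px),
                      nrow(pm))
      near <- domain & abs(sgn_dist) <= 4 * boundary_jitter_px
      new_inside_hole <- (sgn_dist + noise) > 0
      target[near] <- !new_inside_hole[near]
    }
    if (bm_projection_flip_rate > 0) {
      flip <- matrix(stats::runif(length(pm)) < bm_projection_flip_rate,
                     nrow(pm)) & domain
      target <- xor(target, flip)
    }
    lab <- .apply_bm_pattern(lab, pm, target, scheme)
  }

  out <- volume
  out$labels <- lab
  out
}

# rewrite columns whose BM presence must change; spurious BM is inserted at
# the volume's median BM slab depth
.apply_bm_pattern <- function(lab, pm, target, scheme) {
  code_bm <- scheme[["rpe_bm"]]
  code_bg <- scheme[["background"]]
  changed <- which(pm != target)
  if (!length(changed)) return(lab)
  d <- dim(lab)
  # axial extent of the BM slab, for inserting spurious BM
  k_idx <- rep(seq_len(d[3]), each = d[1] * d[2])
  kk <- k_idx[which(lab == code_bm)]
  if (!length(kk)) return(lab)
  k_lo <- min(kk); k_hi <- max(kk)
  rc <- arrayInd(changed, d[1:2])
  for (r in seq_len(nrow(rc))) {
    i <- rc[r, 1]; j <- rc[r, 2]
    if (target[i, j]) {
      lab[i, j, k_lo:k_hi] <- code_bm
    } else {
      col <- lab[i, j, ]
      col[col == code_bm] <- code_bg
      lab[i, j, ] <- col
    }
  }
  lab
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

#' Read / write phantom specs as JSON
#'
#' @param path JSON file.
#' @return [phantom_spec()] (for `read_phantom_spec`).
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  args <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  do.call(phantom_spec, args)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}
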