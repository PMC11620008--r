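# shared fixtures: small phantoms and hand-built label volumes

# quarter-resolution phantom spec over the same 6 x 6 x 2 mm field of view
small_spec <- function(...) {
  phantom_spec(n_bscans = 100L, n_ascans = 100L, n_axial = 320L,
               spacing_bscan_um = 60, spacing_ascan_um = 60,
               spacing_axial_um = 6.25, ...)
}

# coarse spec for CLI round trips (fast to rasterize and write)
coarse_spec <- function(...) {
  phantom_spec(n_bscans = 60L, n_ascans = 60L, n_axial = 160L,
               spacing_bscan_um = 100, spacing_ascan_um = 100,
               spacing_axial_um = 12.5, ...)
}

# cache expensive shared objects across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_phantom <- function() cached("small_phantom", make_phantom(small_spec()))

# a minimal hand-built volume: flat RNFL slab + BM plane with an elliptical
# hole, no vessels; dimensions (nb x na x nz)
slab_volume <- function(nb = 40, na = 40, nz = 40,
                        sy = 150, sx = 150, sz = 10,
                        rnfl_k = NULL, bm_k = NULL,
                        hole = NULL, laterality = "OD") {
  if (is.null(rnfl_k)) rnfl_k <- seq(max(2, round(nz * 0.1)), round(nz * 0.3))
  if (is.null(bm_k)) bm_k <- seq(round(nz * 0.6), min(nz, round(nz * 0.6) + 2))
  arr <- array(0L, dim = c(nb, na, nz))
  arr[, , rnfl_k] <- 1L
  arr[, , bm_k] <- 3L
  if (!is.null(hole)) {
    # hole: list(cx, cy, rx, ry) in pixel units
    for (i in seq_len(nb)) for (j in seq_len(na)) {
      if (((j - hole$cx) / hole$rx)^2 + ((i - hole$cy) / hole$ry)^2 < 1)
        arr[i, j, bm_k] <- 0L
    }
  }
  label_volume(arr, spacing_bscan_um = sy, spacing_ascan_um = sx,
               spacing_axial_um = sz, laterality = laterality,
               acquisition = "cube")
}

# independent mean-squares oracle for ICC(A,1) via stats::aov
icc_a1_oracle <- function(tab, conf_level = 0.95) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  list(icc = icc,
       lo = n * (MSR - FL * MSE) /
         (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
       hi = n * (FU * MSR - MSE) /
         (k * MSC + (k * n - k - n) * MSE + n * FU * MSR))
}

# TSNIT sector bins used for truth computations in tests
tsnit_bins <- list(T = c(-45, 45), TS = c(45, 85), NS = c(85, 125),
                   N = c(125, 235), NI = c(235, 275), TI = c(275, 315))
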