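test_that("enface presence marks exactly the A-scans carrying the label", {
  arr <- array(0L, dim = c(8, 9, 10))
  vol <- label_volume(arr, 30, 30, 3, "OD", "cube")
  expect_false(any(enface_presence(vol, "rpe_bm")$values))

  arr[3, 7, 5] <- 3L
  vol <- label_volume(arr, 30, 30, 3, "OD", "cube")
  m <- enface_presence(vol, "rpe_bm")$values
  expect_true(m[3, 7])
  expect_equal(sum(m), 1L)

  expect_error(enface_presence(vol, "optic_cup"), "not in scheme")
})

test_that("sample_circle is exact on constant and affine maps", {
  nx <- 101
  xs <- (seq_len(nx) - 1) * 30
  const <- enface_map(matrix(100, nx, nx), 30, 30)
  center <- c(1500, 1500)
  p <- sample_circle(const, center, diameter_mm = 2.0, n_samples = 64)
  expect_equal(p$values, rep(100, 64), tolerance = 1e-12)

  # affine map t(x, y) = 7 + 0.02 x - 0.013 y
  vals <- outer(xs, xs, function(y, x) 7 + 0.02 * x - 0.013 * y)
  aff <- enface_map(vals, 30, 30)
  tr <- tsnit_angle_transform("OD", center)
  p <- sample_circle(aff, center, 2.4, n_samples = 360, transform = tr)
  dir <- tr$direction(p$angles_deg)
  expected <- 7 + 0.02 * (center[1] + 1200 * dir[, "dx"]) -
    0.013 * (center[2] + 1200 * dir[, "dy"])
  expect_equal(p$values, unname(expected), tolerance = 1e-12)
  # linearity + symmetry: full-circle mean equals the center value
  expect_equal(mean(p$values), 7 + 0.02 * center[1] - 0.013 * center[2],
               tolerance = 1e-10)
})

test_that("sampling a painted sinusoid recovers the closed form and its bin means", {
  # fine 10-um grid so interpolation error is negligible
  n <- 601
  xs <- (seq_len(n) - 1) * 10
  center <- c(3000, 3000)
  tr <- tsnit_angle_transform("OD", center)
  gx <- matrix(rep(xs, each = n), n)
  gy <- matrix(rep(xs, times = n), n)
  theta <- tr$to_tsnit(gx - center[1], gy - center[2])
  vals <- 100 + 30 * sin(2 * theta * pi / 180)
  map <- enface_map(vals, 10, 10)
  p <- sample_circle(map, center, 3.5, n_samples = 720, transform = tr)
  truth <- 100 + 30 * sin(2 * p$angles_deg * pi / 180)
  expect_lt(max(abs(p$values - truth)), 1)

  s <- sector_summary(p, 3.5)
  for (nm in names(tsnit_bins)) {
    b <- tsnit_bins[[nm]]
    oracle <- stats::integrate(function(th) 100 + 30 * sin(2 * th * pi / 180),
                               b[1], b[2])$value / (b[2] - b[1])
    expect_lt(abs(s$tsnit[[nm]] - oracle), 1)
  }
})

test_that("circle exiting the map is an out-of-bounds error naming the diameter", {
  m <- enface_map(matrix(1, 20, 20), 30, 30)
  expect_error(sample_circle(m, c(300, 300), diameter_mm = 3.5), "3.5")
})

test_that("TSNIT transform: laterality, fovea tilt and degenerate axis", {
  center <- c(3000, 3000)
  # OD, fovea exactly temporal-horizontal (+x): identity rotation
  tr <- tsnit_angle_transform("OD", center, fovea_um = c(5000, 3000))
  expect_true(tr$tilt_applied)
  expect_equal(tr$to_tsnit(1, 0), 0)
  expect_equal(tr$to_tsnit(0, -1), 90)  # up = superior
  expect_equal(tr$to_tsnit(-1, 0), 180)

  # fovea 10 degrees below the temporal horizontal: all angles shift by 10
  dyf <- tan(10 * pi / 180) * 2000
  tr10 <- tsnit_angle_transform("OD", center, fovea_um = c(5000, 3000 + dyf))
  expect_equal(tr10$to_tsnit(1, 0), 10, tolerance = 1e-9)
  expect_equal((tr10$to_tsnit(0, -1) - tr$to_tsnit(0, -1)) %% 360, 10,
               tolerance = 1e-9)

  # no fovea: laterality fallback, flagged
  tr_od <- tsnit_angle_transform("OD", center)
  expect_false(tr_od$tilt_applied)
  expect_equal(tr_od$to_tsnit(1, 0), 0)
  tr_os <- tsnit_angle_transform("OS", center)
  expect_equal(tr_os$to_tsnit(-1, 0), 0)   # temporal is -x for OS
  expect_equal(tr_os$to_tsnit(0, -1), 90)  # superior is up for both eyes

  expect_error(tsnit_angle_transform("OD", center, fovea_um = center),
               "degenerate")
})

test_that("mirroring a volume OD<->OS yields identical TSNIT profiles", {
  n <- 101
  xs <- (seq_len(n) - 1) * 30
  center <- c(1500, 1500)
  gx <- matrix(rep(xs, each = n), n)
  gy <- matrix(rep(xs, times = n), n)
  trOD <- tsnit_angle_transform("OD", center)
  theta <- trOD$to_tsnit(gx - center[1], gy - center[2])
  vals <- 100 + 30 * sin(2 * theta * pi / 180) + 5 * cos(theta * pi / 180)
  map <- enface_map(vals, 30, 30)
  pOD <- sample_circle(map, center, 2.4, n_samples = 180, transform = trOD)

  mir <- enface_map(vals[, rev(seq_len(n))], 30, 30)  # mirror x
  trOS <- tsnit_angle_transform("OS", center)
  pOS <- sample_circle(mir, center, 2.4, n_samples = 180, transform = trOS)
  expect_equal(pOS$values, pOD$values, tolerance = 1e-9)
})

test_that("synthesize_radials: count, angles, axis-aligned identity, symmetry", {
  ph <- small_phantom()
  vol <- ph$volume
  center <- ph$truth$bmo_center_um
  rads <- synthesize_radials(vol, center, n_radials = 24)
  expect_length(rads, 24)
  expect_equal(vapply(rads, function(s) s$angle_deg, numeric(1)),
               (0:23) * 7.5)
  expect_equal(rads[[1]]$lateral_step_um,
               min(vol$spacing_ascan_um, vol$spacing_bscan_um))

  # radial at 0 degrees of an OD volume runs along +x: it equals the B-scan
  # row through the center (same lateral step here)
  r0 <- rads[[1]]
  i_c <- round(center[2] / vol$spacing_bscan_um) + 1L
  j_c <- round(center[1] / vol$spacing_ascan_um) + 1L
  m <- r0$center_offset - 1L
  row <- vol$labels[i_c, (j_c - m):(j_c + m), ]
  expect_identical(r0$labels, row)

  # rotationally symmetric phantom: per-label voxel fractions agree across
  # slices to < 2%
  spec <- small_spec(semi_major_um = 750, semi_minor_um = 750,
                     rnfl_amp_um = 0, vessels = list())
  vol2 <- make_phantom(spec)$volume
  rads2 <- synthesize_radials(vol2, spec$center_um, n_radials = 24)
  frac <- sapply(rads2, function(s)
    vapply(c(1L, 3L, 4L), function(code) mean(s$labels == code), numeric(1)))
  expect_lt(max(apply(frac, 1, function(f) diff(range(f)))), 0.02)

  expect_error(synthesize_radials(vol, c(-10, 3000)), "outside")
})
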