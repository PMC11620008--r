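# small volume with one vessel voxel in a configurable neighborhood
vessel_fixture <- function(fill) {
  arr <- array(0L, dim = c(3, 9, 9))
  fill(arr)
}

test_that("vessel voxels resolve to the nearest annotation; ties go to rnfl", {
  # fully enclosed by rnfl -> rnfl
  arr <- array(0L, dim = c(3, 7, 7))
  arr[2, 3:5, 3:5] <- 1L
  arr[2, 4, 4] <- 2L
  v <- label_volume(arr, 30, 30, 30, "OD", "cube")
  out <- resolve_vessels(v)
  expect_equal(out$labels[2, 4, 4], 1L)
  expect_false(any(out$labels == 2L))

  # surrounded by background -> background
  arr2 <- array(0L, dim = c(3, 7, 7))
  arr2[2, 4, 4] <- 2L
  arr2[2, 1, 1] <- 1L  # distant rnfl
  v2 <- label_volume(arr2, 30, 30, 30, "OD", "cube")
  expect_equal(resolve_vessels(v2)$labels[2, 4, 4], 0L)

  # vessel column spanning the ILM, rnfl below and background above, with an
  # exact tie at the midpoint voxel -> rnfl
  arr3 <- array(0L, dim = c(1, 3, 9))
  arr3[1, 2, 4:6] <- 2L   # vessel column
  arr3[1, 2, 7:9] <- 1L   # rnfl below
  # background above (axial 1:3); voxel 5 is equidistant (2 voxels each way)
  v3 <- label_volume(arr3, 30, 30, 10, "OD", "cube")
  out3 <- resolve_vessels(v3)
  expect_equal(out3$labels[1, 2, 5], 1L)   # tie -> rnfl
  expect_equal(out3$labels[1, 2, 4], 0L)   # nearer background
  expect_equal(out3$labels[1, 2, 6], 1L)   # nearer rnfl
})

test_that("resolution uses physical anisotropic distances within the B-scan", {
  # vessel 1 column from rnfl laterally (30 um) and 2 voxels from background
  # axially; with 10-um axial spacing the background (20 um) wins
  arr <- array(0L, dim = c(1, 5, 7))
  arr[1, 2, 5] <- 2L            # vessel, background directly above and below
  arr[1, 3, 5] <- 1L            # rnfl 30 um away laterally
  v <- label_volume(arr, 30, 30, 10, "OD", "cube")
  expect_equal(resolve_vessels(v)$labels[1, 2, 5], 0L)  # 10 < 30

  # same geometry with 40-um axial spacing: rnfl (30 um lateral) wins
  v2 <- label_volume(arr, 30, 30, 40, "OD", "cube")
  expect_equal(resolve_vessels(v2)$labels[1, 2, 5], 1L)
})

test_that("resolution conserves voxel counts", {
  set.seed(11)
  arr <- array(sample(0:2, 4 * 20 * 30, replace = TRUE), dim = c(4, 20, 30))
  v <- label_volume(arr, 30, 30, 5, "OD", "cube")
  out <- resolve_vessels(v)
  expect_false(any(out$labels == 2L))
  expect_equal(sum(out$labels == 1L) + sum(out$labels == 0L),
               sum(arr %in% 0:2))
})

test_that("thickness is rnfl voxel count times axial spacing", {
  arr <- array(0L, dim = c(2, 3, 40))
  arr[1, 1, 6:30] <- 1L                  # 25 voxels
  arr[1, 2, 6:30] <- 1L
  arr[1, 2, 11:15] <- 2L                 # 5 enclosed vessel voxels
  v <- label_volume(arr, 30, 30, 4, "OD", "cube")
  tm <- thickness_map(v)
  expect_equal(tm$values[1, 1], 100)     # 25 x 4
  expect_equal(tm$values[1, 2], 100)     # vessels resolved into the count
  expect_equal(tm$values[2, 3], 0)       # all-background A-scan

  # monotonicity: adding rnfl voxels never decreases the map value
  arr2 <- arr
  arr2[1, 1, 31:33] <- 1L
  v2 <- label_volume(arr2, 30, 30, 4, "OD", "cube")
  expect_true(all(thickness_map(v2)$values >= tm$values))
})

test_that("sector and clock-hour aggregation recombine to the global mean", {
  set.seed(3)
  p <- angular_profile((0:719) / 2, 100 + rnorm(720, 0, 15))
  s <- sector_summary(p, 3.5)
  widths <- c(TS = 40, NS = 40, N = 110, NI = 40, TI = 40, T = 90)
  expect_equal(sum(widths[names(s$tsnit)] / 360 * s$tsnit),
               s$global_mean_um, tolerance = 1e-9)
  expect_equal(mean(s$clock_hours), s$global_mean_um, tolerance = 1e-12)
})

test_that("cpRNFL on a uniform phantom is flat across sectors and diameters", {
  spec <- small_spec(rnfl_amp_um = 0, vessels = list())
  ph <- cached("uniform_phantom", make_phantom(spec))
  ell <- detect_bmo(ph$volume)
  th <- thickness_map(ph$volume)
  for (d in c(3.4, 3.5)) {
    res <- cprnfl(ph$volume, ell, d, thickness = th)
    expect_equal(unname(res$summary$tsnit), rep(100, 6),
                 tolerance = spec$spacing_axial_um / 100)
    expect_equal(res$summary$diameter_mm, d)
  }
})

test_that("circular-scan route: constant slices, direction parity, metadata error", {
  # uniform circular slice -> constant profile
  sl <- matrix(0L, nrow = 360, ncol = 60)
  sl[, 11:30] <- 1L
  cs <- circular_slice(3.5, sl, spacing_axial_um = 5, start_angle_deg = 0)
  res <- cprnfl_from_circular(cs)
  expect_equal(res$profile$values, rep(100, 360))

  # direction flag reversed: profile reversed about the temporal axis
  sl2 <- matrix(0L, nrow = 360, ncol = 120)
  sl2[, 11:30] <- 1L
  extra <- round(30 * (1 + sin((0:359) * pi / 180)))
  for (i in 1:360) if (extra[i] > 0) sl2[i, 31:(30 + extra[i])] <- 1L
  cs_f <- circular_slice(3.5, sl2, 5, start_angle_deg = 0, direction = 1L)
  cs_r <- circular_slice(3.5, sl2, 5, start_angle_deg = 0, direction = -1L)
  pf <- cprnfl_from_circular(cs_f)$profile
  pr <- cprnfl_from_circular(cs_r)$profile
  idx_rev <- c(1, 360:2)   # theta -> -theta mod 360
  expect_equal(pr$values, pf$values[idx_rev])

  cs_bad <- cs
  cs_bad$start_angle_deg <- NULL
  expect_error(cprnfl_from_circular(cs_bad), "configuration error")
})

test_that("heatmap equals the thickness map and exports a valid PNG", {
  ph <- small_phantom()
  hm <- heatmap_rnfl(ph$volume)
  tm <- thickness_map(ph$volume)
  expect_identical(hm$values, tm$values)
  path <- file.path(tempdir(), "heat.png")
  write_heatmap_png(hm, path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], dim(hm$values))
})
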