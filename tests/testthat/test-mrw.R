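test_that("ILM curve is the shallowest neural-tissue voxel per column", {
  sc <- default_scheme()
  m <- matrix(0L, nrow = 5, ncol = 20)
  m[1:4, 11:15] <- 1L            # rnfl slab, top at axial index 11 (0-based 10)
  m[2, 8:10] <- 4L               # prelaminar above rnfl in column 2
  ilm <- ilm_curve(m, sc, spacing_axial_um = 3)
  expect_equal(ilm[1], 30)       # (11 - 1) * 3
  expect_equal(ilm[2], 21)       # follows the prelaminar top
  expect_true(is.na(ilm[5]))     # pure background column
})

test_that("BM edge point: innermost column, mean axial, missing side flagged", {
  sc <- default_scheme()
  m <- matrix(0L, nrow = 41, ncol = 30)
  m[1:10, 20:23] <- 3L           # BM band ending 10 columns left of center 21
  sl <- radial_slice(0, m, lateral_step_um = 90, spacing_axial_um = 4,
                     center_offset = 21L)
  e <- bm_edge_point(sl, "left", sc)
  expect_equal(e$lateral_um, (10 - 21) * 90)    # -990 um
  expect_equal(e$axial_um, mean((20:23 - 1) * 4))
  expect_null(bm_edge_point(sl, "right", sc))

  # one-column gap before the true end: the innermost BM column wins
  m2 <- m
  m2[9, ] <- 0L
  sl2 <- radial_slice(0, m2, 90, 4, 21L)
  expect_equal(bm_edge_point(sl2, "left", sc)$lateral_um, (10 - 21) * 90)
})

test_that("mrw_meridian: plane distance, 3-4-5 triangle, brute-force equality", {
  sc <- default_scheme()
  # flat ILM 250 um above the edge, extending past it laterally
  m <- matrix(0L, nrow = 41, ncol = 80)
  m[1:15, 51:55] <- 3L                    # BM, mean axial 520 um
  m[1:25, 26:40] <- 1L                    # rnfl slab, top at 250 um
  sl <- radial_slice(0, m, lateral_step_um = 50, spacing_axial_um = 10,
                     center_offset = 21L)
  ilm <- ilm_curve(m, sc, 10)
  e <- bm_edge_point(sl, "left", sc)
  expect_equal(e$axial_um, 520)
  expect_equal(mrw_meridian(e, ilm, sl, "left"), 520 - 250)

  # single ILM point at lateral offset 300, axial offset 400 -> 500 um
  m2 <- matrix(0L, nrow = 41, ncol = 80)
  m2[15, 51:55] <- 3L                     # edge at column 15, axial 520
  m2[9, 13] <- 1L                         # lateral (9-15)*50 = -300, axial 120
  sl2 <- radial_slice(0, m2, 50, 10, 21L)
  ilm2 <- ilm_curve(m2, sc, 10)
  e2 <- bm_edge_point(sl2, "left", sc)
  expect_equal(mrw_meridian(e2, ilm2, sl2, "left"), 500)

  # brute-force oracle over every ILM pixel on phantom meridians
  ph <- small_phantom()
  sls <- synthesize_radials(ph$volume, ph$truth$bmo_center_um, 6)
  for (sl in sls) {
    ilm <- ilm_curve(sl$labels, sc, sl$spacing_axial_um)
    for (side in c("left", "right")) {
      e <- bm_edge_point(sl, side, sc)
      w <- mrw_meridian(e, ilm, sl, side)
      cols <- if (side == "left") seq_len(sl$center_offset)
              else seq(sl$center_offset, nrow(sl$labels))
      best <- Inf
      for (cc in cols) {
        if (!is.finite(ilm[cc])) next
        lat <- (cc - sl$center_offset) * sl$lateral_step_um
        best <- min(best, sqrt((lat - e$lateral_um)^2 +
                                 (ilm[cc] - e$axial_um)^2))
      }
      expect_equal(w, best)
    }
  }
})

test_that("mrw invariants: anisotropy scaling, monotone response, contact -> 0", {
  sc <- default_scheme()
  m <- matrix(0L, nrow = 41, ncol = 80)
  m[15, 51:55] <- 3L
  m[9, 13] <- 1L
  sl <- radial_slice(0, m, 50, 10, 21L)
  w1 <- mrw_meridian(bm_edge_point(sl, "left", sc),
                     ilm_curve(m, sc, 10), sl, "left")
  sl2 <- radial_slice(0, m, 50, 20, 21L)   # doubled axial spacing
  w2 <- mrw_meridian(bm_edge_point(sl2, "left", sc),
                     ilm_curve(m, sc, 20), sl2, "left")
  # axial contribution doubles exactly for a fixed voxel configuration
  expect_equal(sqrt(w2^2 - 300^2), 2 * sqrt(w1^2 - 300^2))

  # dilating the ILM toward the BM edge never increases the width
  m3 <- m
  m3[14, 50] <- 1L   # new ILM point much closer to the edge
  sl3 <- radial_slice(0, m3, 50, 10, 21L)
  w3 <- mrw_meridian(bm_edge_point(sl3, "left", sc),
                     ilm_curve(m3, sc, 10), sl3, "left")
  expect_lte(w3, w1)

  # ILM touching the BM edge: width 0
  m4 <- matrix(0L, nrow = 21, ncol = 30)
  m4[5, 10] <- 3L; m4[5, 12] <- 3L   # BM mean axial = index 11
  m4[5, 11] <- 1L                    # tissue exactly at the mean axial
  sl4 <- radial_slice(0, m4, 50, 10, 11L)
  w4 <- mrw_meridian(bm_edge_point(sl4, "left", sc),
                     ilm_curve(m4, sc, 10), sl4, "left")
  expect_equal(w4, 0)
})

test_that("compute_mrw: symmetric phantom widths, truth recovery, quality gate", {
  spec <- small_spec(semi_major_um = 750, semi_minor_um = 750,
                     rnfl_amp_um = 0, vessels = list())
  ph <- cached("round_phantom", make_phantom(spec))
  ell <- detect_bmo(ph$volume)
  res <- compute_mrw(ph$volume, ell)
  expect_equal(res$n_meridians, 48)
  expect_equal(res$n_missing, 0)
  quant <- spec$spacing_ascan_um + spec$spacing_axial_um
  # rotational symmetry: all 48 half-meridian widths agree within quantization
  expect_lt(diff(range(res$per_meridian$values)), quant)
  truth <- ph$truth$mrw_um(res$per_meridian$angles_deg)
  expect_lt(abs(res$global_mean_um - mean(truth)), quant)

  # radial-set route on the same continuous phantom: within 5 um
  rcs <- derive_radial_set(spec)
  res2 <- compute_mrw(rcs)
  expect_lt(abs(res2$global_mean_um - res$global_mean_um), 5)

  # volumes where most meridians lack a BM edge trip the quality gate
  sc <- default_scheme()
  empty <- matrix(0L, 41, 30)
  some <- empty; some[25:41, 10:12] <- 3L; some[1:41, 3:5] <- 1L
  slices <- c(
    lapply((0:8) * 10, function(a) radial_slice(a, empty, 50, 10, 21L)),
    lapply((9:11) * 10, function(a) radial_slice(a, some, 50, 10, 21L)))
  rset <- radial_circular_set(slices, laterality = "OD")
  expect_error(compute_mrw(rset), class = "onhmark_quality_error")
})
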