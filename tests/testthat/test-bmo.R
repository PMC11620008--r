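test_that("BM presence includes alpha/beta PPA and excludes gamma PPA", {
  base <- slab_volume(nb = 40, na = 40, nz = 40,
                      hole = list(cx = 20, cy = 20, rx = 8, ry = 8))
  m0 <- bm_presence_map(base)$values
  hole0 <- sum(!m0)

  # alpha-PPA ring just inside the hole edge: hole shrinks by the ring width
  arr <- base$labels
  for (i in 1:40) for (j in 1:40) {
    r2 <- ((j - 20) / 8)^2 + ((i - 20) / 8)^2
    if (r2 < 1 && r2 >= 0.6) arr[i, j, 25] <- 6L  # ppa_alpha
  }
  va <- label_volume(arr, 150, 150, 10, "OD", "cube")
  ma <- bm_presence_map(va)$values
  expect_lt(sum(!ma), hole0)

  # gamma-PPA ring in the same place: hole unchanged
  arr_g <- base$labels
  for (i in 1:40) for (j in 1:40) {
    r2 <- ((j - 20) / 8)^2 + ((i - 20) / 8)^2
    if (r2 < 1 && r2 >= 0.6) arr_g[i, j, 25] <- 8L  # ppa_gamma
  }
  vg <- label_volume(arr_g, 150, 150, 10, "OD", "cube")
  expect_identical(bm_presence_map(vg)$values, m0)
})

test_that("close_and_boundary traces the hole contour and survives salt noise", {
  # clean elliptical hole on a 100x100, 30-um grid
  n <- 100
  cx <- 1500; cy <- 1500; a <- 700; b <- 450
  xs <- (seq_len(n) - 1) * 30
  gx <- matrix(rep(xs, each = n), n); gy <- matrix(rep(xs, times = n), n)
  q <- ((gx - cx) / a)^2 + ((gy - cy) / b)^2
  clean <- enface_map(q >= 1, 30, 30)
  pts <- close_and_boundary(clean, closing_radius_px = 3)
  qb <- ((pts[, 1] - cx) / a)^2 + ((pts[, 2] - cy) / b)^2
  # all boundary points within one pixel of the true ellipse
  expect_lt(max(abs(sqrt(qb) - 1)), 30 / b + 1e-9)
  # 5% spurious-BM salt inside the hole: same contour within one pixel
  set.seed(42)
  noisy <- clean$values
  inside <- which(q < 0.9)   # interior of the hole
  flips <- inside[runif(length(inside)) < 0.05]
  noisy[flips] <- TRUE
  pts_n <- close_and_boundary(enface_map(noisy, 30, 30), closing_radius_px = 3)
  d2 <- outer(pts_n[, 1], pts[, 1], "-")^2 + outer(pts_n[, 2], pts[, 2], "-")^2
  expect_lt(max(sqrt(apply(d2, 1, min))), 30 + 1e-9)

  expect_error(close_and_boundary(enface_map(matrix(TRUE, 20, 20), 30, 30)),
               "no BMO")
})

test_that("direct least-squares ellipse fit is exact, guaranteed and equivariant", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  rot <- 30 * pi / 180
  a <- 900; b <- 600; cx <- 3100; cy <- 2800
  x <- cx + a * cos(th) * cos(rot) - b * sin(th) * sin(rot)
  y <- cy + a * cos(th) * sin(rot) + b * sin(th) * cos(rot)
  fit <- fit_ellipse(cbind(x, y))
  expect_equal(fit$semi_major_um, a, tolerance = 1e-6)
  expect_equal(fit$semi_minor_um, b, tolerance = 1e-6)
  expect_equal(fit$center_um, c(cx, cy), tolerance = 1e-6)
  expect_equal(fit$rotation_deg, 30, tolerance = 1e-4)
  expect_equal(fit$area_mm2, pi * a * b * 1e-6, tolerance = 1e-6)
  # internal consistency: area is always pi * a * b
  expect_equal(fit$area_mm2,
               pi * fit$semi_major_um * fit$semi_minor_um * 1e-6)

  # circle: both axes equal, area pi r^2
  xc <- 1000 + 800 * cos(th); yc <- 1000 + 800 * sin(th)
  fc <- fit_ellipse(cbind(xc, yc))
  expect_equal(fc$semi_major_um, 800, tolerance = 1e-6)
  expect_equal(fc$semi_minor_um, 800, tolerance = 1e-6)
  expect_equal(fc$area_mm2, pi * 0.64, tolerance = 1e-9)

  # affine equivariance: scaling coordinates scales the fitted axes exactly
  set.seed(7)
  xn <- x + rnorm(100, 0, 15); yn <- y + rnorm(100, 0, 15)
  f1 <- fit_ellipse(cbind(xn, yn))
  f2 <- fit_ellipse(cbind(xn, yn) * 2.5)
  expect_equal(f2$semi_major_um, 2.5 * f1$semi_major_um, tolerance = 1e-9)
  expect_equal(f2$semi_minor_um, 2.5 * f1$semi_minor_um, tolerance = 1e-9)

  expect_error(fit_ellipse(cbind(x[1:5], y[1:5])), "6 points")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))), "degenerate|collinear")
})

test_that("detect_bmo recovers center and area; jittered boundaries stay within 2%", {
  ph <- small_phantom()
  ell <- detect_bmo(ph$volume)
  # center within half an en-face pixel of truth
  expect_lt(max(abs(ell$center_um - ph$truth$bmo_center_um)),
            ph$volume$spacing_ascan_um / 2)
  expect_lt(abs(ell$area_mm2 / ph$truth$bmo_area_mm2 - 1), 0.02)

  # volume with no BM at all
  novol <- slab_volume(nb = 10, na = 10, nz = 10, bm_k = integer(0))
  expect_error(detect_bmo(novol), "no BMO")

  # Monte-Carlo: boundary displaced radially by N(0, 1 px) (smooth periodic
  # noise along the contour); fitted area within 2% of pi*a*b (median over
  # 100 seeded jitters)
  n <- 200; px <- 30
  cx <- 3000; cy <- 3000; a <- 900; b <- 600
  xs <- (seq_len(n) - 1) * px
  gx <- matrix(rep(xs, each = n), n); gy <- matrix(rep(xs, times = n), n)
  u <- gx - cx; v <- gy - cy
  rho <- sqrt((u / a)^2 + (v / b)^2)
  theta <- atan2(v, u)
  r_local <- ifelse(rho > 0, sqrt(u^2 + v^2) / rho, 1)  # boundary radius
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    knots <- rnorm(24, 0, 1)            # periodic displacement field, px
    disp <- stats::approx(seq(-pi, pi, length.out = 25),
                          c(knots, knots[1]), xout = theta)$y
    noisy <- rho >= 1 + disp * px / r_local
    pts <- close_and_boundary(enface_map(matrix(noisy, n), px, px), 3)
    abs(fit_ellipse(pts)$area_mm2 / (pi * a * b * 1e-6) - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})
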