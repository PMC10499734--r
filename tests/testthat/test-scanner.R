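# Chart extraction, gamma estimation, WPPLS colour correction and the
# dE* evaluation map.

test_that("extract_patch_colors recovers rendered patch colours", {
  chart <- identity_chart()
  gs <- extract_patch_colors(chart$image, chart$layout)
  expect_identical(dim(gs$values), c(3L, 13L))
  expect_equal(gs$values, ref_chart()$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("patch averaging beats pixel noise by the standard error", {
  # one uniform 100 x 100 patch, additive noise sd 0.01, central 50 x 50
  set.seed(21)
  truth <- c(0.4, 0.55, 0.3)
  px <- array(rep(truth, each = 1e4), c(100, 100, 3)) +
    array(rnorm(3e4, 0, 0.01), c(100, 100, 3))
  img <- image_patch(px, "device_gamma")
  got <- vapply(1:3, function(ch)
    mean(px[26:75, 26:75, ch]), numeric(1))
  lay13 <- stats::setNames(rep(list(c(0, 0, 100, 100)), 13),
                           chart_patch_ids())
  cols <- extract_patch_colors(img, lay13)
  expect_equal(as.numeric(cols$values[, 1]), got, tolerance = 1e-12)
  expect_true(all(abs(as.numeric(cols$values[, 1]) - truth) <
                    3 * 0.01 / 50 + 1e-9))
})

test_that("layout errors are reported", {
  chart <- identity_chart()
  lay <- chart$layout
  lay[["A1"]] <- c(-1, 0, 10, 10)
  expect_error(extract_patch_colors(chart$image, lay), "out of image bounds")
  lay2 <- chart$layout
  lay2[["BG"]] <- NULL
  expect_error(extract_patch_colors(chart$image, lay2), "missing patch")
})

test_that("estimate_gamma recovers display gammas", {
  Gr <- ref_chart()
  # identity scan: gamma 1
  expect_equal(estimate_gamma(ref_chart(), Gr)$gamma, 1, tolerance = 0.01)
  for (g in c(1.8, 2.2)) {
    chart <- render_color_chart(Gr, scanner_sim_config(gamma = g))
    gs <- extract_patch_colors(chart$image, chart$layout)
    est <- estimate_gamma(gs, Gr)
    expect_equal(est$gamma, g, tolerance = 0.01)
  }
})

test_that("noisy gamma estimate matches a dense grid-search oracle", {
  Gr <- ref_chart()
  chart <- render_color_chart(Gr, scanner_sim_config(gamma = 2.2))
  gs <- extract_patch_colors(chart$image, chart$layout)
  set.seed(31)
  gs$values <- gs$values + matrix(rnorm(39, 0, 0.005), 3)
  gs$values["R", "BG"] <- min(gs$values["R", "BG"], 1)  # keep BG a fixed point
  est <- estimate_gamma(gs, Gr)
  yrow <- srgb_matrix()[2, ]
  ids <- c("A1", "B1", "C1", "BG")
  Ys <- as.numeric(yrow %*% gs$values[, ids])
  Yr <- as.numeric(yrow %*% Gr$values[, ids])
  ok <- Ys > 0 & Ys < 1 & Yr > 0 & Yr < 1
  grid <- seq(0.2, 5, by = 0.001)
  sse <- vapply(grid, function(g) sum((Ys[ok]^g - Yr[ok])^2), numeric(1))
  expect_equal(est$gamma, grid[which.min(sse)], tolerance = 0.005)
})

test_that("gamma fit refuses saturated charts", {
  Gr <- ref_chart()
  sat <- Gr
  sat$values[, c("A1", "B1", "C1")] <- 1  # everything at the white fixed point
  expect_error(estimate_gamma(sat, Gr), "insufficient data")
})

test_that("WPPLS reproduces an identity and a known linear scanner", {
  Gr <- ref_chart()
  map <- fit_wppls(Gr, Gr)
  expect_equal(predict(map, Gr)$values, Gr$values, tolerance = 1e-9,
               ignore_attr = TRUE)
  # known white-preserving 3 x 3 device matrix
  A <- matrix(c(0.90, 0.07, 0.03,
                0.05, 0.90, 0.05,
                0.02, 0.06, 0.92), 3, byrow = TRUE)
  gs <- Gr
  gs$values <- A %*% Gr$values
  map2 <- fit_wppls(Gr, gs)
  expect_equal(map2$coeffs[, 1:3], solve(A), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(abs(map2$coeffs[, 4:5]), matrix(0, 3, 2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("WPPLS matches a null-space constrained least-squares oracle", {
  Gr <- ref_chart()
  set.seed(41)
  gs <- Gr
  gs$values <- Gr$values + matrix(rnorm(39, 0, 0.02), 3)
  gs$values[, "BG"] <- 1
  map <- fit_wppls(Gr, gs)
  # oracle: eliminate the constraint a' m = u_c by the null-space
  # parameterization m = a/5 + N z and solve unconstrained least squares
  Phi <- rbind(gs$values, gs$values[1, ] * gs$values[2, ] * gs$values[3, ], 1)
  a <- c(1, 1, 1, 1, 1)
  N <- qr.Q(qr(cbind(a, diag(5))))[, 2:5]
  for (ch in 1:3) {
    y <- Gr$values[ch, ]
    X <- t(Phi) %*% N
    z <- qr.solve(X, y - as.numeric(t(Phi) %*% (a / 5)))
    m_oracle <- a / 5 + N %*% z
    expect_equal(as.numeric(map$coeffs[ch, ]), as.numeric(m_oracle),
                 tolerance = 1e-8)
  }
  expect_error(fit_wppls(Gr, chart_colors(matrix(0.5, 3, 13), "scanned")),
               "degenerate")
})

test_that("white preservation holds exactly for noisy fits", {
  Gr <- ref_chart()
  set.seed(43)
  for (i in 1:10) {
    gs <- Gr
    gs$values <- pmax(Gr$values + matrix(rnorm(39, 0, 0.03), 3), 0)
    map <- fit_wppls(Gr, gs)
    expect_lt(max(abs(predict(map, c(1, 1, 1)) - 1)), 1e-9)
  }
})

test_that("apply_color_map evaluates per pixel and preserves white", {
  Gr <- ref_chart()
  idmap <- fit_wppls(Gr, Gr)
  set.seed(17)
  px <- array(runif(5 * 4 * 3), c(5, 4, 3))
  img <- image_patch(px, "device_linear")
  out <- apply_color_map(img, idmap)
  expect_identical(out$encoding, "standard_linear")
  expect_equal(out$pixels, px, tolerance = 1e-9)
  # distorted map vs naive per-pixel loop oracle
  gs <- Gr
  gs$values <- 0.9 * Gr$values + 0.05
  gs$values[, "BG"] <- 1
  map <- fit_wppls(Gr, gs)
  out2 <- apply_color_map(img, map)
  for (r in 1:5) for (cc in 1:4) {
    p <- px[r, cc, ]
    feat <- c(p, prod(p), 1)
    expect_equal(out2$pixels[r, cc, ], as.numeric(map$coeffs %*% feat),
                 tolerance = 1e-12)
  }
  white <- image_patch(array(1, c(2, 2, 3)), "device_linear")
  expect_equal(apply_color_map(white, map)$pixels, white$pixels,
               tolerance = 1e-9)
})

test_that("dE* maps summarize pixelwise colour differences", {
  set.seed(19)
  px <- array(runif(6 * 6 * 3, 0.2, 0.9), c(6, 6, 3))
  a <- image_patch(px, "standard_linear")
  same <- compute_de_map(a, a)
  expect_equal(max(same$values), 0)
  expect_equal(same$mean, 0)
  expect_length(same$histogram, 64)
  expect_equal(sum(same$histogram), 36)
  # two uniform images: every pixel equals the scalar delta_e
  c1 <- c(0.8, 0.4, 0.3); c2 <- c(0.7, 0.45, 0.35)
  u1 <- image_patch(array(rep(c1, each = 16), c(4, 4, 3)), "standard_linear")
  u2 <- image_patch(array(rep(c2, each = 16), c(4, 4, 3)), "standard_linear")
  dm <- compute_de_map(u1, u2)
  expect_equal(as.numeric(dm$values),
               rep(delta_e(linear_rgb_to_lab(c1), linear_rgb_to_lab(c2)), 16),
               tolerance = 1e-10)
  mask <- matrix(FALSE, 4, 4); mask[1:2, ] <- TRUE
  dm2 <- compute_de_map(u1, u2, mask = mask)
  expect_equal(sum(dm2$histogram), 8)
  b <- image_patch(array(0.5, c(3, 3, 3)), "standard_linear")
  expect_error(compute_de_map(u1, b), "dimensions differ")
})

test_that("simulated scanners are recovered end to end", {
  Gr <- ref_chart()
  # exact self-calibration for the identity scanner
  chart <- identity_chart()
  cal <- scanner_calibration(chart$image, chart$layout, Gr)
  expect_lt(mean(cal$patch_de), 1e-6)
  # random scanners, noiseless: imperceptible residual
  set.seed(53)
  for (g in c(1.0, 1.8, 2.2)) {
    cfg <- scanner_sim_config(random_device_matrix(), gamma = g,
                              incident = c(0.97, 1, 0.98))
    ch <- render_color_chart(Gr, cfg)
    cal <- scanner_calibration(ch$image, ch$layout, Gr)
    expect_equal(cal$gamma$gamma, g, tolerance = 0.01)
    expect_lt(mean(residuals(cal)), 0.1)
  }
})

test_that("calibration does not worsen the chart under noise", {
  Gr <- ref_chart()
  lab_ref <- linear_rgb_to_lab(Gr$values)
  set.seed(59)
  for (i in 1:5) {
    cfg <- scanner_sim_config(random_device_matrix(), gamma = 2.2,
                              noise_sd = 0.003, seed = 1000 + i)
    ch <- render_color_chart(Gr, cfg)
    cal <- scanner_calibration(ch$image, ch$layout, Gr)
    de_cal <- mean(residuals(cal))
    de_uncal <- mean(delta_e(linear_rgb_to_lab(cal$scanned$values), lab_ref))
    expect_lte(de_cal, de_uncal)
  }
})
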