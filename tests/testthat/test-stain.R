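# Bead-panel measurement, DAB vector estimation, unmixing and the
# staining-intensity transfer (methods 1 and 2).

test_that("stain model builds an invertible unit basis", {
  sm <- stain_model(ruifrok_vectors()$dab)
  expect_equal(colSums(sm$matrix^2), c(dab = 1, hematoxylin = 1, residual = 1),
               tolerance = 1e-12)
  expect_lt(kappa(sm$matrix), 1e6)
  expect_error(stain_model(c(0.6, 0.7, 0.3), c(0.6, 0.7, 0.3)), "collinear")
  expect_error(stain_model(c(-1, 1, 0)), "nonnegative")
})

test_that("unmixing is the exact inverse of composition", {
  sm <- stain_model(ruifrok_vectors()$dab)
  # pure DAB pixel
  od1 <- array(0.4 * sm$dab_vector, c(1, 1, 3))
  ch <- unmix(od1, sm)
  expect_equal(ch$dab[1, 1], 0.4, tolerance = 1e-12)
  expect_equal(ch$hematoxylin[1, 1], 0, tolerance = 1e-12)
  # fixed mixture
  od2 <- array(0.3 * sm$dab_vector + 0.2 * sm$hematoxylin_vector, c(1, 1, 3))
  ch2 <- unmix(od2, sm)
  expect_equal(c(ch2$dab[1, 1], ch2$hematoxylin[1, 1]), c(0.3, 0.2),
               tolerance = 1e-10)
  # zero OD
  ch0 <- unmix(array(0, c(2, 2, 3)), sm)
  expect_equal(ch0$dab, matrix(0, 2, 2))
  # closure on random nonnegative stain images
  set.seed(61)
  dab <- matrix(runif(30, 0, 0.8), 5, 6)
  hem <- matrix(runif(30, 0, 0.8), 5, 6)
  back <- unmix(compose_od(dab, hem, sm), sm)
  expect_equal(back$dab, dab, tolerance = 1e-10)
  expect_equal(back$hematoxylin, hem, tolerance = 1e-10)
})

test_that("bead panels are measured exactly on rendered calibrators", {
  panel <- ref_panel()
  expect_length(panel$levels, 10)
  truth <- outer(stain_batch_config()$dab_vector, default_bead_ladder())
  expect_equal(panel$mean_od, truth, tolerance = 1e-6, ignore_attr = TRUE)
  # projected DAB OD nondecreasing in level
  expect_true(all(diff(panel_dab_od(panel)) >= 0))
  blank <- image_patch(array(1, c(40, 40, 3)), "standard_linear")
  expect_error(measure_bead_panel(blank), "missing level|detected")
})

test_that("DAB vector estimation uses the lightly stained levels", {
  v <- c(0.27, 0.57, 0.78); v <- v / sqrt(sum(v^2))
  panel <- bead_panel(outer(v, default_bead_ladder()))
  got <- estimate_dab_vector(panel)
  expect_equal(got, v, tolerance = 1e-12)
  expect_equal(sum(got^2), 1, tolerance = 1e-12)
  # noisy levels: angle below 2 degrees
  set.seed(67)
  noisy <- bead_panel(outer(v, default_bead_ladder()) +
                        matrix(rnorm(30, 0, 0.005), 3))
  ang <- acos(min(sum(estimate_dab_vector(noisy) * v), 1)) * 180 / pi
  expect_lt(ang, 2)
  thin <- bead_panel(outer(v, c(0.005, 0.01, 0.7, 0.9, 1.1)))
  expect_error(estimate_dab_vector(thin), "estimation error")
})

test_that("intensity transfer recovers batch scaling", {
  sm <- stain_model(ruifrok_vectors()$dab)
  panel <- ref_panel()
  # identity
  tr_id <- build_intensity_transfer(panel, panel, sm, sm)
  x <- seq(0, max(panel_dab_od(panel)), length.out = 50)
  expect_equal(predict(tr_id, x), x, tolerance = 1e-9)
  expect_equal(predict(tr_id, 0), 0)
  # scaled batch: map multiplies by 1/scale
  scaled <- bead_panel(0.7 * panel$mean_od)
  tr <- build_intensity_transfer(scaled, panel, sm, sm)
  xs <- seq(0.01, max(panel_dab_od(scaled)), length.out = 40)
  expect_equal(predict(tr, xs), xs / 0.7, tolerance = 1e-9)
  expect_equal(predict(tr, 0), 0)
  expect_error(build_intensity_transfer(
    bead_panel(panel$mean_od[, 1:5]), panel, sm, sm), "mismatched")
})

test_that("non-monotone panels are repaired by isotonic regression", {
  sm <- stain_model(ruifrok_vectors()$dab)
  ods <- default_bead_ladder()
  ods[4] <- ods[5] + 0.01  # swap-like defect
  panel <- bead_panel(outer(sm$dab_vector, ods))
  tr <- build_intensity_transfer(panel, ref_panel(), sm, sm)
  expect_true(all(diff(tr$knots$target) > 0))
  expect_true(all(diff(tr$knots$reference) >= 0))
  x <- seq(0, 1.5, by = 0.01)
  y <- predict(tr, x)
  expect_true(all(diff(y) >= -1e-12))
})

test_that("threshold adjustment (method 1) inverts the transfer", {
  ts <- threshold_set(0.05, 0.15, 0.29)
  sm <- stain_model(ruifrok_vectors()$dab)
  panel <- ref_panel()
  tr_id <- build_intensity_transfer(panel, panel, sm, sm)
  expect_equal(as.numeric(calibrate_thresholds_method1(ts, tr_id)),
               as.numeric(ts), tolerance = 1e-9)
  # transfer that doubles OD (target at half scale): thresholds halve
  half <- bead_panel(0.5 * panel$mean_od)
  tr2 <- build_intensity_transfer(half, panel, sm, sm)
  expect_equal(as.numeric(calibrate_thresholds_method1(ts, tr2)),
               as.numeric(ts) / 2, tolerance = 1e-9)
  # generic piecewise map: forward-check oracle
  set.seed(71)
  adj <- calibrate_thresholds_method1(ts, tr2)
  expect_lt(max(abs(predict(tr2, as.numeric(adj)) - as.numeric(ts))), 1e-9)
  # flat segment: midpoint with warning
  flat <- structure(list(knots = data.frame(target = c(0, 0.1, 0.2, 0.5),
                                            reference = c(0, 0.15, 0.15, 0.6))),
                    class = "intensity_transfer")
  expect_warning(got <- transfer_inverse(flat, 0.15), "flat")
  expect_equal(got, 0.15)
})

test_that("image correction (method 2) maps only the DAB channel", {
  sm <- stain_model(ruifrok_vectors()$dab)
  set.seed(73)
  dab <- matrix(runif(64, 0, 0.5), 8, 8)
  hem <- matrix(runif(64, 0, 0.5), 8, 8)
  img <- od_to_rgb(compose_od(dab, hem, sm))
  panel <- ref_panel()
  tr_id <- build_intensity_transfer(panel, panel, sm, sm)
  out <- correct_image_method2(img, tr_id, sm, sm)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-9)
  # doubling transfer doubles recomposed DAB OD, leaves hematoxylin alone
  half <- bead_panel(0.5 * panel$mean_od)
  tr2 <- build_intensity_transfer(half, panel, sm, sm)
  out2 <- correct_image_method2(img, tr2, sm, sm)
  ch <- unmix(rgb_to_od(out2), sm)
  expect_equal(ch$dab, 2 * dab, tolerance = 1e-8)
  expect_equal(ch$hematoxylin, hem, tolerance = 1e-8)
  hem_only <- od_to_rgb(compose_od(matrix(0, 4, 4),
                                   matrix(0.4, 4, 4), sm))
  out3 <- correct_image_method2(hem_only, tr2, sm, sm)
  expect_equal(out3$pixels, hem_only$pixels, tolerance = 1e-9)
})

test_that("methods 1 and 2 classify cells identically off the thresholds", {
  sm <- stain_model(ruifrok_vectors()$dab)
  panel <- ref_panel()
  ts <- threshold_set(0.05, 0.15, 0.29)
  set.seed(79)
  for (scale in c(0.75, 1.25)) {
    batch <- stain_batch_config(dab_scale = scale)
    target_panel <- measure_rendered_panel(batch)
    tr <- build_intensity_transfer(target_panel, panel, sm, sm)
    rt <- render_tissue(tissue_phantom_spec("2+", seed = 500 + scale * 100),
                        batch, scanner_sim_config())
    img <- image_patch(rt$image$pixels, "standard_linear")
    cells1 <- detect_cells(img, sm)
    s1 <- classify_cells(cells1, calibrate_thresholds_method1(ts, tr))
    img2 <- correct_image_method2(img, tr, sm, sm)
    cells2 <- detect_cells(img2, sm)
    idx <- match_cells(cells2, cells1)
    expect_false(anyNA(idx))
    # exclude cells at a threshold tie
    tie <- vapply(seq_len(nrow(cells1)), function(i)
      any(abs(predict(tr, cells1$membrane_dab_od[i]) - as.numeric(ts)) < 1e-6),
      logical(1))
    s2 <- classify_cells(cells2, ts)
    expect_identical(s2[!tie[idx]], s1[idx][!tie[idx]])
  }
})
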