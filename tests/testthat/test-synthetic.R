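# Forward models: scanner simulation and the three slide renderers.

test_that("simulate_scan applies the forward model deterministically", {
  set.seed(107)
  px <- array(runif(5 * 5 * 3, 0.1, 0.9), c(5, 5, 3))
  img <- image_patch(px, "standard_linear")
  # identity configuration: unchanged pixels
  out <- simulate_scan(img, scanner_sim_config())
  expect_equal(out$pixels, px)
  expect_identical(out$encoding, "device_gamma")
  # gamma encoding of mid-gray
  gray <- image_patch(array(0.5, c(2, 2, 3)), "standard_linear")
  out2 <- simulate_scan(gray, scanner_sim_config(gamma = 2.2))
  expect_equal(out2$pixels[1, 1, 1], 0.5^(1 / 2.2), tolerance = 1e-12)
  # seeded determinism is bitwise
  cfg <- scanner_sim_config(noise_sd = 0.01, seed = 42)
  a <- simulate_scan(img, cfg); b <- simulate_scan(img, cfg)
  expect_identical(a$pixels, b$pixels)
  expect_error(scanner_sim_config(matrix(1, 3, 3) * 2), "rows must sum")
  expect_error(scanner_sim_config(gamma = -1), "positive")
})

test_that("random device matrices are white-preserving and well-conditioned", {
  set.seed(109)
  for (i in 1:10) {
    m <- random_device_matrix()
    expect_equal(rowSums(m), c(1, 1, 1), tolerance = 1e-12)
    expect_lt(kappa(m), 10)
  }
})

test_that("rendered charts round-trip through extraction", {
  chart <- identity_chart()
  gs <- extract_patch_colors(chart$image, chart$layout)
  expect_lt(max(abs(gs$values - ref_chart()$values)), 1e-6)
  # 13 distinct regions in the layout
  expect_length(chart$layout, 13)
  bad <- default_chart_layout()
  bad[["A2"]] <- bad[["A1"]]
  expect_error(render_color_chart(ref_chart(), scanner_sim_config(),
                                  layout = bad), "overlap")
  tiny <- default_chart_layout()
  attr(tiny, "canvas") <- c(0, 0)
  expect_error(render_color_chart(ref_chart(), scanner_sim_config(),
                                  layout = tiny), "zero-size|out of image")
})

test_that("rendered calibrators carry exact ground truth", {
  batch <- stain_batch_config()
  rc <- render_calibrator(batch, scanner_sim_config())
  panel <- measure_bead_panel(image_patch(rc$image$pixels, "standard_linear"),
                              layout = calibrator_layout(rc$geometry))
  expect_equal(panel$mean_od, rc$truth$mean_od, tolerance = 1e-6,
               ignore_attr = TRUE)
  # monotone ladder renders monotonically darker beads
  darkness <- -colSums(panel$mean_rgb)
  expect_true(all(diff(darkness) > 0))
  expect_error(stain_batch_config(dab_scale = 0), "positive")
  small <- default_calibrator_geometry()
  small$canvas <- c(20, 20)
  expect_error(render_calibrator(batch, scanner_sim_config(),
                                 geometry = small), "overflow")
})

test_that("tissue phantoms round-trip membrane OD within 2%", {
  batch <- stain_batch_config()
  sm <- stain_model(batch$dab_vector, batch$hematoxylin_vector)
  rt <- render_tissue(tissue_phantom_spec("3+", seed = 11), batch,
                      scanner_sim_config())
  img <- image_patch(rt$image$pixels, "standard_linear")
  cells <- detect_cells(img, sm)
  expect_equal(nrow(cells), nrow(rt$cells))
  idx <- match_cells(cells, rt$cells)
  expect_false(anyNA(idx))
  err <- abs(cells$membrane_dab_od - rt$cells$membrane_dab_od[idx])
  expect_lt(max(err / pmax(rt$cells$membrane_dab_od[idx], 0.05)), 0.02)
  # determinism: same seed, same table and image
  rt2 <- render_tissue(tissue_phantom_spec("3+", seed = 11), batch,
                       scanner_sim_config())
  expect_identical(rt2$cells, rt$cells)
  expect_identical(rt2$image$pixels, rt$image$pixels)
})

test_that("an unstained phantom scores all cells 0", {
  spec <- tissue_phantom_spec("0", seed = 13,
                              membrane_mix = data.frame(weight = 1, lo = 0,
                                                        hi = 0))
  rt <- render_tissue(spec, stain_batch_config(), scanner_sim_config())
  sm <- stain_model(ruifrok_vectors()$dab)
  cells <- detect_cells(image_patch(rt$image$pixels, "standard_linear"), sm)
  scores <- classify_cells(cells, threshold_set(0.05, 0.15, 0.29))
  expect_true(all(scores == 0L))
})

test_that("impossible placements fail loudly", {
  spec <- tissue_phantom_spec("0", height = 40, width = 40, n_cells = 60,
                              seed = 17)
  expect_error(render_tissue(spec, stain_batch_config(),
                             scanner_sim_config(), max_retries = 20),
               "placement")
})

test_that("make_experiment reproduces the scanner-by-gamma design", {
  expect_error(make_experiment(ref_chart(), design = data.frame()),
               "at least one row")
  des <- target_design()
  expect_equal(nrow(des), 10)
  expect_equal(sort(unique(des$gamma)), c(1.0, 1.8, 2.2))
  ex <- make_experiment(ref_chart(), design = des[c(1, 5), ], seed = 3,
                        n_cells = 12)
  expect_length(ex$targets, 2)
  for (t in ex$targets)
    expect_identical(names(t$tissues), c("0", "1+", "2+", "3+"))
  expect_true(all(ex$manifest$dab_scale >= 0.7 &
                    ex$manifest$dab_scale <= 1.3))
})

test_that("calibration closes the full inverse problem", {
  # one distorted dataset: calibrate scanner + staining, corrected tissue
  # ODs must match the nominal reference rendering closely
  Gr <- ref_chart()
  ex <- make_experiment(Gr, design = data.frame(scanner = "B", gamma = 1.8),
                        seed = 5, noise_sd = 0, n_cells = 20)
  prep <- prepare_reference(ex$reference, Gr, use_ccs = TRUE)
  tgt <- ex$targets[[1]]
  cal <- scanner_calibration(tgt$chart$image, tgt$chart$layout, Gr)
  panel_t <- measure_bead_panel(predict(cal, tgt$calibrator$image),
                                layout = calibrator_layout(tgt$calibrator$geometry))
  sm_t <- stain_model(estimate_dab_vector(panel_t))
  tr <- build_intensity_transfer(panel_t, prep$panel, sm_t, prep$stains)
  tis <- tgt$tissues[["2+"]]
  corrected <- correct_image_method2(predict(cal, tis$image), tr, sm_t,
                                     prep$stains)
  cells <- detect_cells(corrected, prep$stains)
  idx <- match_cells(cells, tis$cells)
  err <- abs(cells$membrane_dab_od - tis$cells$membrane_dab_od[idx])
  expect_lt(mean(err), 0.01)
})
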