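# Shared fixtures, memoized because the reference chart and experiment
# bundles are reused by many tests.

.fixture_cache <- new.env(parent = emptyenv())

ref_chart <- function() {
  if (is.null(.fixture_cache$Gr))
    .fixture_cache$Gr <- compute_reference_chart(synthetic_chart_spectra())
  .fixture_cache$Gr
}

# A rendered, noiseless, identity-scanner chart image plus its layout.
identity_chart <- function() {
  if (is.null(.fixture_cache$identity_chart))
    .fixture_cache$identity_chart <-
      render_color_chart(ref_chart(), scanner_sim_config())
  .fixture_cache$identity_chart
}

# Reference bead panel (scale 1, identity scanner, noiseless).
ref_panel <- function() {
  if (is.null(.fixture_cache$ref_panel)) {
    rc <- render_calibrator(stain_batch_config(), scanner_sim_config())
    .fixture_cache$ref_panel <- measure_bead_panel(
      image_patch(rc$image$pixels, "standard_linear"),
      layout = calibrator_layout(rc$geometry))
  }
  .fixture_cache$ref_panel
}

# Measure a calibrator rendered with the given batch/scanner.
measure_rendered_panel <- function(batch, cfg = scanner_sim_config()) {
  rc <- render_calibrator(batch, cfg)
  img <- rc$image
  if (img$encoding != "standard_linear")
    img <- image_patch(img$pixels, "standard_linear")
  measure_bead_panel(img, layout = calibrator_layout(rc$geometry))
}

# Match detected cells to ground-truth (or other detected) cells by
# nearest centroid; returns index into `truth` for each row of `cells`.
match_cells <- function(cells, truth, max_dist = 3) {
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    d <- sqrt((truth$row - cells$row[i])^2 + (truth$col - cells$col[i])^2)
    j <- which.min(d)
    if (d[j] > max_dist) NA_integer_ else j
  }, integer(1))
  idx
}
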