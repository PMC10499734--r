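# End-to-end orchestration: spectral-table I/O, the six calibration
# selectors (CCS stage on/off x staining method 0/1/2), reference-dataset
# preparation, the full pipeline run, and deterministic JSON reports.

PIPELINE_SELECTORS <- c("0-0", "0-1", "0-2", "1-0", "1-1", "1-2")

#' Load a spectral transmittance table
#'
#' CSV with a `wavelength_nm` column (340..830 in 5 nm steps) and one
#' transmittance column per chart patch (A1..C4, BG).
#'
#' @param path CSV file path.
#' @return Named list of 13 [spectral_curve()] objects.
#' @export
load_spectral_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop("spectral table must have a wavelength_nm column")
  ids <- chart_patch_ids()
  missing <- setdiff(ids, names(df))
  if (length(missing))
    stop("spectral table missing patch column(s): ",
         paste(missing, collapse = ", "))
  grid <- spectral_grid()
  if (nrow(df) != length(grid) || any(df$wavelength_nm != grid))
    stop("grid mismatch: expected ", length(grid),
         " rows covering 340..830 nm in 5 nm steps")
  out <- lapply(ids, function(id) spectral_curve(df[[id]]))
  names(out) <- ids
  out
}

#' Write a spectral transmittance table
#'
#' @param curves Named list of 13 [spectral_curve()] objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spectral_table <- function(curves, path) {
  df <- data.frame(wavelength_nm = spectral_grid())
  for (id in chart_patch_ids()) df[[id]] <- curves[[id]]$transmittance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.logistic <- function(x) 1 / (1 + exp(-x))

#' Synthetic spectral transmittance data for the colour chart
#'
#' A synthetic stand-in for the chart's proprietary calibration data:
#' flat neutral spectra for the grayscale patches (A1, B1, C1) and the
#' clear-glass background, and smooth band/edge filters for the nine
#' colour patches. All curves are designed to stay inside the sRGB gamut
#' so the rendered chart is physically displayable.
#'
#' @return Named list of 13 [spectral_curve()] objects.
#' @export
synthetic_chart_spectra <- function() {
  wl <- spectral_grid()
  band <- function(center, width, amp, base = 0.05)
    pmin(base + amp * exp(-0.5 * ((wl - center) / width)^2), 0.97)
  edge <- function(center, scale, amp, base = 0.05, lowpass = FALSE) {
    s <- .logistic((wl - center) / scale)
    pmin(base + amp * (if (lowpass) 1 - s else s), 0.97)
  }
  flat <- function(v) rep(v, length(wl))
  curves <- list(
    A1 = flat(0.15),                              # dark gray
    A2 = band(630, 55, 0.75),                     # red
    A3 = band(545, 50, 0.65),                     # green
    A4 = band(470, 62, 0.55, base = 0.10),        # blue
    B1 = flat(0.40),                              # mid gray
    B2 = edge(530, 25, 0.80),                     # yellow (long-pass)
    B3 = edge(570, 25, 0.75, lowpass = TRUE),     # cyan (short-pass)
    B4 = pmin(0.05 + 0.6 * exp(-0.5 * ((wl - 445) / 40)^2) +
                0.65 * exp(-0.5 * ((wl - 650) / 50)^2), 0.97),  # magenta
    C1 = flat(0.70),                              # light gray
    C2 = edge(575, 35, 0.70, base = 0.10),        # orange
    C3 = pmin(0.08 + 0.45 * exp(-0.5 * ((wl - 450) / 45)^2) +
                0.35 * exp(-0.5 * ((wl - 700) / 60)^2), 0.97),  # purple
    C4 = 0.25 + 0.45 * .logistic((wl - 560) / 60),              # tan
    BG = flat(1.0)                                # clear glass
  )
  lapply(curves, spectral_curve)
}

# Relabel a raw device image as standard linear RGB: what "no scanner
# calibration" (selector 0-x) means operationally.
.as_standard <- function(img) {
  image_patch(img$pixels, "standard_linear", img$pixel_size_um)
}

# Measurement rectangles for a dataset's calibrator: explicit layout if
# present, else derived from its geometry, else NULL (auto-detect).
.calibrator_rects <- function(calibrator) {
  if (!is.null(calibrator$layout)) return(calibrator$layout)
  if (!is.null(calibrator$geometry))
    return(calibrator_layout(calibrator$geometry))
  NULL
}

#' Prepare the reference side of the protocol
#'
#' Preparation stage on a reference dataset: optionally calibrate the
#' scanner from the reference chart, measure the reference bead panel,
#' estimate the reference DAB vector, detect cells in the score-known
#' reference tissues, and derive the reference classification thresholds
#' by the concordance-maximizing grid search.
#'
#' @param dataset A dataset as produced by [make_experiment()] (fields
#'   `chart`, `calibrator`, `tissues`).
#' @param chart_reference Reference chart colours (`chart_colors`).
#' @param use_ccs Logical: run the chart-based scanner calibration
#'   (selectors 1-x) or evaluate raw images as-is (selectors 0-x).
#' @param rule HER2 status rule table.
#' @param grid Threshold search grid.
#' @return An object of class `reference_prep`.
#' @export
prepare_reference <- function(dataset, chart_reference, use_ccs = TRUE,
                              rule = default_status_rule(),
                              grid = seq(0.01, 0.60, by = 0.01)) {
  scanner_cal <- NULL
  standardize <- .as_standard
  if (use_ccs) {
    scanner_cal <- scanner_calibration(dataset$chart$image,
                                       dataset$chart$layout, chart_reference)
    standardize <- function(img) predict(scanner_cal, img)
  }
  panel <- measure_bead_panel(standardize(dataset$calibrator$image),
                              layout = .calibrator_rects(dataset$calibrator))
  stains <- stain_model(estimate_dab_vector(panel))
  cells <- lapply(dataset$tissues, function(t)
    detect_cells(standardize(t$image), stains))
  thresholds <- derive_reference_thresholds(cells, names(dataset$tissues),
                                            grid = grid, rule = rule)
  structure(list(panel = panel, stains = stains, thresholds = thresholds,
                 chart_reference = chart_reference, use_ccs = use_ccs,
                 scanner_cal = scanner_cal, cells = cells, rule = rule),
            class = "reference_prep")
}

#' @export
print.reference_prep <- function(x, ...) {
  cat(sprintf("Reference preparation (%s scanner calibration)\n",
              if (x$use_ccs) "with" else "without"))
  print(x$thresholds)
  invisible(x)
}

#' Run the calibration-and-scoring pipeline on a target dataset
#'
#' Executes the stages selected by the method combination
#' `"<ccs>-<ihc>"`: first digit 1 enables chart-based scanner
#' calibration, second digit selects the staining calibration (0 none,
#' 1 threshold adjustment, 2 image intensity correction), then scores
#' every tissue image.
#'
#' @param target Target dataset (fields `chart`, `calibrator`,
#'   `tissues`; `chart`/`calibrator` are only required by the stages
#'   that use them).
#' @param reference A [prepare_reference()] result with matching
#'   `use_ccs`.
#' @param selector One of `"0-0"`, `"0-1"`, `"0-2"`, `"1-0"`, `"1-1"`,
#'   `"1-2"`.
#' @param rule HER2 status rule table.
#' @return An object of class `pipeline_result`: per-tissue
#'   [her2_score()] results plus stage diagnostics.
#' @export
run_pipeline <- function(target, reference, selector = "1-2",
                         rule = default_status_rule()) {
  selector <- match.arg(selector, PIPELINE_SELECTORS)
  use_ccs <- substr(selector, 1, 1) == "1"
  method <- substr(selector, 3, 3)
  if (use_ccs != reference$use_ccs)
    stop("configuration error: reference preparation used ",
         if (reference$use_ccs) "CCS" else "no CCS",
         " but selector is ", selector)
  diagnostics <- list(selector = selector)
  standardize <- .as_standard
  if (use_ccs) {
    if (is.null(target$chart))
      stop("configuration error: selector ", selector,
           " needs a chart image")
    cal <- scanner_calibration(target$chart$image, target$chart$layout,
                               reference$chart_reference)
    standardize <- function(img) predict(cal, img)
    diagnostics$gamma <- cal$gamma$gamma
    diagnostics$chart_mean_de <- mean(cal$patch_de)
    diagnostics$scanner_cal <- cal
  }
  thresholds <- reference$thresholds
  stains_measure <- reference$stains
  transform_tissue <- identity
  if (method != "0") {
    if (is.null(target$calibrator))
      stop("configuration error: selector ", selector,
           " needs a calibrator image")
    panel_t <- measure_bead_panel(standardize(target$calibrator$image),
                                  layout = .calibrator_rects(target$calibrator))
    stains_t <- stain_model(estimate_dab_vector(panel_t))
    transfer <- build_intensity_transfer(panel_t, reference$panel,
                                         stains_t, reference$stains)
    diagnostics$transfer <- transfer
    if (method == "1") {
      thresholds <- calibrate_thresholds_method1(reference$thresholds,
                                                 transfer)
      stains_measure <- stains_t
    } else {
      transform_tissue <- function(img)
        correct_image_method2(img, transfer, stains_t, reference$stains)
    }
  }
  diagnostics$thresholds_used <- thresholds
  results <- lapply(target$tissues, function(t) {
    img <- transform_tissue(standardize(t$image))
    cells <- detect_cells(img, stains_measure)
    res <- her2_score(cells, thresholds, rule)
    res$cells <- cells
    res
  })
  structure(list(selector = selector, results = results,
                 diagnostics = diagnostics),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run, selector %s\n", x$selector))
  if (!is.null(x$diagnostics$gamma))
    cat(sprintf("  fitted gamma %.3f, chart mean dE* %.3f\n",
                x$diagnostics$gamma, x$diagnostics$chart_mean_de))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  tissue %-3s -> status %-3s H-score %6.1f (n = %d)\n",
                nm, r$status, r$h_score, r$distribution$n_cells))
  }
  invisible(x)
}

# Recursively sort list names so serialized reports are deterministic.
.sort_named <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, .sort_named)
  } else x
}

#' Write a pipeline report as deterministic JSON
#'
#' Sorted keys, fixed float formatting (H-scores with 4 decimals), and a
#' versioned schema; calibration blocks appear only for the stages that
#' ran. Round-trips through [read_report()].
#'
#' @param result A `pipeline_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(result, path) {
  d <- result$diagnostics
  rep <- list(schema_version = "1.0", selector = result$selector)
  if (!is.null(d$gamma))
    rep$scanner_calibration <- list(
      gamma = round(d$gamma, 6),
      chart_mean_de = round(d$chart_mean_de, 6),
      incident = round(as.numeric(d$scanner_cal$incident), 6),
      color_map = round(d$scanner_cal$color_map$coeffs, 8))
  if (!is.null(d$transfer))
    rep$stain_calibration <- list(
      transfer_knots_target = round(d$transfer$knots$target, 6),
      transfer_knots_reference = round(d$transfer$knots$reference, 6))
  rep$thresholds <- round(as.numeric(d$thresholds_used), 6)
  rep$results <- lapply(result$results, function(r) list(
    status = r$status,
    h_score = round(r$h_score, 4),
    n_cells = r$distribution$n_cells,
    P0 = round(r$distribution$P0, 4), P1 = round(r$distribution$P1, 4),
    P2 = round(r$distribution$P2, 4), P3 = round(r$distribution$P3, 4)))
  json <- jsonlite::toJSON(.sort_named(rep), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a pipeline report
#'
#' @param path JSON path written by [write_report()].
#' @return Nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Load a pipeline configuration file
#'
#' YAML key/value file with at least `selector` (one of the six method
#' combinations); other keys (paths, seed, thresholds) pass through.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$selector) || !cfg$selector %in% PIPELINE_SELECTORS)
    stop("configuration error: selector must be one of ",
         paste(PIPELINE_SELECTORS, collapse = ", "))
  cfg
}

# --- experiment bundle I/O -------------------------------------------------

#' Write a simulated experiment to a directory tree
#'
#' Images as 16-bit TIFF, ground-truth cell tables as CSV, layouts and
#' the manifest as JSON.
#'
#' @param bundle Result of [make_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr_ds <- function(ds, sub) {
    d <- file.path(dir, sub)
    dir.create(d, showWarnings = FALSE)
    write_image_patch(ds$chart$image, file.path(d, "chart.tiff"))
    jsonlite::write_json(ds$chart$layout, file.path(d, "chart_layout.json"),
                         auto_unbox = FALSE)
    write_image_patch(ds$calibrator$image, file.path(d, "calibrator.tiff"))
    jsonlite::write_json(.calibrator_rects(ds$calibrator),
                         file.path(d, "calibrator_layout.json"),
                         auto_unbox = FALSE)
    utils::write.csv(
      data.frame(level = ds$calibrator$truth$levels,
                 t(ds$calibrator$truth$mean_od)),
      file.path(d, "calibrator_truth.csv"), row.names = FALSE)
    for (nm in names(ds$tissues)) {
      safe <- gsub("\\+", "p", nm)
      write_image_patch(ds$tissues[[nm]]$image,
                        file.path(d, paste0("tissue_", safe, ".tiff")))
      write_cell_table(ds$tissues[[nm]]$cells,
                       file.path(d, paste0("cells_", safe, ".csv")))
    }
    invisible(NULL)
  }
  wr_ds(bundle$reference, "reference")
  for (i in seq_along(bundle$targets))
    wr_ds(bundle$targets[[i]], sprintf("target_%02d", i))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Read a simulated experiment from a directory tree
#'
#' @param dir Directory written by [write_experiment()].
#' @return Bundle list with `reference`, `targets`, `manifest`.
#' @export
read_experiment <- function(dir) {
  rd_ds <- function(sub) {
    d <- file.path(dir, sub)
    layout <- jsonlite::fromJSON(file.path(d, "chart_layout.json"))
    layout <- lapply(layout, as.numeric)
    tissues <- list()
    for (f in list.files(d, pattern = "^tissue_.*\\.tiff$")) {
      nm <- gsub("p$", "+", sub("^tissue_(.*)\\.tiff$", "\\1", f))
      tissues[[nm]] <- list(
        image = read_image_patch(file.path(d, f)),
        cells = read_cell_table(file.path(
          d, sub("^tissue", "cells", sub("tiff$", "csv", f)))))
    }
    clay <- jsonlite::fromJSON(file.path(d, "calibrator_layout.json"))
    if (is.matrix(clay)) clay <- lapply(seq_len(nrow(clay)), function(i) clay[i, ])
    list(chart = list(image = read_image_patch(file.path(d, "chart.tiff")),
                      layout = layout),
         calibrator = list(
           image = read_image_patch(file.path(d, "calibrator.tiff")),
           layout = lapply(clay, as.numeric)),
         tissues = tissues)
  }
  targets <- lapply(sort(list.files(dir, pattern = "^target_")), rd_ds)
  list(reference = rd_ds("reference"), targets = targets,
       manifest = jsonlite::fromJSON(file.path(dir, "manifest.json")))
}
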