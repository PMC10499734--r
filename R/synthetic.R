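# Forward models rendering the three slide types -- colour chart,
# DAB microbead calibrator, and tissue phantom -- under a parameterized
# scanner model (white-preserving device matrix, display gamma, incident
# light, additive device-space noise) and staining-batch intensity
# scaling. Every inverse operation in the package is validated against
# these renderers, which carry full ground truth.

#' Scanner simulation configuration
#'
#' Forward model of a whole-slide scanner: per-pixel white-preserving
#' 3 x 3 device colour mixing, multiplication by the incident light,
#' additive Gaussian noise in device space, clipping to `[0, 1]` and
#' display-gamma encoding with exponent 1/gamma.
#'
#' @param device_matrix 3 x 3 mixing matrix whose rows sum to 1 (so white
#'   stays white).
#' @param gamma Display gamma; 1.0 means a linear scanner.
#' @param incident Per-channel incident light, components in (0, 1].
#' @param noise_sd Additive Gaussian SD in device space (post-matrix,
#'   pre-gamma).
#' @param seed Optional integer making the noise reproducible.
#' @return An object of class `scanner_sim_config`.
#' @export
scanner_sim_config <- function(device_matrix = diag(3), gamma = 1,
                               incident = c(1, 1, 1), noise_sd = 0,
                               seed = NULL) {
  device_matrix <- as.matrix(device_matrix)
  if (!identical(dim(device_matrix), c(3L, 3L)))
    stop("device matrix must be 3 x 3")
  if (any(abs(rowSums(device_matrix) - 1) > 1e-8))
    stop("device matrix rows must sum to 1 (white-preserving)")
  if (gamma <= 0) stop("gamma must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  incident <- as.numeric(incident)
  if (length(incident) != 3 || any(incident <= 0))
    stop("incident light must be a positive 3-vector")
  structure(list(device_matrix = device_matrix, gamma = gamma,
                 incident = incident, noise_sd = noise_sd, seed = seed),
            class = "scanner_sim_config")
}

#' Fixed scanner personalities
#'
#' Two preset device matrices with mild (A) and stronger (B) channel
#' crosstalk and slightly coloured incident light, so multi-scanner
#' experiment designs are reproducible by name.
#'
#' @param name `"A"` or `"B"`.
#' @param gamma,noise_sd,seed Passed to [scanner_sim_config()].
#' @return A `scanner_sim_config`.
#' @export
scanner_preset <- function(name = c("A", "B"), gamma = 1, noise_sd = 0.003,
                           seed = NULL) {
  name <- match.arg(name)
  if (name == "A") {
    m <- matrix(c(0.94, 0.04, 0.02,
                  0.03, 0.93, 0.04,
                  0.02, 0.05, 0.93), 3, byrow = TRUE)
    i0 <- c(0.985, 1.0, 0.97)
  } else {
    m <- matrix(c(0.89, 0.08, 0.03,
                  0.05, 0.88, 0.07,
                  0.04, 0.09, 0.87), 3, byrow = TRUE)
    i0 <- c(0.96, 0.99, 1.0)
  }
  scanner_sim_config(m, gamma = gamma, incident = i0, noise_sd = noise_sd,
                     seed = seed)
}

#' Random white-preserving device matrix
#'
#' Identity with random nonnegative channel crosstalk (sensor mixing is
#' nonnegative), rows renormalized to sum 1, resampled until the
#' condition number is below `max_kappa`.
#'
#' @param strength Scale of the half-normal off-diagonal crosstalk.
#' @param max_kappa Condition-number cap.
#' @return A 3 x 3 nonnegative matrix with unit row sums.
#' @export
random_device_matrix <- function(strength = 0.05, max_kappa = 10) {
  repeat {
    m <- diag(3)
    m[row(m) != col(m)] <- abs(stats::rnorm(6, 0, strength))
    m <- m / rowSums(m)
    if (kappa(m) < max_kappa && det(m) > 0.1) return(m)
  }
}

#' Simulate scanning a standard-linear image
#'
#' Applies the forward scanner model of a [scanner_sim_config()]. With
#' the same seed the output is bitwise reproducible.
#'
#' @param linear_img `image_patch`, encoding `"standard_linear"`.
#' @param cfg A `scanner_sim_config`.
#' @return An `image_patch` with encoding `"device_gamma"`.
#' @export
simulate_scan <- function(linear_img, cfg) {
  if (linear_img$encoding != "standard_linear")
    stop("encoding error: simulate_scan expects a 'standard_linear' image")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- .px_mat(linear_img) %*% t(cfg$device_matrix)
  m <- sweep(m, 2, cfg$incident, "*")
  if (cfg$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, cfg$noise_sd)
  m <- pmin(pmax(m, 0), 1)^(1 / cfg$gamma)
  image_patch(.px_unmat(m, linear_img), "device_gamma",
              linear_img$pixel_size_um)
}

# --- colour chart ----------------------------------------------------------

#' Default colour-chart layout
#'
#' Twelve patches in a 3 x 4 grid (rows A, B, C) plus a background
#' rectangle in the top-left margin, on a 160 x 208 canvas.
#'
#' @param patch Patch side length in pixels.
#' @param gap Gap between patches.
#' @param margin Outer margin.
#' @return Named list of rectangles `c(row0, col0, height, width)` plus
#'   attribute `canvas` with the image height and width.
#' @export
default_chart_layout <- function(patch = 32, gap = 16, margin = 16) {
  out <- list()
  for (r in 1:3) for (cc in 1:4) {
    id <- paste0(c("A", "B", "C")[r], cc)
    out[[id]] <- c(margin + (r - 1) * (patch + gap),
                   margin + (cc - 1) * (patch + gap), patch, patch)
  }
  out[["BG"]] <- c(2, 2, margin - 4, margin - 4)
  h <- 2 * margin + 3 * patch + 2 * gap
  w <- 2 * margin + 4 * patch + 3 * gap
  attr(out, "canvas") <- c(h, w)
  out
}

#' Render a colour chart slide and scan it
#'
#' Fills the patch rectangles with the reference colours on a background
#' of the BG colour, then applies the scanner forward model.
#'
#' @param reference `chart_colors`, role `"reference"`.
#' @param cfg A [scanner_sim_config()].
#' @param layout Chart layout with a `canvas` attribute (default
#'   [default_chart_layout()]).
#' @return List with `image` (`image_patch`, device encoding) and
#'   `layout`.
#' @export
render_color_chart <- function(reference, cfg, layout = default_chart_layout()) {
  canvas <- attr(layout, "canvas")
  if (is.null(canvas)) stop("layout must carry a canvas attribute")
  if (canvas[1] < 1 || canvas[2] < 1) stop("zero-size canvas requested")
  bg <- reference$values[, "BG"]
  px <- array(rep(bg, each = canvas[1] * canvas[2]), c(canvas, 3))
  painted <- matrix(FALSE, canvas[1], canvas[2])
  for (id in setdiff(chart_patch_ids(), "BG")) {
    rect <- .check_rect(layout[[id]], canvas, id)
    rows <- (rect[1] + 1):(rect[1] + rect[3])
    cols <- (rect[2] + 1):(rect[2] + rect[4])
    if (any(painted[rows, cols])) stop("layout error: overlapping rectangles")
    painted[rows, cols] <- TRUE
    for (ch in 1:3) px[rows, cols, ch] <- reference$values[ch, id]
  }
  img <- simulate_scan(image_patch(px, "standard_linear"), cfg)
  list(image = img, layout = layout)
}

# --- staining batches and the calibrator slide -----------------------------

#' Staining-batch configuration
#'
#' A batch is characterized by a multiplicative DAB intensity factor
#' (day-to-day staining variation), its stain OD directions, and the
#' nominal DAB optical densities of the ten calibrator bead levels.
#'
#' @param dab_scale Multiplicative DAB OD factor (> 0); 1 is the
#'   reference batch.
#' @param dab_vector,hematoxylin_vector Unit OD directions; defaults are
#'   the Ruifrok-Johnston values.
#' @param bead_level_ods Strictly increasing nominal DAB ODs of the ten
#'   bead levels; the default ladder spans 0.02 to 1.2 geometrically.
#' @return An object of class `stain_batch_config`.
#' @export
stain_batch_config <- function(dab_scale = 1,
                               dab_vector = ruifrok_vectors()$dab,
                               hematoxylin_vector = ruifrok_vectors()$hematoxylin,
                               bead_level_ods = default_bead_ladder()) {
  if (dab_scale <= 0) stop("dab_scale must be positive")
  if (any(diff(bead_level_ods) <= 0))
    stop("bead level ODs must be strictly increasing")
  structure(list(dab_scale = dab_scale,
                 dab_vector = dab_vector / sqrt(sum(dab_vector^2)),
                 hematoxylin_vector =
                   hematoxylin_vector / sqrt(sum(hematoxylin_vector^2)),
                 bead_level_ods = as.numeric(bead_level_ods)),
            class = "stain_batch_config")
}

#' Nominal bead-ladder optical densities
#'
#' @param n Number of levels.
#' @param od_min,od_max Range of the geometric ladder.
#' @return Strictly increasing numeric vector of length `n`.
#' @export
default_bead_ladder <- function(n = 10, od_min = 0.02, od_max = 1.2) {
  od_min * (od_max / od_min)^((seq_len(n) - 1) / (n - 1))
}

#' Default calibrator-slide geometry
#'
#' Ten bead disks in two rows of five (levels 1-5 top row left to right,
#' 6-10 bottom row).
#'
#' @param radius Bead radius in pixels.
#' @param pitch Centre-to-centre spacing.
#' @param margin Border margin.
#' @return List with `centers` (10 x 2), `radius`, `canvas`.
#' @export
default_calibrator_geometry <- function(radius = 10, pitch = 30, margin = 17) {
  cr <- c(rep(margin, 5), rep(margin + pitch + 4, 5))
  cc <- rep(margin + (0:4) * pitch, 2)
  canvas <- c(2 * margin + pitch + 4, 2 * margin + 4 * pitch)
  list(centers = cbind(cr, cc), radius = radius, canvas = canvas)
}

#' Per-level measurement rectangles of a calibrator geometry
#'
#' Square rectangles around each bead centre, for the layout-driven path
#' of [measure_bead_panel()].
#'
#' @param geometry A calibrator geometry (see
#'   [default_calibrator_geometry()]).
#' @return List of 10 rectangles `c(row0, col0, height, width)`.
#' @export
calibrator_layout <- function(geometry = default_calibrator_geometry()) {
  side <- 2 * geometry$radius + 2
  lapply(seq_len(nrow(geometry$centers)), function(k) {
    c(geometry$centers[k, 1] - geometry$radius - 1,
      geometry$centers[k, 2] - geometry$radius - 1, side, side)
  })
}

#' Render an IHC calibrator slide and scan it
#'
#' Draws the ten bead levels with OD `dab_scale * level_od * dab_vector`,
#' converts to linear RGB and applies the scanner model. The returned
#' ground-truth panel holds the exact per-level ODs.
#'
#' @param batch A [stain_batch_config()].
#' @param cfg A [scanner_sim_config()].
#' @param geometry Calibrator geometry (default
#'   [default_calibrator_geometry()]).
#' @return List with `image` (device encoding), `truth` (a
#'   [bead_panel()]), and `geometry`.
#' @export
render_calibrator <- function(batch, cfg,
                              geometry = default_calibrator_geometry()) {
  canvas <- geometry$canvas
  if (any(geometry$centers[, 1] + geometry$radius > canvas[1]) ||
      any(geometry$centers[, 2] + geometry$radius > canvas[2]) ||
      any(geometry$centers - geometry$radius < 0))
    stop("geometry overflow: beads do not fit the canvas")
  ods <- batch$dab_scale * batch$bead_level_ods
  od <- array(0, c(canvas, 3))
  for (k in seq_along(ods)) {
    ctr <- geometry$centers[k, ]
    rows <- max(1, floor(ctr[1] - geometry$radius)):
      min(canvas[1], ceiling(ctr[1] + geometry$radius))
    cols <- max(1, floor(ctr[2] - geometry$radius)):
      min(canvas[2], ceiling(ctr[2] + geometry$radius))
    dd <- sqrt(outer((rows - ctr[1])^2, (cols - ctr[2])^2, "+"))
    sel <- dd <= geometry$radius
    for (ch in 1:3) {
      plane <- od[rows, cols, ch]
      plane[sel] <- ods[k] * batch$dab_vector[ch]
      od[rows, cols, ch] <- plane
    }
  }
  img <- simulate_scan(od_to_rgb(od), cfg)
  truth <- bead_panel(outer(batch$dab_vector, ods))
  list(image = img, truth = truth, geometry = geometry)
}

# --- tissue phantoms -------------------------------------------------------

#' Tissue phantom specification
#'
#' Cells are drawn as a hematoxylin nucleus disk surrounded by a DAB
#' membrane annulus. The nominal membrane OD of each cell is sampled
#' from a mixture of uniform components; per-status default mixtures are
#' provided by [default_membrane_mixture()].
#'
#' @param intended_status Intended HER2 status of the phantom
#'   (`"0"`, `"1+"`, `"2+"`, `"3+"`); selects the default OD mixture.
#' @param height,width Image size in pixels.
#' @param n_cells Number of cells to place.
#' @param membrane_mix Data frame with columns `weight`, `lo`, `hi`:
#'   mixture of uniform membrane-OD components on the reference scale.
#' @param nucleus_radius Integer range of nucleus radii in pixels.
#' @param membrane_band Membrane annulus width in pixels.
#' @param nucleus_hem_od Hematoxylin OD of the nucleus.
#' @param seed Integer seed for placement and OD sampling.
#' @return An object of class `tissue_phantom_spec`.
#' @export
tissue_phantom_spec <- function(intended_status = "2+", height = 180,
                                width = 180, n_cells = 35,
                                membrane_mix =
                                  default_membrane_mixture(intended_status),
                                nucleus_radius = c(4L, 6L),
                                membrane_band = 3, nucleus_hem_od = 0.6,
                                seed = 1) {
  if (n_cells < 1) stop("at least one cell is required")
  if (any(membrane_mix$lo < 0) || any(membrane_mix$hi < membrane_mix$lo))
    stop("membrane OD components must be nonnegative intervals")
  structure(list(intended_status = intended_status, height = height,
                 width = width, n_cells = n_cells,
                 membrane_mix = membrane_mix,
                 nucleus_radius = nucleus_radius,
                 membrane_band = membrane_band,
                 nucleus_hem_od = nucleus_hem_od, seed = seed),
            class = "tissue_phantom_spec")
}

#' Per-status default membrane OD mixtures
#'
#' Uniform-mixture components of nominal membrane DAB OD (reference
#' scale) producing the intended HER2 status under reference thresholds
#' near (0.05, 0.15, 0.29) with comfortable margins from every
#' threshold.
#'
#' @param intended_status `"0"`, `"1+"`, `"2+"` or `"3+"`.
#' @return Data frame with columns `weight`, `lo`, `hi`.
#' @export
default_membrane_mixture <- function(intended_status) {
  switch(intended_status,
    "0"  = data.frame(weight = 1, lo = 0.000, hi = 0.025),
    "1+" = data.frame(weight = c(0.6, 0.4), lo = c(0.08, 0.00),
                      hi = c(0.12, 0.02)),
    "2+" = data.frame(weight = c(0.5, 0.25, 0.25), lo = c(0.18, 0.08, 0.00),
                      hi = c(0.25, 0.12, 0.02)),
    "3+" = data.frame(weight = c(0.6, 0.2, 0.2), lo = c(0.34, 0.18, 0.08),
                      hi = c(0.48, 0.25, 0.12)),
    stop("unknown intended status: ", intended_status)
  )
}

#' Render a tissue phantom and scan it
#'
#' Places non-overlapping cells by dart throwing, composes the OD image
#' from the batch's stain vectors (membrane DAB scaled by `dab_scale`),
#' converts to linear RGB and applies the scanner model. The ground
#' truth table carries each cell's nominal (reference-scale) membrane OD
#' and intended immunoscore under the nominal thresholds.
#'
#' @param spec A [tissue_phantom_spec()].
#' @param batch A [stain_batch_config()].
#' @param cfg A [scanner_sim_config()].
#' @param max_retries Dart-throwing retries per cell before giving up.
#' @return List with `image` (device encoding) and `cells` (ground-truth
#'   data frame).
#' @export
render_tissue <- function(spec, batch, cfg, max_retries = 200) {
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  rmax <- max(spec$nucleus_radius) + spec$membrane_band
  margin <- rmax + 2
  placed <- matrix(numeric(0), 0, 3)  # row, col, outer radius
  for (i in seq_len(spec$n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      r <- sample(spec$nucleus_radius[1]:spec$nucleus_radius[2], 1)
      ro <- r + spec$membrane_band
      cr <- sample(margin:(H - margin), 1)
      cc <- sample(margin:(W - margin), 1)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2) >
              placed[, 3] + ro + 1)) {
        placed <- rbind(placed, c(cr, cc, ro))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: could not place ", spec$n_cells, " cells")
  }
  comp <- sample.int(nrow(spec$membrane_mix), spec$n_cells, replace = TRUE,
                     prob = spec$membrane_mix$weight)
  od_nominal <- stats::runif(spec$n_cells, spec$membrane_mix$lo[comp],
                             spec$membrane_mix$hi[comp])
  dab <- matrix(0, H, W); hem <- matrix(0, H, W)
  for (i in seq_len(spec$n_cells)) {
    cr <- placed[i, 1]; cc <- placed[i, 2]
    rn <- placed[i, 3] - spec$membrane_band
    rows <- (cr - placed[i, 3]):(cr + placed[i, 3])
    cols <- (cc - placed[i, 3]):(cc + placed[i, 3])
    dd <- sqrt(outer((rows - cr)^2, (cols - cc)^2, "+"))
    hsub <- hem[rows, cols]
    hsub[dd <= rn] <- spec$nucleus_hem_od
    hem[rows, cols] <- hsub
    dsub <- dab[rows, cols]
    dsub[dd > rn & dd <= placed[i, 3]] <- od_nominal[i] * batch$dab_scale
    dab[rows, cols] <- dsub
  }
  od <- array(0, c(H, W, 3))
  for (ch in 1:3)
    od[, , ch] <- dab * batch$dab_vector[ch] + hem * batch$hematoxylin_vector[ch]
  img <- simulate_scan(od_to_rgb(od), cfg)
  cells <- data.frame(cell_id = seq_len(spec$n_cells),
                      membrane_dab_od = od_nominal, nucleus_detected = TRUE,
                      row = placed[, 1], col = placed[, 2],
                      nucleus_radius = placed[, 3] - spec$membrane_band)
  list(image = img, cells = cells)
}

# --- full experiment designs -----------------------------------------------

#' Scanner-by-gamma design of the target datasets
#'
#' Ten target datasets over two scanner personalities and display gammas
#' 1.0, 1.8 and 2.2: scanner A twice at 1.0, twice at 1.8, once at 2.2;
#' scanner B twice at 1.0, once at 1.8, twice at 2.2.
#'
#' @return Data frame with columns `scanner`, `gamma`.
#' @export
target_design <- function() {
  data.frame(
    scanner = c("A", "A", "A", "A", "A", "B", "B", "B", "B", "B"),
    gamma = c(1.0, 1.0, 1.8, 1.8, 2.2, 1.0, 1.0, 1.8, 2.2, 2.2)
  )
}

.subseed <- function(seed, k) (seed + 7919 * k) %% 2147483629

#' Simulate a full calibration experiment
#'
#' Renders one reference dataset (scanner A, linear, batch scale 1) and
#' one target dataset per design row (given scanner personality, display
#' gamma, and a batch scale drawn from `scale_range`). Every dataset
#' contains a chart image, a calibrator image and four tissue phantoms
#' with intended HER2 statuses 0, 1+, 2+ and 3+. Tissue geometry per
#' case is fixed across datasets (serial sections of the same case);
#' scanner noise differs per dataset.
#'
#' @param reference Reference chart colours (`chart_colors`).
#' @param design Data frame with columns `scanner`, `gamma` (default
#'   [target_design()]).
#' @param seed Master seed; all sub-seeds derive from it.
#' @param scale_range Range of the per-dataset staining batch scale.
#' @param noise_sd Scanner noise SD.
#' @param n_cells Cells per tissue phantom.
#' @return List with `reference` (dataset), `targets` (list of
#'   datasets), and `manifest` (per-dataset parameters). Each dataset
#'   holds `chart`, `calibrator`, `tissues` (named by intended status)
#'   and the generating parameters.
#' @export
make_experiment <- function(reference, design = target_design(), seed = 1,
                            scale_range = c(0.7, 1.3), noise_sd = 0.003,
                            n_cells = 35) {
  if (nrow(design) < 1) stop("design must have at least one row")
  statuses <- c("0", "1+", "2+", "3+")
  set.seed(seed)
  scales <- stats::runif(nrow(design), scale_range[1], scale_range[2])
  case_seeds <- .subseed(seed, 100 + seq_along(statuses))
  render_dataset <- function(scanner, gamma, scale, dseed) {
    batch <- stain_batch_config(dab_scale = scale)
    cfgk <- function(k) scanner_preset(scanner, gamma = gamma,
                                       noise_sd = noise_sd,
                                       seed = .subseed(dseed, k))
    tissues <- lapply(seq_along(statuses), function(j) {
      spec <- tissue_phantom_spec(statuses[j], n_cells = n_cells,
                                  seed = case_seeds[j])
      render_tissue(spec, batch, cfgk(10 + j))
    })
    names(tissues) <- statuses
    list(chart = render_color_chart(reference, cfgk(1)),
         calibrator = render_calibrator(batch, cfgk(2)),
         tissues = tissues, scanner = scanner, gamma = gamma,
         dab_scale = scale)
  }
  ref_dataset <- render_dataset("A", 1.0, 1.0, .subseed(seed, 1))
  targets <- lapply(seq_len(nrow(design)), function(i) {
    render_dataset(design$scanner[i], design$gamma[i], scales[i],
                   .subseed(seed, 1 + i))
  })
  manifest <- cbind(design, dab_scale = scales,
                    n_tissues = length(statuses))
  list(reference = ref_dataset, targets = targets, manifest = manifest)
}
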