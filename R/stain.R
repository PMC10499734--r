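# Staining-batch calibration from the DAB microbead calibrator slide:
# bead optical-density measurement, DAB stain-vector estimation from the
# lightly stained levels, colour unmixing, and the monotone intensity
# transfer map used either to adjust classification thresholds (method 1)
# or to correct tissue images (method 2).

#' Ruifrok-Johnston stain optical-density directions
#'
#' Widely used unit OD directions for hematoxylin and DAB. The calibrator
#' slide carries DAB only, so the hematoxylin direction cannot be
#' estimated from it and defaults to this standard value.
#'
#' @return Named list with unit 3-vectors `hematoxylin` and `dab`.
#' @export
ruifrok_vectors <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  list(hematoxylin = unit(c(0.650, 0.704, 0.286)),
       dab = unit(c(0.269, 0.568, 0.778)))
}

#' Construct a two-stain colour model
#'
#' Unit OD-space directions for DAB and hematoxylin plus a residual third
#' vector (their normalized cross product) completing the unmixing basis.
#'
#' @param dab_vector 3-vector, nonnegative components.
#' @param hematoxylin_vector 3-vector, nonnegative components; default
#'   the Ruifrok-Johnston hematoxylin direction.
#' @return An object of class `stain_model` with fields `dab_vector`,
#'   `hematoxylin_vector`, `residual_vector`, `matrix` (3 x 3 basis).
#' @export
stain_model <- function(dab_vector,
                        hematoxylin_vector = ruifrok_vectors()$hematoxylin) {
  unit <- function(v) {
    v <- as.numeric(v)
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector must be nonzero")
    v / n
  }
  dab <- unit(dab_vector); hem <- unit(hematoxylin_vector)
  if (any(dab < 0) || any(hem < 0))
    stop("stain vectors must have nonnegative components")
  res <- c(dab[2] * hem[3] - dab[3] * hem[2],
           dab[3] * hem[1] - dab[1] * hem[3],
           dab[1] * hem[2] - dab[2] * hem[1])
  n <- sqrt(sum(res^2))
  if (n < 1e-8) stop("stain vectors are collinear")
  S <- cbind(dab = dab, hematoxylin = hem, residual = res / n)
  if (kappa(S) > 1e6) stop("stain matrix is near-singular")
  structure(list(dab_vector = dab, hematoxylin_vector = hem,
                 residual_vector = res / n, matrix = S),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Stain model (unit OD directions):\n")
  print(round(x$matrix, 4))
  invisible(x)
}

# Unmix into all three channels; stain channels clipped at zero, the
# residual channel kept signed.
.unmix3 <- function(od, stains) {
  d <- dim(od)
  conc <- solve(stains$matrix, t(matrix(od, d[1] * d[2], 3)))
  list(dab = matrix(pmax(conc[1, ], 0), d[1], d[2]),
       hematoxylin = matrix(pmax(conc[2, ], 0), d[1], d[2]),
       residual = matrix(conc[3, ], d[1], d[2]))
}

#' Colour-unmix an optical-density image
#'
#' Per-pixel solve of the 3 x 3 stain system, separating the DAB and
#' hematoxylin signals as intensity (OD) images. Negative concentrations
#' are clipped at zero; the residual channel is discarded.
#'
#' @param od H x W x 3 optical-density array (see [rgb_to_od()]).
#' @param stains A [stain_model()].
#' @return List with H x W matrices `dab` and `hematoxylin`.
#' @export
unmix <- function(od, stains) {
  .unmix3(od, stains)[c("dab", "hematoxylin")]
}

#' Compose an optical-density image from stain intensities
#'
#' Forward model `OD = dab * v_dab + hematoxylin * v_hem`, the inverse of
#' [unmix()] for nonnegative intensities.
#'
#' @param dab,hematoxylin H x W matrices of stain OD intensities.
#' @param stains A [stain_model()].
#' @return H x W x 3 optical-density array.
#' @export
compose_od <- function(dab, hematoxylin, stains) {
  d <- dim(dab)
  od <- array(0, c(d, 3))
  for (ch in 1:3)
    od[, , ch] <- dab * stains$dab_vector[ch] +
      hematoxylin * stains$hematoxylin_vector[ch]
  od
}

# --- bead panel ------------------------------------------------------------

#' Construct a bead panel
#'
#' @param mean_od 3 x n matrix of per-level mean optical densities.
#' @param mean_rgb 3 x n matrix of per-level mean linear RGB colours.
#' @param n_pixels Integer vector of per-level pixel counts.
#' @return An object of class `bead_panel`.
#' @export
bead_panel <- function(mean_od, mean_rgb = 10^(-mean_od),
                       n_pixels = rep(NA_integer_, ncol(mean_od))) {
  mean_od <- as.matrix(mean_od)
  if (nrow(mean_od) != 3) stop("mean_od must be 3 x n")
  structure(list(levels = seq_len(ncol(mean_od)), mean_od = mean_od,
                 mean_rgb = as.matrix(mean_rgb), n_pixels = n_pixels),
            class = "bead_panel")
}

#' @export
print.bead_panel <- function(x, ...) {
  cat(sprintf("Bead panel, %d levels; per-level OD norm:\n", length(x$levels)))
  print(round(sqrt(colSums(x$mean_od^2)), 4))
  invisible(x)
}

#' Measure the bead panel of a calibrator-slide image
#'
#' Converts the image to optical density and averages each concentration
#' level over bead-interior pixels. Beads are found by thresholding the
#' summed OD, labelling connected components and eroding each component;
#' with an explicit layout the erosion happens inside each level
#' rectangle, otherwise components are auto-detected and assigned to
#' levels by grid position (top row left-to-right, then bottom row).
#'
#' @param calib_img `image_patch`, encoding `"standard_linear"`.
#' @param layout Optional named/indexed list of per-level rectangles
#'   `c(row0, col0, height, width)`; `NULL` for auto-detection.
#' @param incident Incident-light 3-vector.
#' @param n_levels Number of concentration levels (10 for the HER2
#'   calibrator).
#' @param od_threshold Summed-OD threshold separating bead from glass.
#' @param min_pixels Components smaller than this are ignored.
#' @return A `bead_panel` with `n_levels` levels.
#' @export
measure_bead_panel <- function(calib_img, layout = NULL,
                               incident = c(1, 1, 1), n_levels = 10,
                               od_threshold = 0.05, min_pixels = 9) {
  od <- rgb_to_od(calib_img, incident)
  odsum <- od[, , 1] + od[, , 2] + od[, , 3]
  mask <- odsum > od_threshold
  brush <- EBImage::makeBrush(3, shape = "box")
  level_mask <- function(m) {
    interior <- EBImage::erode(m * 1, brush) > 0
    if (sum(interior) > 0) interior else m
  }
  masks <- vector("list", n_levels)
  if (!is.null(layout)) {
    if (length(layout) != n_levels)
      stop("layout must describe ", n_levels, " levels")
    for (k in seq_len(n_levels)) {
      rect <- .check_rect(layout[[k]], dim(od), paste0("level", k))
      sub <- matrix(FALSE, nrow(mask), ncol(mask))
      sub[(rect[1] + 1):(rect[1] + rect[3]),
          (rect[2] + 1):(rect[2] + rect[4])] <- TRUE
      m <- mask & sub
      if (sum(m) < min_pixels) {
        # very lightly stained bead: fall back to the central area of the
        # level rectangle (inside the bead by construction), provided it
        # is distinguishable from clear glass at all
        cr <- .central_rect(rect, 0.5)
        m <- matrix(FALSE, nrow(mask), ncol(mask))
        m[(cr[1] + 1):(cr[1] + cr[3]), (cr[2] + 1):(cr[2] + cr[4])] <- TRUE
        if (mean(odsum[m]) <= 0.005)
          stop("missing level: no bead signal detected at level ", k)
        masks[[k]] <- m
        next
      }
      masks[[k]] <- level_mask(m)
    }
  } else {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_pixels)
    if (length(keep) != n_levels)
      stop("missing level: detected ", length(keep), " beads, expected ",
           n_levels)
    cent <- t(vapply(keep, function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      colMeans(w)
    }, numeric(2)))
    band <- as.integer(cent[, 1] > nrow(mask) / 2)      # 0 = top row
    ord <- order(band, cent[, 2])
    for (j in seq_len(n_levels))
      masks[[j]] <- level_mask(lab == keep[ord[j]])
  }
  mean_od <- vapply(masks, function(m) {
    c(mean(od[, , 1][m]), mean(od[, , 2][m]), mean(od[, , 3][m]))
  }, numeric(3))
  mean_rgb <- vapply(masks, function(m) {
    c(mean(calib_img$pixels[, , 1][m]), mean(calib_img$pixels[, , 2][m]),
      mean(calib_img$pixels[, , 3][m]))
  }, numeric(3))
  bead_panel(mean_od, mean_rgb, vapply(masks, sum, integer(1)))
}

#' Estimate the DAB stain vector from a bead panel
#'
#' Unit-normalized mean of the per-level OD directions over the lightly
#' stained levels (OD norm within `od_range`). Darkly stained beads are
#' excluded because strong DAB scatters and departs from Beer-Lambert
#' behaviour.
#'
#' @param panel A `bead_panel`.
#' @param od_range Inclusive-exclusive (low, high) OD-norm window
#'   selecting the lightly stained levels.
#' @return Unit 3-vector.
#' @export
estimate_dab_vector <- function(panel, od_range = c(0.02, 0.6)) {
  norms <- sqrt(colSums(panel$mean_od^2))
  ok <- norms > od_range[1] & norms < od_range[2]
  if (sum(ok) < 2)
    stop("estimation error: need at least 2 lightly stained bead levels")
  dirs <- sweep(panel$mean_od[, ok, drop = FALSE], 2, norms[ok], "/")
  v <- rowMeans(dirs)
  v / sqrt(sum(v^2))
}

#' Per-level DAB optical density of a panel
#'
#' Projection of each level's mean OD onto the panel's DAB direction.
#'
#' @param panel A `bead_panel`.
#' @param dab_vector Unit 3-vector; default estimated from the panel.
#' @return Numeric vector, one DAB OD per level.
#' @export
panel_dab_od <- function(panel, dab_vector = estimate_dab_vector(panel)) {
  as.numeric(dab_vector %*% panel$mean_od)
}

# --- intensity transfer map ------------------------------------------------

#' Build the staining-intensity transfer map between two batches
#'
#' Pairs each calibrator level's DAB OD on the target batch with the same
#' level's DAB OD on the reference batch, giving a monotone piecewise-
#' linear map from the target OD scale to the reference OD scale,
#' anchored at (0, 0). Non-monotone (noisy) ladders are repaired by
#' isotonic regression before the knots are built; beyond the last knot
#' the last segment's slope continues.
#'
#' @param target,reference `bead_panel` objects with equal level counts.
#' @param stains_target,stains_reference [stain_model()]s whose DAB
#'   directions project each panel to scalar DAB OD.
#' @return An object of class `intensity_transfer` with a data frame of
#'   `knots` (columns `target`, `reference`).
#' @export
build_intensity_transfer <- function(target, reference,
                                     stains_target, stains_reference) {
  if (length(target$levels) != length(reference$levels))
    stop("panels have mismatched level counts")
  x <- panel_dab_od(target, stains_target$dab_vector)
  y <- panel_dab_od(reference, stains_reference$dab_vector)
  if (is.unsorted(x)) x <- stats::isoreg(seq_along(x), x)$yf
  if (is.unsorted(y)) y <- stats::isoreg(seq_along(y), y)$yf
  x <- c(0, x); y <- c(0, y)
  # collapse duplicate abscissae so the map is a function
  y <- as.numeric(tapply(y, factor(x, levels = unique(x)), mean))
  x <- unique(x)
  if (length(x) < 2) stop("degenerate panel: no usable OD range")
  structure(list(knots = data.frame(target = x, reference = y)),
            class = "intensity_transfer")
}

#' Identity intensity transfer on a given OD range
#'
#' @param max_od Upper end of the knot range.
#' @return An `intensity_transfer` mapping every OD to itself.
#' @export
identity_transfer <- function(max_od = 1.5) {
  structure(list(knots = data.frame(target = c(0, max_od),
                                    reference = c(0, max_od))),
            class = "intensity_transfer")
}

#' @export
print.intensity_transfer <- function(x, ...) {
  cat("Staining intensity transfer map (target OD -> reference OD):\n")
  print(round(x$knots, 4))
  invisible(x)
}

#' Evaluate an intensity transfer map
#'
#' Piecewise-linear interpolation through the knots; beyond the last knot
#' the last segment's slope is continued.
#'
#' @param object An `intensity_transfer`.
#' @param newdata Nonnegative OD values (any shape; shape is preserved).
#' @param ... Unused.
#' @return Mapped OD values.
#' @export
predict.intensity_transfer <- function(object, newdata, ...) {
  k <- object$knots
  n <- nrow(k)
  x <- as.numeric(newdata)
  out <- stats::approx(k$target, k$reference, xout = pmin(x, k$target[n]),
                       rule = 2)$y
  slope <- (k$reference[n] - k$reference[n - 1]) /
    (k$target[n] - k$target[n - 1])
  over <- x > k$target[n]
  out[over] <- k$reference[n] + slope * (x[over] - k$target[n])
  if (!is.null(dim(newdata))) dim(out) <- dim(newdata)
  out
}

#' @export
plot.intensity_transfer <- function(x, ...) {
  k <- x$knots
  graphics::plot(k$target, k$reference, type = "b", pch = 19,
                 xlab = "target DAB OD", ylab = "reference DAB OD",
                 main = "Staining intensity transfer", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Invert an intensity transfer map
#'
#' Returns the target-scale OD that maps to a given reference-scale OD.
#' On a flat (non-invertible) segment the midpoint is returned with a
#' warning. Beyond the last knot the extrapolated slope is inverted.
#'
#' @param object An `intensity_transfer`.
#' @param y Reference-scale OD values.
#' @return Target-scale OD values.
#' @export
transfer_inverse <- function(object, y) {
  k <- object$knots
  n <- nrow(k)
  vapply(as.numeric(y), function(yi) {
    if (yi >= k$reference[n]) {
      slope <- (k$reference[n] - k$reference[n - 1]) /
        (k$target[n] - k$target[n - 1])
      return(k$target[n] + (yi - k$reference[n]) / slope)
    }
    hit <- which(k$reference == yi)
    if (length(hit) > 1) {
      warning("flat transfer segment: threshold inverted to segment midpoint")
      return((k$target[min(hit)] + k$target[max(hit)]) / 2)
    }
    if (length(hit) == 1) return(k$target[hit])
    lo <- max(which(k$reference < yi))
    hi <- min(which(k$reference > yi))
    k$target[lo] + (yi - k$reference[lo]) *
      (k$target[hi] - k$target[lo]) / (k$reference[hi] - k$reference[lo])
  }, numeric(1))
}

# --- thresholds and the two calibration methods ----------------------------

#' Construct a DAB-intensity threshold set
#'
#' Three strictly increasing positive optical-density thresholds
#' separating immunoscores 0/1, 1/2 and 2/3.
#'
#' @param t1,t2,t3 Thresholds in OD units.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(t1, t2, t3) {
  t <- c(t1 = t1, t2 = t2, t3 = t3)
  if (any(!is.finite(t)) || any(t <= 0) || t[1] >= t[2] || t[2] >= t[3])
    stop("thresholds must be positive and strictly increasing")
  structure(list(t1 = t[[1]], t2 = t[[2]], t3 = t[[3]]),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Immunoscore thresholds (DAB OD): t1 = %.4f, t2 = %.4f, t3 = %.4f\n",
              x$t1, x$t2, x$t3))
  invisible(x)
}

#' @export
as.double.threshold_set <- function(x, ...) c(x$t1, x$t2, x$t3)

#' Method 1: adjust classification thresholds for a target batch
#'
#' Maps each reference-scale threshold back through the inverse of the
#' intensity transfer, yielding thresholds on the target batch's own OD
#' scale so the uncorrected image can be classified directly.
#'
#' @param ref_thresholds A [threshold_set()] on the reference OD scale.
#' @param transfer An `intensity_transfer` (target -> reference).
#' @return A `threshold_set` on the target OD scale.
#' @export
calibrate_thresholds_method1 <- function(ref_thresholds, transfer) {
  t <- transfer_inverse(transfer, as.numeric(ref_thresholds))
  threshold_set(t[1], t[2], t[3])
}

#' Method 2: correct the colour intensity of a tissue image
#'
#' Unmixes the image with the target batch's stain model, maps the DAB
#' channel through the intensity transfer onto the reference scale,
#' recomposes with the reference stain vectors (hematoxylin and the
#' signed residual pass through untouched) and converts back to linear
#' RGB. The corrected image can then be classified with the reference
#' thresholds.
#'
#' @param img `image_patch`, encoding `"standard_linear"`.
#' @param transfer An `intensity_transfer` (target -> reference).
#' @param stains_target,stains_reference [stain_model()]s of the two
#'   batches.
#' @param incident Incident-light 3-vector.
#' @return Corrected `image_patch`, encoding `"standard_linear"`.
#' @export
correct_image_method2 <- function(img, transfer, stains_target,
                                  stains_reference = stains_target,
                                  incident = c(1, 1, 1)) {
  od <- rgb_to_od(img, incident)
  ch <- .unmix3(od, stains_target)
  dab <- predict(transfer, ch$dab)
  d <- dim(dab)
  od2 <- array(0, c(d, 3))
  for (i in 1:3)
    od2[, , i] <- dab * stains_reference$dab_vector[i] +
      ch$hematoxylin * stains_reference$hematoxylin_vector[i] +
      ch$residual * stains_reference$residual_vector[i]
  od_to_rgb(pmax(od2, 0), incident)
}
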