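# Scanner (device) calibration from a colour chart slide: patch colour
# extraction, gamma linearization fitted on grayscale-patch luminance,
# and a white-point-preserving polynomial colour correction (WPPLS)
# solved as an equality-constrained least-squares problem.

# --- layouts ---------------------------------------------------------------

# A layout is a named list id -> c(row0, col0, height, width), 0-based,
# half-open, row-major. Shared by chart extraction and the renderers.
.check_rect <- function(rect, dims, id) {
  rect <- as.numeric(rect)
  if (length(rect) != 4 || any(!is.finite(rect)) || rect[3] < 1 || rect[4] < 1)
    stop("layout error: invalid rectangle for patch '", id, "'")
  if (rect[1] < 0 || rect[2] < 0 ||
      rect[1] + rect[3] > dims[1] || rect[2] + rect[4] > dims[2])
    stop("layout error: rectangle for patch '", id, "' out of image bounds")
  rect
}

# Central sub-rectangle covering `frac` of each side.
.central_rect <- function(rect, frac) {
  h <- max(1, round(rect[3] * frac)); w <- max(1, round(rect[4] * frac))
  r0 <- rect[1] + floor((rect[3] - h) / 2)
  c0 <- rect[2] + floor((rect[4] - w) / 2)
  c(r0, c0, h, w)
}

#' Mean patch colours of a scanned colour chart
#'
#' Averages the central area of each chart patch (by default the central
#' 50% of the rectangle per side) and returns the 3 x 13 scanned-colour
#' matrix in canonical patch order.
#'
#' @param chart_img An `image_patch` of the chart slide.
#' @param layout Named list mapping each patch id (A1..C4, BG) to a
#'   rectangle `c(row0, col0, height, width)`, 0-based, half-open.
#' @param central_frac Fraction of each rectangle side to average over.
#' @return A `chart_colors` object with role `"scanned"`.
#' @export
extract_patch_colors <- function(chart_img, layout, central_frac = 0.5) {
  ids <- chart_patch_ids()
  missing <- setdiff(ids, names(layout))
  if (length(missing))
    stop("layout error: missing patch id(s): ", paste(missing, collapse = ", "))
  d <- dim(chart_img$pixels)
  cols <- vapply(ids, function(id) {
    rect <- .check_rect(layout[[id]], d, id)
    cr <- .central_rect(rect, central_frac)
    rows <- (cr[1] + 1):(cr[1] + cr[3])
    cls <- (cr[2] + 1):(cr[2] + cr[4])
    apply(chart_img$pixels[rows, cls, , drop = FALSE], 3, mean)
  }, numeric(3))
  chart_colors(cols, role = "scanned")
}

#' Incident light from the chart background
#'
#' Mean RGB of the central area of the clear-glass (BG) patch of a raw
#' chart image, used as the default incident-light vector I0.
#'
#' @inheritParams extract_patch_colors
#' @return Positive numeric 3-vector.
#' @export
incident_from_chart <- function(chart_img, layout, central_frac = 0.5) {
  rect <- .check_rect(layout[["BG"]], dim(chart_img$pixels), "BG")
  cr <- .central_rect(rect, central_frac)
  i0 <- apply(chart_img$pixels[(cr[1] + 1):(cr[1] + cr[3]),
                               (cr[2] + 1):(cr[2] + cr[4]), , drop = FALSE],
              3, mean)
  if (any(i0 <= 0)) stop("incident light estimated as nonpositive")
  i0
}

# --- gamma -----------------------------------------------------------------

#' Estimate the display gamma from grayscale chart patches
#'
#' Finds the exponent gamma minimizing the squared luminance error
#' `sum((Ys^gamma - Yr)^2)` over the grayscale patches (A1, B1, C1 and
#' background), by bounded 1-D minimization. Luminance is the Y row of
#' the conversion matrix. Patches whose scanned or reference luminance is
#' outside (0, 1) carry no gamma information (saturated, dark, or the
#' fixed point at white) and are excluded.
#'
#' @param scanned `chart_colors` of the incident-normalized, still
#'   gamma-encoded chart.
#' @param reference `chart_colors` of the reference chart.
#' @param C Conversion matrix used for luminance.
#' @param bounds Search interval for gamma.
#' @return An object of class `gamma_estimate` with fields `gamma`,
#'   `fit_residual`, `n_patches`.
#' @export
estimate_gamma <- function(scanned, reference, C = srgb_matrix(),
                           bounds = c(0.2, 5.0)) {
  yrow <- C[2, ]
  ids <- grayscale_patch_ids()
  Ys <- as.numeric(yrow %*% scanned$values[, ids])
  Yr <- as.numeric(yrow %*% reference$values[, ids])
  ok <- Ys > 0 & Ys < 1 & Yr > 0 & Yr < 1
  if (sum(ok) < 2)
    stop("insufficient data: need at least 2 unsaturated grayscale patches")
  Ys <- Ys[ok]; Yr <- Yr[ok]
  obj <- function(g) sum((Ys^g - Yr)^2)
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-10)
  structure(list(gamma = opt$minimum, fit_residual = opt$objective,
                 n_patches = sum(ok)),
            class = "gamma_estimate")
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat(sprintf("gamma = %.4f (luminance SSE %.3g on %d grayscale patches)\n",
              x$gamma, x$fit_residual, x$n_patches))
  invisible(x)
}

# --- white-point-preserving polynomial colour map --------------------------

# 5-term polynomial feature matrix: rows (R, G, B, R*G*B, 1), one column
# per input colour.
.poly_features <- function(m) {
  rbind(m, m[1, ] * m[2, ] * m[3, ], 1)
}

POLY_BASIS <- c("R", "G", "B", "R*G*B", "1")

#' Fit the white-point-preserving polynomial colour correction
#'
#' Solves, per output channel, the least-squares problem
#' `Gr = M{Gs}` over the 13 chart patches with the 5-term basis
#' (R, G, B, R*G*B, 1), subject to the equality constraint
#' `M{(1,1,1)} = (1,1,1)` so the background white is preserved exactly.
#' The constraint is imposed through the KKT (Lagrange-multiplier)
#' system, so it holds to machine precision regardless of noise.
#'
#' @param reference `chart_colors`, role `"reference"` (target colours Gr).
#' @param scanned_linear `chart_colors` of the linearized,
#'   incident-normalized scanned chart (Gs).
#' @return An object of class `polynomial_color_map` with fields `basis`,
#'   `coeffs` (3 x 5), `white_preserving`.
#' @export
fit_wppls <- function(reference, scanned_linear) {
  Gr <- reference$values
  Phi <- .poly_features(scanned_linear$values)       # 5 x 13
  A <- Phi %*% t(Phi)                                # 5 x 5 normal matrix
  a <- .poly_features(matrix(1, 3, 1))[, 1]          # constraint: features of u
  kkt <- rbind(cbind(2 * A, a), c(a, 0))
  if (abs(det(kkt)) < 1e-12 || rcond(kkt) < 1e-12)
    stop("degenerate fit: chart colours do not span the polynomial basis")
  coeffs <- t(vapply(1:3, function(ch) {
    rhs <- c(2 * (Phi %*% Gr[ch, ]), 1)
    solve(kkt, rhs)[1:5]
  }, numeric(5)))
  dimnames(coeffs) <- list(c("R", "G", "B"), POLY_BASIS)
  structure(list(basis = POLY_BASIS, coeffs = coeffs, white_preserving = TRUE),
            class = "polynomial_color_map")
}

#' @export
print.polynomial_color_map <- function(x, ...) {
  cat("White-point-preserving polynomial colour map, basis (R, G, B, R*G*B, 1):\n")
  print(round(x$coeffs, 5))
  invisible(x)
}

#' Apply a polynomial colour map to colours
#'
#' @param object A `polynomial_color_map`.
#' @param newdata 3-vector, 3 x n matrix, or `chart_colors` of linear
#'   device colours.
#' @param ... Unused.
#' @return Mapped colours, same shape as the input.
#' @export
predict.polynomial_color_map <- function(object, newdata, ...) {
  if (inherits(newdata, "chart_colors")) {
    out <- newdata
    out$values[] <- object$coeffs %*% .poly_features(newdata$values)
    return(out)
  }
  v <- is.null(dim(newdata))
  m <- object$coeffs %*%
    .poly_features(if (v) matrix(as.numeric(newdata), 3) else newdata)
  if (v) { m <- as.numeric(m); names(m) <- c("R", "G", "B") }
  m
}

#' Apply a colour map to a whole image
#'
#' Per-pixel polynomial evaluation. Values may leave `[0, 1]`; clipping
#' happens only at image export.
#'
#' @param img An `image_patch` with encoding `"device_linear"`.
#' @param map A `polynomial_color_map`.
#' @return An `image_patch` with encoding `"standard_linear"`.
#' @export
apply_color_map <- function(img, map) {
  if (img$encoding != "device_linear")
    stop("encoding error: colour map expects a 'device_linear' image")
  out <- t(predict(map, t(.px_mat(img))))
  image_patch(.px_unmat(out, img), "standard_linear", img$pixel_size_um)
}

# --- full device calibration ----------------------------------------------

#' Fit a scanner calibration from a scanned colour chart
#'
#' The device characterization pipeline: estimate the incident light from
#' the chart's glass background (unless supplied), normalize the patch
#' colours, fit the display gamma on the grayscale patches, linearize,
#' and fit the white-point-preserving polynomial colour correction
#' against the reference chart colours.
#'
#' @param chart_img Raw scanned chart (`image_patch`, encoding
#'   `"device_gamma"`).
#' @param layout Chart layout (see [extract_patch_colors()]).
#' @param reference Reference chart colours, e.g. from
#'   [compute_reference_chart()].
#' @param C Conversion matrix (default [srgb_matrix()]).
#' @param incident Optional incident-light 3-vector; default measured
#'   from the chart background.
#' @param central_frac Central patch fraction for extraction.
#' @return An object of class `scanner_calibration`.
#' @export
scanner_calibration <- function(chart_img, layout, reference,
                                C = srgb_matrix(), incident = NULL,
                                central_frac = 0.5) {
  if (is.null(incident))
    incident <- incident_from_chart(chart_img, layout, central_frac)
  gs_raw <- extract_patch_colors(chart_img, layout, central_frac)
  gs_raw$values <- gs_raw$values / incident
  gamma <- estimate_gamma(gs_raw, reference, C)
  gs_lin <- gs_raw
  gs_lin$values <- gs_raw$values^gamma$gamma
  map <- fit_wppls(reference, gs_lin)
  fitted <- predict(map, gs_lin)
  fitted$role <- "reference"
  de <- delta_e(linear_rgb_to_lab(fitted$values, C),
                linear_rgb_to_lab(reference$values, C))
  names(de) <- chart_patch_ids()
  structure(list(gamma = gamma, color_map = map, incident = incident,
                 reference = reference, scanned = gs_raw, fitted = fitted,
                 patch_de = de, C = C),
            class = "scanner_calibration")
}

#' @export
print.scanner_calibration <- function(x, ...) {
  cat("Scanner calibration (chart-based colorimetric characterization)\n")
  cat(sprintf("  incident light I0: (%.4f, %.4f, %.4f)\n",
              x$incident[1], x$incident[2], x$incident[3]))
  cat(sprintf("  gamma: %.4f\n", x$gamma$gamma))
  cat(sprintf("  mean patch dE* after calibration: %.4f (%s)\n",
              mean(x$patch_de), delta_e_interpretation(mean(x$patch_de))))
  invisible(x)
}

#' @export
summary.scanner_calibration <- function(object, ...) {
  print(object)
  cat("  colour map coefficients:\n")
  print(round(object$color_map$coeffs, 5))
  cat("  per-patch residual dE*:\n")
  print(round(object$patch_de, 4))
  invisible(object)
}

#' @export
coef.scanner_calibration <- function(object, ...) {
  list(gamma = object$gamma$gamma, color_map = object$color_map$coeffs,
       incident = object$incident)
}

#' @export
residuals.scanner_calibration <- function(object, ...) object$patch_de

#' Apply a fitted scanner calibration to an image
#'
#' Runs normalize -> linearize -> colour map, turning a raw scanner image
#' into standard linear RGB.
#'
#' @param object A `scanner_calibration`.
#' @param newdata An `image_patch` with encoding `"device_gamma"`.
#' @param ... Unused.
#' @return An `image_patch` with encoding `"standard_linear"`.
#' @export
predict.scanner_calibration <- function(object, newdata, ...) {
  img <- normalize_by_incident(newdata, object$incident)
  img$pixels <- pmin(pmax(img$pixels, 0), 1)
  img <- linearize(img, object$gamma)
  apply_color_map(img, object$color_map)
}

# --- dE* evaluation map ----------------------------------------------------

#' Pixelwise colour-difference map between two images
#'
#' Computes the CIE76 dE* at every pixel of two aligned standard-linear
#' images, with summary mean/SD over an optional mask and a 64-bin
#' histogram of the masked values. The caller must supply aligned images;
#' registration is out of scope.
#'
#' @param imgA,imgB `image_patch` objects of identical size, encoding
#'   `"standard_linear"`.
#' @param mask Optional H x W logical matrix restricting the summary.
#' @param C,white Conversion matrix and reference white.
#' @param nbins Number of histogram bins.
#' @return An object of class `delta_e_map` with fields `values`, `mask`,
#'   `mean`, `sd`, `histogram` (counts), `breaks`.
#' @export
compute_de_map <- function(imgA, imgB, mask = NULL, C = srgb_matrix(),
                           white = d65_white(), nbins = 64) {
  if (!identical(dim(imgA$pixels), dim(imgB$pixels)))
    stop("image dimensions differ; supply aligned images")
  if (imgA$encoding != "standard_linear" || imgB$encoding != "standard_linear")
    stop("encoding error: dE* map requires 'standard_linear' images")
  d <- dim(imgA$pixels)
  labA <- linear_rgb_to_lab(t(.px_mat(imgA)), C, white)
  labB <- linear_rgb_to_lab(t(.px_mat(imgB)), C, white)
  de <- matrix(delta_e(labA, labB), d[1], d[2])
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2])) stop("mask dimensions differ from image")
  vals <- de[mask]
  top <- max(vals, 1e-12)
  breaks <- seq(0, top, length.out = nbins + 1)
  counts <- tabulate(pmin(findInterval(vals, breaks,
                                       rightmost.closed = TRUE), nbins),
                     nbins)
  structure(list(values = de, mask = mask, mean = mean(vals),
                 sd = stats::sd(vals), histogram = counts, breaks = breaks),
            class = "delta_e_map")
}

#' @export
print.delta_e_map <- function(x, ...) {
  cat(sprintf("dE* map %d x %d: mean %.3f, SD %.3f over %d masked pixels (%s)\n",
              nrow(x$values), ncol(x$values), x$mean, x$sd, sum(x$mask),
              delta_e_interpretation(x$mean)))
  invisible(x)
}

#' @export
plot.delta_e_map <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$histogram, names.arg = round(mids, 2), space = 0,
                    xlab = "dE*", ylab = "pixels",
                    main = sprintf("dE* histogram (mean %.2f)", x$mean), ...)
  invisible(x)
}
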