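# Device-independent colour math: spectral transmittance -> CIEXYZ ->
# standard linear RGB -> CIELAB, and the CIE76 colour difference dE*.
# The standard colour space of the whole package is linear RGB with sRGB
# primaries and a D65 white point; all calibration targets live there.

#' Canonical colour-chart patch identifiers
#'
#' Twelve colour patches (rows A-C, columns 1-4) plus the clear-glass
#' background patch `BG`, in the canonical column order used by every
#' 3 x 13 chart-colour matrix in the package.
#'
#' @return Character vector of length 13.
#' @export
chart_patch_ids <- function() {
  c(paste0(rep(c("A", "B", "C"), each = 4), 1:4), "BG")
}

# Grayscale patches used for the gamma fit (column 1 of each row plus glass).
grayscale_patch_ids <- function() c("A1", "B1", "C1", "BG")

#' The wavelength grid of the chart's spectral calibration data
#'
#' @return Numeric vector, 340 to 830 nm in 5 nm steps (99 samples).
#' @export
spectral_grid <- function() seq(340, 830, by = 5)

# Piecewise Gaussian with independent left/right widths, the building block
# of the analytic colour-matching-function approximation.
.pgauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 2-degree colour-matching functions on the chart grid
#'
#' Analytic multi-lobe piecewise-Gaussian approximation to the CIE 1931
#' standard observer, evaluated on the 340-830 nm / 5 nm grid and clamped
#' at zero. The approximation error is absorbed downstream by the
#' white-point normalization in [spectral_to_xyz()], which makes the full
#' pipeline exactly self-consistent at the white point.
#'
#' @return Data frame with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function() {
  wl <- spectral_grid()
  xbar <- 1.056 * .pgauss(wl, 599.8, 37.9, 31.0) +
    0.362 * .pgauss(wl, 442.0, 16.0, 26.7) -
    0.065 * .pgauss(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * .pgauss(wl, 568.8, 46.9, 40.5) +
    0.286 * .pgauss(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * .pgauss(wl, 437.0, 11.8, 36.0) +
    0.681 * .pgauss(wl, 459.0, 26.0, 13.8)
  data.frame(
    wavelength_nm = wl,
    xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0)
  )
}

#' Relative spectral power of the reference illuminant
#'
#' Analytic approximation to daylight D65: the Planckian radiator at
#' 6504 K, normalized to 1 at 560 nm. Only this illuminant is supported;
#' chromatic adaptation between illuminants is out of scope.
#'
#' @return Data frame with columns `wavelength_nm`, `power`.
#' @export
illuminant_d65 <- function() {
  wl <- spectral_grid()
  planck <- function(l_nm, temp) {
    l <- l_nm * 1e-9
    c2 <- 1.4388e-2  # second radiation constant, m K
    l^-5 / (exp(c2 / (l * temp)) - 1)
  }
  p <- planck(wl, 6504) / planck(560, 6504)
  data.frame(wavelength_nm = wl, power = p)
}

#' Linear RGB to XYZ conversion matrix (sRGB primaries, D65 white)
#'
#' The standard sRGB matrix C such that `T = C %*% R` maps linear RGB to
#' CIEXYZ tristimulus values (Y of white = 1).
#'
#' @return A 3 x 3 numeric matrix.
#' @export
srgb_matrix <- function() {
  matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), nrow = 3, byrow = TRUE, dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))
}

#' D65 white point in XYZ
#'
#' The tristimulus values of linear RGB (1,1,1) under the package's
#' conversion matrix, i.e. the white every conversion is anchored to.
#'
#' @param C Conversion matrix, by default [srgb_matrix()].
#' @return Named numeric 3-vector (X, Y, Z).
#' @export
d65_white <- function(C = srgb_matrix()) {
  w <- as.numeric(C %*% c(1, 1, 1))
  names(w) <- c("X", "Y", "Z")
  w
}

#' Construct and validate a spectral transmittance curve
#'
#' @param transmittance Unitless fractions in `[0, 1]`, one per grid point.
#' @param wavelengths_nm Wavelength grid; must equal [spectral_grid()].
#' @return An object of class `spectral_curve`.
#' @export
spectral_curve <- function(transmittance, wavelengths_nm = spectral_grid()) {
  grid <- spectral_grid()
  if (length(wavelengths_nm) != length(grid) || any(wavelengths_nm != grid))
    stop("grid mismatch: wavelengths must be 340..830 nm in 5 nm steps")
  transmittance <- as.numeric(transmittance)
  if (length(transmittance) != length(grid))
    stop("grid mismatch: expected ", length(grid), " transmittance samples")
  if (any(!is.finite(transmittance)) ||
      any(transmittance < 0) || any(transmittance > 1))
    stop("transmittance out of range: values must lie in [0, 1]")
  structure(list(wavelengths_nm = grid, transmittance = transmittance),
            class = "spectral_curve")
}

.check_grid <- function(wl) {
  grid <- spectral_grid()
  if (length(wl) != length(grid) || any(wl != grid))
    stop("grid mismatch: tables must share the 340..830/5 nm grid")
  invisible(TRUE)
}

#' Spectral transmittance to CIEXYZ
#'
#' Tristimulus values by summation over the wavelength grid,
#' `X = kX * sum(S * xbar * T)` (likewise Y, Z). The normalization
#' constants are fixed per channel so that full transmittance (T == 1)
#' maps exactly onto the white point implied by the conversion matrix;
#' in particular `kY = 1 / sum(S * ybar)` so Y = 1 for T == 1.
#'
#' @param curve A [spectral_curve()].
#' @param illum Illuminant table (default [illuminant_d65()]).
#' @param cmf Colour-matching functions (default [cie_cmf()]).
#' @param white White point the normalization is anchored to.
#' @return Named numeric 3-vector (X, Y, Z).
#' @export
spectral_to_xyz <- function(curve, illum = illuminant_d65(), cmf = cie_cmf(),
                            white = d65_white()) {
  if (!inherits(curve, "spectral_curve")) curve <- spectral_curve(curve)
  .check_grid(illum$wavelength_nm)
  .check_grid(cmf$wavelength_nm)
  if (any(illum$power < 0)) stop("illuminant power must be nonnegative")
  S <- illum$power
  Tt <- curve$transmittance
  k <- white / c(sum(S * cmf$xbar), sum(S * cmf$ybar), sum(S * cmf$zbar))
  out <- c(
    X = k[[1]] * sum(S * cmf$xbar * Tt),
    Y = k[[2]] * sum(S * cmf$ybar * Tt),
    Z = k[[3]] * sum(S * cmf$zbar * Tt)
  )
  out
}

#' CIEXYZ to linear RGB
#'
#' Inverts `T = C %*% R`. No clipping is applied: out-of-gamut values pass
#' through so that downstream fitting sees unclipped residuals.
#'
#' @param xyz Numeric 3-vector or 3 x n matrix of tristimulus values.
#' @param C Conversion matrix (default [srgb_matrix()]).
#' @return Numeric 3-vector or 3 x n matrix of linear RGB values.
#' @export
xyz_to_linear_rgb <- function(xyz, C = srgb_matrix()) {
  if (abs(det(C)) < 1e-12) stop("conversion matrix is singular")
  v <- is.null(dim(xyz))
  m <- solve(C, if (v) matrix(as.numeric(xyz), 3) else xyz)
  if (v) { m <- as.numeric(m); names(m) <- c("R", "G", "B") }
  m
}

#' Linear RGB to CIEXYZ
#'
#' @inheritParams xyz_to_linear_rgb
#' @param rgb Numeric 3-vector or 3 x n matrix of linear RGB values.
#' @return Tristimulus values, same shape as the input.
#' @export
linear_rgb_to_xyz <- function(rgb, C = srgb_matrix()) {
  v <- is.null(dim(rgb))
  m <- C %*% (if (v) matrix(as.numeric(rgb), 3) else rgb)
  if (v) { m <- as.numeric(m); names(m) <- c("X", "Y", "Z") }
  m
}

# CIE 1976 nonlinearity f(t); delta = 6/29.
.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' CIEXYZ to CIELAB
#'
#' Standard CIE 1976 L*a*b* with respect to a reference white.
#'
#' @param xyz Numeric 3-vector or 3 x n matrix.
#' @param white Reference white XYZ (default [d65_white()]); its Y must be
#'   positive.
#' @return 3-vector or 3 x n matrix with components (L, a, b).
#' @export
xyz_to_lab <- function(xyz, white = d65_white()) {
  if (white[[2]] <= 0) stop("reference white must have positive luminance")
  v <- is.null(dim(xyz))
  m <- if (v) matrix(as.numeric(xyz), 3) else xyz
  fx <- .lab_f(m[1, ] / white[[1]])
  fy <- .lab_f(m[2, ] / white[[2]])
  fz <- .lab_f(m[3, ] / white[[3]])
  lab <- rbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (v) { lab <- as.numeric(lab); names(lab) <- c("L", "a", "b") }
  lab
}

#' Linear RGB to CIELAB
#'
#' @inheritParams linear_rgb_to_xyz
#' @param white Reference white XYZ (default [d65_white()]).
#' @return CIELAB values, same shape as the input.
#' @export
linear_rgb_to_lab <- function(rgb, C = srgb_matrix(), white = d65_white()) {
  xyz_to_lab(linear_rgb_to_xyz(rgb, C), white = white)
}

#' CIE76 colour difference dE*
#'
#' Euclidean distance in CIELAB. Values below 1.0 are imperceptible to a
#' human observer; between 1.0 and 2.0 only an experienced observer
#' notices the difference.
#'
#' @param lab1,lab2 CIELAB 3-vectors or 3 x n matrices.
#' @return Nonnegative scalar or length-n vector.
#' @export
delta_e <- function(lab1, lab2) {
  d <- (if (is.null(dim(lab1))) matrix(as.numeric(lab1), 3) else lab1) -
    (if (is.null(dim(lab2))) matrix(as.numeric(lab2), 3) else lab2)
  as.numeric(sqrt(colSums(d^2)))
}

#' Perceptual interpretation of a dE* value
#'
#' @param de Nonnegative dE* values.
#' @return Character vector: `"imperceptible"` (< 1), `"expert-perceptible"`
#'   (1 to 2), `"perceptible"` (> 2).
#' @export
delta_e_interpretation <- function(de) {
  ifelse(de < 1, "imperceptible",
         ifelse(de <= 2, "expert-perceptible", "perceptible"))
}

#' Construct a 3 x 13 chart-colour matrix
#'
#' @param values 3 x 13 numeric matrix, columns in [chart_patch_ids()]
#'   order (A1..C4 then BG), rows R, G, B.
#' @param role `"reference"` or `"scanned"`.
#' @return An object of class `chart_colors`.
#' @export
chart_colors <- function(values, role = c("reference", "scanned")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != 3 || ncol(values) != 13)
    stop("chart layout error: expected a 3 x 13 matrix (12 patches + BG)")
  if (any(!is.finite(values))) stop("chart colours must be finite")
  dimnames(values) <- list(c("R", "G", "B"), chart_patch_ids())
  structure(list(values = values, role = role), class = "chart_colors")
}

#' @export
print.chart_colors <- function(x, ...) {
  cat(sprintf("Chart colours (%s), linear RGB:\n", x$role))
  print(round(x$values, 4))
  invisible(x)
}

#' Reference chart colours from spectral transmittance data
#'
#' Converts the 13 per-patch transmittance curves of the colour chart
#' slide into the 3 x 13 reference matrix Gr of linear RGB colours,
#' via XYZ under the reference illuminant.
#'
#' @param curves List of 13 [spectral_curve()] objects in canonical patch
#'   order (A1..C4, BG), optionally named.
#' @param illum,cmf,C Illuminant, colour-matching functions and conversion
#'   matrix; defaults as elsewhere.
#' @return A `chart_colors` object with role `"reference"`.
#' @export
compute_reference_chart <- function(curves, illum = illuminant_d65(),
                                    cmf = cie_cmf(), C = srgb_matrix()) {
  if (length(curves) != 13)
    stop("chart layout error: exactly 13 spectral curves required (A1..C4, BG)")
  if (!is.null(names(curves))) {
    if (!setequal(names(curves), chart_patch_ids()))
      stop("chart layout error: curve names must be the 13 canonical patch ids")
    curves <- curves[chart_patch_ids()]
  }
  white <- d65_white(C)
  cols <- vapply(curves, function(cv) {
    xyz_to_linear_rgb(spectral_to_xyz(cv, illum, cmf, white = white), C)
  }, numeric(3))
  chart_colors(cols, role = "reference")
}
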