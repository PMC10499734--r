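# Image container and basic radiometric operations. Pixels are stored as
# an H x W x 3 array in [0,1]-ish range with an explicit encoding tag so
# pipeline stages can refuse inputs in the wrong state:
#   device_gamma    raw scanner output, gamma-encoded
#   device_linear   after gamma linearization, still device colour space
#   standard_linear after colour correction: linear RGB, sRGB primaries

IMG_ENCODINGS <- c("device_gamma", "device_linear", "standard_linear")

#' Construct an image patch
#'
#' @param pixels H x W x 3 numeric array of channel values (nominally in
#'   `[0, 1]`; intermediate stages may exceed the range).
#' @param encoding One of `"device_gamma"`, `"device_linear"`,
#'   `"standard_linear"`.
#' @param pixel_size_um Optional pixel pitch in microns.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, encoding, pixel_size_um = NULL) {
  encoding <- match.arg(encoding, IMG_ENCODINGS)
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop("image must have at least one pixel")
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  structure(list(pixels = pixels, encoding = encoding,
                 pixel_size_um = pixel_size_um),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_patch %d x %d, encoding '%s', range [%.4f, %.4f]\n",
              d[1], d[2], x$encoding, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_patch <- function(x) dim(x$pixels)

# Pixels as an N x 3 matrix (row-major over the image) and back.
.px_mat <- function(img) {
  d <- dim(img$pixels)
  matrix(img$pixels, d[1] * d[2], 3)
}
.px_unmat <- function(m, like) {
  array(m, dim = dim(like$pixels))
}

#' Read an image patch from PNG or TIFF
#'
#' 8- or 16-bit integer codes are mapped to `[0, 1]` by the readers.
#' Grayscale files are expanded to three identical channels; any alpha
#' channel is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param encoding Encoding tag to attach (default `"device_gamma"`, the
#'   state of raw scanner exports).
#' @return An `image_patch`.
#' @export
read_image_patch <- function(path, encoding = "device_gamma") {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  image_patch(px, encoding)
}

#' Write an image patch to PNG or TIFF
#'
#' Values are clipped to `[0, 1]` at this export boundary only; in-memory
#' processing never clips.
#'
#' @param img An `image_patch`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth, 8 or 16.
#' @return The path, invisibly.
#' @export
write_image_patch <- function(img, path, bits = 16) {
  px <- pmin(pmax(img$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = bits),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Normalize an image by the incident light
#'
#' Elementwise (Hadamard) division of every pixel by the per-channel
#' incident intensity measured on clear glass, so glass-level pixels map
#' to (1,1,1). The encoding tag is unchanged.
#'
#' @param img An `image_patch`.
#' @param incident Positive 3-vector of per-channel incident intensity.
#' @return An `image_patch`.
#' @export
normalize_by_incident <- function(img, incident) {
  incident <- as.numeric(incident)
  if (length(incident) != 3 || any(!is.finite(incident)) || any(incident <= 0))
    stop("incident light must be a positive 3-vector")
  px <- img$pixels
  for (ch in 1:3) px[, , ch] <- px[, , ch] / incident[ch]
  image_patch(px, img$encoding, img$pixel_size_um)
}

#' Gamma linearization
#'
#' Inverts the display gamma encoding by the per-channel power law
#' `value^gamma`, turning a `device_gamma` image into `device_linear`.
#'
#' @param img An `image_patch` with encoding `"device_gamma"` and
#'   nonnegative pixels.
#' @param gamma A positive scalar or a [gamma_estimate] object.
#' @return An `image_patch` with encoding `"device_linear"`.
#' @export
linearize <- function(img, gamma) {
  if (inherits(gamma, "gamma_estimate")) gamma <- gamma$gamma
  if (img$encoding != "device_gamma")
    stop("encoding error: linearize expects a 'device_gamma' image")
  if (any(img$pixels < 0))
    stop("negative pixel values: clip upstream before linearization")
  image_patch(img$pixels^gamma, "device_linear", img$pixel_size_um)
}

# Floor below which transmittance is clamped before taking logs
# (one 16-bit code value).
OD_EPS <- 1 / 65536

#' Linear RGB image to optical density
#'
#' Beer-Lambert convention: `OD = -log10(value / incident)` per channel,
#' with transmittance floored at 1/65536 so fully dark pixels stay finite.
#'
#' @param img An `image_patch` with encoding `"standard_linear"`.
#' @param incident Positive 3-vector of incident intensity (default white).
#' @return H x W x 3 numeric array of nonnegative optical densities.
#' @export
rgb_to_od <- function(img, incident = c(1, 1, 1)) {
  incident <- as.numeric(incident)
  if (length(incident) != 3 || any(incident <= 0))
    stop("incident light must be a positive 3-vector")
  if (img$encoding != "standard_linear")
    stop("encoding error: optical density requires a 'standard_linear' image")
  od <- img$pixels
  for (ch in 1:3) od[, , ch] <- -log10(pmax(od[, , ch] / incident[ch], OD_EPS))
  pmax(od, 0)
}

#' Optical density to linear RGB image
#'
#' Inverse of [rgb_to_od()]: `value = incident * 10^(-OD)`.
#'
#' @param od H x W x 3 array of optical densities.
#' @param incident Positive 3-vector of incident intensity.
#' @return An `image_patch` with encoding `"standard_linear"`.
#' @export
od_to_rgb <- function(od, incident = c(1, 1, 1)) {
  incident <- as.numeric(incident)
  if (length(incident) != 3 || any(incident <= 0))
    stop("incident light must be a positive 3-vector")
  px <- od
  for (ch in 1:3) px[, , ch] <- incident[ch] * 10^(-od[, , ch])
  image_patch(px, "standard_linear")
}
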