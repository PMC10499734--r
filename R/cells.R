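# Simplified blob/disk cell detector for tissue phantoms. Nuclei are
# found on the unmixed hematoxylin OD image; the membrane is read out on
# the DAB OD image over a thin annulus just outside each nucleus. This
# stands in for full histology segmentation, which is out of scope; a
# tabular per-cell input path (read_cell_table) covers real segmentations.

#' Detect cells and measure membrane DAB intensity
#'
#' Thresholds the hematoxylin channel, labels connected components as
#' nuclei, estimates each nucleus radius from its area, and averages the
#' DAB optical density over an annulus just outside the nucleus boundary
#' (the membrane of the phantom cells).
#'
#' @param img `image_patch`, encoding `"standard_linear"`.
#' @param stains A [stain_model()] used for unmixing.
#' @param incident Incident-light 3-vector.
#' @param hem_threshold Hematoxylin OD threshold for nucleus pixels.
#' @param ring Offsets `(inner, outer]` added to the nucleus radius to
#'   define the membrane annulus, in pixels.
#' @param min_area Minimum nucleus area in pixels.
#' @return Cell table: data frame with columns `cell_id`,
#'   `membrane_dab_od`, `nucleus_detected`, `row`, `col`.
#' @export
detect_cells <- function(img, stains, incident = c(1, 1, 1),
                         hem_threshold = 0.15, ring = c(0.5, 2.5),
                         min_area = 9) {
  od <- rgb_to_od(img, incident)
  ch <- unmix(od, stains)
  lab <- EBImage::bwlabel((ch$hematoxylin > hem_threshold) * 1)
  n <- max(lab)
  H <- nrow(lab); W <- ncol(lab)
  out <- list()
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    r <- sqrt(nrow(idx) / pi)
    r0 <- r + ring[1]; r1 <- r + ring[2]
    rows <- max(1, floor(cr - r1)):min(H, ceiling(cr + r1))
    cols <- max(1, floor(cc - r1)):min(W, ceiling(cc + r1))
    dd <- sqrt(outer((rows - cr)^2, (cols - cc)^2, "+"))
    sel <- dd > r0 & dd <= r1
    if (!any(sel)) next
    out[[length(out) + 1]] <- data.frame(
      membrane_dab_od = mean(ch$dab[rows, cols][sel]),
      nucleus_detected = TRUE, row = cr, col = cc)
  }
  if (!length(out))
    return(data.frame(cell_id = integer(0), membrane_dab_od = numeric(0),
                      nucleus_detected = logical(0), row = numeric(0),
                      col = numeric(0)))
  cells <- do.call(rbind, out)
  cbind(cell_id = seq_len(nrow(cells)), cells)
}
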