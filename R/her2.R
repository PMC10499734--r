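# Automated HER2 assessment: per-cell immunoscore from mean membrane DAB
# optical density, score percentages, H-score, and an ASCO/CAP-style
# status rule reduced to percentage-of-cells criteria. Also the grid
# search deriving reference thresholds from score-known reference cases.

#' Default HER2 status rule table
#'
#' Percentage-of-cells reduction of the ASCO/CAP guideline: status 3+ if
#' more than `pct`% of cells score 3, else 2+ if scores >= 2 exceed
#' `pct`%, else 1+ if scores >= 1 exceed `pct`%, else 0. Comparisons are
#' strict, so exactly 10% does not qualify. The table is configurable
#' because the guideline's membrane-completeness criteria are not
#' computable from mean OD alone.
#'
#' @param pct Percentage threshold applied at each level.
#' @return Data frame with columns `status`, `min_score`, `pct`, ordered
#'   from the strongest status down.
#' @export
default_status_rule <- function(pct = 10) {
  data.frame(status = c("3+", "2+", "1+"), min_score = c(3, 2, 1), pct = pct)
}

#' Classify cells into immunoscores
#'
#' Score 0 if OD < t1, 1 if t1 <= OD < t2, 2 if t2 <= OD < t3, 3 if
#' OD >= t3: half-open intervals, boundary values belong to the higher
#' score.
#'
#' @param cells Data frame with a `membrane_dab_od` column, or a numeric
#'   vector of mean membrane DAB optical densities.
#' @param thresholds A [threshold_set()].
#' @return Integer vector of immunoscores in 0..3.
#' @export
classify_cells <- function(cells, thresholds) {
  od <- if (is.data.frame(cells)) cells$membrane_dab_od else as.numeric(cells)
  if (is.null(od)) stop("cells must provide a membrane_dab_od column")
  if (any(!is.finite(od)) || any(od < 0))
    stop("input error: membrane OD must be finite and nonnegative")
  findInterval(od, as.numeric(thresholds))
}

#' Immunoscore distribution
#'
#' Percentages P0..P3 of cells at each immunoscore.
#'
#' @param immunoscores Integer vector of scores in 0..3.
#' @return An object of class `score_distribution` with fields `P0`,
#'   `P1`, `P2`, `P3` (summing to 100) and `n_cells`.
#' @export
score_distribution <- function(immunoscores) {
  if (length(immunoscores) == 0) stop("no cells: score list is empty")
  if (any(!immunoscores %in% 0:3)) stop("immunoscores must be in 0..3")
  p <- 100 * tabulate(immunoscores + 1L, 4L) / length(immunoscores)
  structure(list(P0 = p[1], P1 = p[2], P2 = p[3], P3 = p[4],
                 n_cells = length(immunoscores)),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("Immunoscore distribution over %d cells: P0 = %.1f%%, P1 = %.1f%%, P2 = %.1f%%, P3 = %.1f%%\n",
              x$n_cells, x$P0, x$P1, x$P2, x$P3))
  invisible(x)
}

#' H-score of an immunoscore distribution
#'
#' `H = sum(Pm * m)` over the immunoscore percentages, ranging from 0
#' (all negative) to 300 (all strongly stained).
#'
#' @param dist A [score_distribution()].
#' @return Scalar in `[0, 300]`.
#' @export
h_score <- function(dist) {
  dist$P1 * 1 + dist$P2 * 2 + dist$P3 * 3
}

# Vectorized rule evaluation on percentage vectors (columns P1..P3).
.status_from_p <- function(P1, P2, P3, rule = default_status_rule()) {
  out <- rep("0", length(P1))
  undecided <- rep(TRUE, length(P1))
  cum <- cbind(P1 + P2 + P3, P2 + P3, P3)  # cells scoring >= 1, 2, 3
  for (r in seq_len(nrow(rule))) {
    hit <- undecided & cum[, rule$min_score[r]] > rule$pct[r]
    out[hit] <- rule$status[r]
    undecided <- undecided & !hit
  }
  out
}

#' HER2 status from an immunoscore distribution
#'
#' Applies the (configurable) percentage rule table; see
#' [default_status_rule()].
#'
#' @param dist A [score_distribution()].
#' @param rule Status rule table.
#' @return One of `"0"`, `"1+"`, `"2+"`, `"3+"`.
#' @export
her2_status <- function(dist, rule = default_status_rule()) {
  .status_from_p(dist$P1, dist$P2, dist$P3, rule)
}

#' Automated HER2 assessment of a cell table
#'
#' Classifies every cell, tabulates the immunoscore distribution and
#' returns the H-score and HER2 status. Cells without a detected nucleus
#' are included.
#'
#' @inheritParams classify_cells
#' @param rule Status rule table (default [default_status_rule()]).
#' @return An object of class `her2_result` with fields `scores`,
#'   `distribution`, `h_score`, `status`, `thresholds`.
#' @export
her2_score <- function(cells, thresholds, rule = default_status_rule()) {
  scores <- classify_cells(cells, thresholds)
  dist <- score_distribution(scores)
  structure(list(scores = scores, distribution = dist,
                 h_score = h_score(dist), status = her2_status(dist, rule),
                 thresholds = thresholds),
            class = "her2_result")
}

#' @export
print.her2_result <- function(x, ...) {
  print(x$distribution)
  cat(sprintf("H-score = %.1f; HER2 status: %s\n", x$h_score, x$status))
  invisible(x)
}

#' Derive reference thresholds from score-known cases
#'
#' Exhaustive search over ordered threshold triples on an OD grid,
#' maximizing the number of reference cases whose automated HER2 status
#' matches the known status. Among equally concordant triples the one
#' whose thresholds keep the largest margin to the nearest observed cell
#' OD is chosen (thresholds that hug a cell's OD do not survive
#' re-measurement jitter); remaining ties go to the smallest t1, then
#' t2, then t3, making the result deterministic.
#'
#' @param reference_cases List of cell tables (or OD vectors), one per
#'   reference case.
#' @param known_status Character vector of known statuses
#'   (`"0"`, `"1+"`, `"2+"`, `"3+"`), one per case; all four statuses
#'   must be represented.
#' @param grid Candidate threshold values in OD units.
#' @param rule Status rule table.
#' @return A [threshold_set()]. If no triple reproduces every known
#'   status, the best triple is returned with a warning.
#' @export
derive_reference_thresholds <- function(reference_cases, known_status,
                                        grid = seq(0.01, 0.60, by = 0.01),
                                        rule = default_status_rule()) {
  if (length(reference_cases) != length(known_status))
    stop("one known status per reference case is required")
  if (!all(c("0", "1+", "2+", "3+") %in% known_status))
    stop("insufficient reference: need at least one case per status 0..3+")
  ods <- lapply(reference_cases, function(cs)
    if (is.data.frame(cs)) cs$membrane_dab_od else as.numeric(cs))
  triples <- utils::combn(length(grid), 3)          # lexicographic order
  matches <- integer(ncol(triples))
  for (ci in seq_along(ods)) {
    od <- ods[[ci]]
    n <- length(od)
    cnt <- vapply(grid, function(g) sum(od < g), numeric(1))
    below1 <- cnt[triples[1, ]]; below2 <- cnt[triples[2, ]]
    below3 <- cnt[triples[3, ]]
    P1 <- 100 * (below2 - below1) / n
    P2 <- 100 * (below3 - below2) / n
    P3 <- 100 * (n - below3) / n
    matches <- matches +
      (.status_from_p(P1, P2, P3, rule) == known_status[ci])
  }
  pooled <- sort(unique(unlist(ods)))
  margin_g <- vapply(grid, function(g) min(abs(g - pooled)), numeric(1))
  margin <- pmin(margin_g[triples[1, ]],
                 pmin(margin_g[triples[2, ]], margin_g[triples[3, ]]))
  top <- matches == max(matches)
  best <- which(top)[which.max(margin[top])]
  if (matches[best] < length(ods))
    warning("no threshold triple reproduces all known scores; ",
            "returning the best triple (", matches[best], "/", length(ods),
            " concordant)")
  threshold_set(grid[triples[1, best]], grid[triples[2, best]],
                grid[triples[3, best]])
}

#' Read a cell table from CSV
#'
#' Expected header: `cell_id`, `membrane_dab_od`, `nucleus_detected`,
#' `row`, `col`.
#'
#' @param path CSV file path.
#' @return Data frame of cell records.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "membrane_dab_od")
  if (!all(need %in% names(df)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a cell table to CSV
#'
#' @param cells Data frame of cell records.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
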