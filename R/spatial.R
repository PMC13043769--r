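#' Filter spots by total transcript count
#'
#' Removes spots with fewer than `min_total` transcripts (boundary
#' inclusive: a spot with exactly `min_total` is retained).
#'
#' @param grid A `spot_grid` (or data.frame with a `total_counts` column).
#' @param min_total Minimum total count, default 100.
#' @return Filtered grid; attribute `n_removed` records the removals.
#' @export
filter_spots <- function(grid, min_total = 100L) {
  if (nrow(grid) == 0L) stop("empty spot grid")
  keep <- grid$total_counts >= min_total
  if (!any(keep)) stop("all spots removed by the count filter")
  out <- grid[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Simplified per-spot module score
#'
#' Library-size-normalises each spot to counts per 10,000, log1p
#' transforms, averages over the gene set, and z-scores across spots. A
#' deliberate simplification of control-bin module scoring: the z-score
#' plays the role of the background subtraction.
#'
#' @param expr Spot x gene count matrix (dense or sparse) with dimnames;
#'   rows are spots.
#' @param gene_set Character vector of gene names; must intersect the
#'   measured genes.
#' @param totals Per-spot library sizes used for normalisation; defaults
#'   to the matrix row sums, but the measured per-spot totals (e.g. the
#'   grid's `total_counts`) can be supplied so the score does not depend
#'   on which genes happen to be included in the matrix.
#' @return Named numeric vector of per-spot scores (mean 0, sd 1 unless
#'   the raw score is constant, in which case all zeros).
#' @export
module_score <- function(expr, gene_set, totals = Matrix::rowSums(expr)) {
  genes <- intersect(gene_set, colnames(expr))
  if (length(genes) == 0L) stop("gene set does not intersect measured genes")
  norm <- log1p(1e4 * as.matrix(expr[, genes, drop = FALSE]) /
                  pmax(totals, 1))
  raw <- rowMeans(norm)
  s <- stats::sd(raw)
  score <- if (is.na(s) || s == 0) rep(0, length(raw)) else
    (raw - mean(raw)) / s
  setNames(score, rownames(expr))
}

#' Spots in the top score quartile
#'
#' Marks spots whose score is at or above the 75th percentile
#' (linear-interpolation percentile, inclusive at the cut) as enriched.
#'
#' @param grid A `spot_grid` after QC.
#' @param score_field Name of the score column, default "tcell_score".
#' @return Logical vector (TRUE = enriched), named by spot id; the cut
#'   value is attached as attribute `cutoff`.
#' @export
enriched_spots <- function(grid, score_field = "tcell_score") {
  if (nrow(grid) < 4L) stop("need at least 4 spots to form quartiles")
  s <- grid[[score_field]]
  cut <- unname(quantile(s, 0.75))
  enr <- s >= cut
  if (all(enr)) warning("constant scores: every spot is 'enriched'")
  out <- setNames(enr, grid$spot_id)
  attr(out, "cutoff") <- cut
  out
}

#' Minimum Euclidean distance from each spot to an enriched spot
#'
#' All-pairs brute force: for every spot, the smallest Euclidean distance
#' to any enriched spot (enriched spots get 0).
#'
#' @param grid A `spot_grid`.
#' @param enriched Logical vector as from [enriched_spots()] (aligned with
#'   the grid rows).
#' @return Numeric vector of distances, named by spot id.
#' @export
min_distance_to_enriched <- function(grid, enriched) {
  if (!any(enriched)) stop("no enriched spots")
  ex <- grid$x[enriched]
  ey <- grid$y[enriched]
  d <- vapply(seq_len(nrow(grid)), function(i) {
    sqrt(min((grid$x[i] - ex)^2 + (grid$y[i] - ey)^2))
  }, numeric(1L))
  d[enriched] <- 0
  setNames(d, grid$spot_id)
}

#' Correlation between signature score and T-cell proximity
#'
#' Spearman correlation between the per-spot signature score and the
#' minimum distance to a T-cell-enriched spot. A signature that is higher
#' near T cells yields a NEGATIVE correlation with distance (distance is
#' the inverse of proximity); the sign convention is recorded in the
#' output.
#'
#' @param grid A QC'd `spot_grid` with a `signature_score` column.
#' @param score_field Score used to define enrichment, default
#'   "tcell_score".
#' @return List: rho, p, n, cutoff, sign_convention.
#' @export
signature_proximity_correlation <- function(grid,
                                            score_field = "tcell_score") {
  if (nrow(grid) < 5L) stop("need at least 5 spots")
  enr <- enriched_spots(grid, score_field)
  d <- min_distance_to_enriched(grid, enr)
  if (stats::sd(grid$signature_score) == 0 || stats::sd(d) == 0) {
    stop("constant signature or distance; correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(grid$signature_score, d, method = "spearman"))
  list(
    rho = unname(ct$estimate), p = ct$p.value, n = nrow(grid),
    cutoff = attr(enr, "cutoff"),
    sign_convention = "negative rho = signature increases with T-cell proximity"
  )
}
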