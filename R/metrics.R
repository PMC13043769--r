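#' Aggregation propensity factor
#'
#' APF = 100 * (MFI_ko - MFI_control) / MFI_ko, a flow-cytometry summary
#' of aggregate staining in a test (knockdown) sample relative to its
#' control; negative when the control exceeds the test. Vectorised.
#'
#' @param mfi_ko Mean fluorescence intensity of the test sample (> 0).
#' @param mfi_control Mean fluorescence intensity of the control (>= 0).
#' @return Numeric APF value(s).
#' @examples
#' apf(200, 100)  # 50
#' @export
apf <- function(mfi_ko, mfi_control) {
  if (any(mfi_ko <= 0)) stop("mfi_ko must be positive")
  if (any(mfi_control < 0)) stop("mfi_control must be non-negative")
  100 * (mfi_ko - mfi_control) / mfi_ko
}

#' Select a gene signature from a differential-expression table
#'
#' Keeps genes with log2 fold change above `lfc_min` and p-value below
#' `p_max`; strict inequalities by default, matching printed "> / <"
#' thresholds. Original row order is preserved.
#'
#' @param table Data.frame with the gene, fold-change and p-value columns.
#' @param lfc_min Fold-change threshold, default 0.5.
#' @param p_max P-value threshold, default 0.05.
#' @param strict If FALSE, use >= / <= at the thresholds.
#' @param gene_col,lfc_col,p_col Column names (defaults "gene", "log2fc",
#'   "p"); point `p_col` at an adjusted-p column to filter on that
#'   instead.
#' @return Character vector of selected genes (possibly empty).
#' @export
signature_select <- function(table, lfc_min = 0.5, p_max = 0.05,
                             strict = TRUE, gene_col = "gene",
                             lfc_col = "log2fc", p_col = "p") {
  stopifnot(all(c(gene_col, lfc_col, p_col) %in% names(table)))
  lfc <- table[[lfc_col]]
  p <- table[[p_col]]
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  keep <- if (strict) lfc > lfc_min & p < p_max else lfc >= lfc_min & p <= p_max
  keep[is.na(keep)] <- FALSE
  table[[gene_col]][keep]
}
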