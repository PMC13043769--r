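#' Subsample reads to a fixed depth
#'
#' Uniform sampling without replacement of exactly `min(depth, n)` reads;
#' deterministic given the seed. Mirrors the depth normalisation applied
#' to RIP-seq libraries before isodecoder counting.
#'
#' @param reads A data.frame of reads (any columns) or a vector.
#' @param depth Target depth, default 1,000,000.
#' @param seed Integer seed.
#' @return The subsampled reads, original order preserved.
#' @export
subsample_reads <- function(reads, depth = 1000000L, seed = 1L) {
  stopifnot(depth > 0)
  n <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  if (n <= depth) return(reads)
  keep <- sort(withr::with_seed(seed, sample.int(n, depth)))
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Isodecoder percentages per sample
#'
#' Converts isodecoder counts to percentages of the sample total.
#'
#' @param counts Data.frame with columns `isodecoder_id`, `anticodon`,
#'   `count`, and optionally `sample` (percentages are computed within
#'   sample).
#' @return The input with a `pct` column added; percentages sum to 100
#'   within each sample.
#' @export
isodecoder_percentages <- function(counts) {
  stopifnot(all(c("isodecoder_id", "anticodon", "count") %in% names(counts)),
            all(counts$count >= 0))
  sample_id <- if ("sample" %in% names(counts)) counts$sample else
    rep("sample1", nrow(counts))
  totals <- tapply(counts$count, sample_id, sum)
  if (any(totals == 0)) stop("zero total count in sample(s): ",
                             paste(names(totals)[totals == 0], collapse = ", "))
  counts$pct <- 100 * counts$count / as.numeric(totals[as.character(sample_id)])
  counts
}

#' Differential binding of anticodon groups between conditions
#'
#' Sums isodecoder percentages into the four anticodon groups (by 3'
#' base) per condition and reports, per group, the log2 ratio
#' `log2((P_kd + alpha_pct) / (P_ctr + alpha_pct))` together with the raw
#' percentage-point difference. Per-isodecoder percentages are retained
#' for dispersion display.
#'
#' @param pct_ctr,pct_kd Percentage tables from
#'   [isodecoder_percentages()] over a shared isodecoder universe.
#' @param alpha_pct Pseudocount in percentage points (default 0.01).
#' @return List: `groups` (group, pct_ctr, pct_kd, diff_pp, log2_ratio)
#'   and `isodecoders` (per-isodecoder merged percentages with group).
#' @export
group_differential_binding <- function(pct_ctr, pct_kd, alpha_pct = 0.01) {
  if (!setequal(pct_ctr$isodecoder_id, pct_kd$isodecoder_id)) {
    stop("conditions must share the isodecoder universe")
  }
  m <- merge(pct_ctr[, c("isodecoder_id", "anticodon", "pct")],
             pct_kd[, c("isodecoder_id", "pct")],
             by = "isodecoder_id", suffixes = c("_ctr", "_kd"))
  m$group <- unname(anticodon_group(m$anticodon))
  agg <- function(col) tapply(m[[col]], m$group, sum)
  groups <- sort(unique(m$group))
  p_ctr <- as.numeric(agg("pct_ctr")[groups])
  p_kd <- as.numeric(agg("pct_kd")[groups])
  out <- data.frame(
    group = groups,
    pct_ctr = p_ctr, pct_kd = p_kd,
    diff_pp = p_kd - p_ctr,
    log2_ratio = log2((p_kd + alpha_pct) / (p_ctr + alpha_pct)),
    stringsAsFactors = FALSE
  )
  list(groups = out, isodecoders = m)
}

#' Percent of bound reads per RNA species
#'
#' Per-sample percentages of reads per RNA biotype, with condition means
#' and standard deviations across replicates when a `condition` column is
#' present.
#'
#' @param counts Data.frame with columns `sample`, `biotype`, `count`,
#'   and optionally `condition`.
#' @return List: `per_sample` (sample, biotype, pct) and `by_condition`
#'   (condition, biotype, mean_pct, sd_pct; NULL without conditions).
#' @export
species_percent_bound <- function(counts) {
  stopifnot(all(c("sample", "biotype", "count") %in% names(counts)))
  totals <- tapply(counts$count, counts$sample, sum)
  if (any(totals == 0)) stop("zero total count in sample(s)")
  per_sample <- counts
  per_sample$pct <- 100 * counts$count /
    as.numeric(totals[as.character(counts$sample)])
  by_condition <- NULL
  if ("condition" %in% names(counts)) {
    by_condition <- do.call(rbind, lapply(
      split(per_sample, list(per_sample$condition, per_sample$biotype),
            drop = TRUE),
      function(d) data.frame(
        condition = d$condition[1L], biotype = d$biotype[1L],
        mean_pct = mean(d$pct), sd_pct = stats::sd(d$pct),
        stringsAsFactors = FALSE
      )))
    rownames(by_condition) <- NULL
  }
  list(per_sample = per_sample, by_condition = by_condition)
}
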