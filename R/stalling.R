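#' Per-gene ribosome stalling
#'
#' A gene's stalling value is its mean mapped-read count per location,
#' where a location is an A-site codon position within the CDS (all CDS
#' codon positions are considered, covered or not). Reads are
#' length-filtered to the RPF range and the P-site offset applied; reads
#' whose A-site codon falls outside the CDS are ignored.
#'
#' @param reads Footprint table (e.g. from [read_footprints()] or the
#'   simulator).
#' @param transcripts A `transcript_set`.
#' @param offset P-site offset in nt (default 15).
#' @param min_len,max_len Read-length bounds (default 27-33 nt).
#' @return A data.frame of class `gene_stalling`: gene_id, n_reads,
#'   n_locations, m (= n_reads / n_locations).
#' @export
gene_stalling <- function(reads, transcripts, offset = 15L,
                          min_len = 27L, max_len = 33L) {
  reads <- filter_by_length(reads, min_len, max_len)
  idx <- match(reads$transcript_id, transcripts$id)
  if (anyNA(idx)) stop("reads reference transcripts absent from the annotation")
  nc_tx <- n_codons(transcripts)
  a <- (reads$five_prime + as.integer(offset) -
          transcripts$cds_start[idx]) %/% 3L + 1L
  in_cds <- a >= 0L & a < nc_tx[idx]
  gene_of_read <- transcripts$gene_id[idx][in_cds]
  # locations per gene: total CDS codon count over its isoforms
  loc <- tapply(nc_tx, transcripts$gene_id, sum)
  genes <- sort(unique(transcripts$gene_id))
  r <- table(factor(gene_of_read, levels = genes))
  out <- data.frame(
    gene_id = genes,
    n_reads = as.integer(r),
    n_locations = as.integer(loc[genes]),
    stringsAsFactors = FALSE
  )
  out$m <- out$n_reads / out$n_locations
  class(out) <- c("gene_stalling", "data.frame")
  out
}

# average replicate gene_stalling tables at the m level (equal weights)
.average_stalling <- function(x) {
  if (inherits(x, "gene_stalling")) return(x)
  stopifnot(is.list(x), length(x) >= 1L)
  base <- x[[1L]]
  ms <- sapply(x, function(tb) tb$m[match(base$gene_id, tb$gene_id)])
  base$m <- rowMeans(as.matrix(ms))
  base
}

#' Between-condition stalling fold change
#'
#' Per-gene log2((m_kd + alpha) / (m_ctr + alpha)) with the control
#' condition as reference. Replicate tables (passed as a list) are
#' averaged at the m level before the ratio.
#'
#' @param kd,ctr `gene_stalling` tables, or lists of replicate tables.
#' @param alpha Pseudocount added to each m (default 1 read-equivalent);
#'   must be > 0 if any gene has m = 0.
#' @return Data.frame: gene_id, m_ctr, m_kd, log2fc.
#' @export
stalling_log2fc <- function(kd, ctr, alpha = 1) {
  kd <- .average_stalling(kd)
  ctr <- .average_stalling(ctr)
  m <- merge(ctr[, c("gene_id", "m")], kd[, c("gene_id", "m")],
             by = "gene_id", suffixes = c("_ctr", "_kd"))
  if (alpha <= 0 && any(m$m_ctr == 0 | m$m_kd == 0)) {
    stop("alpha must be positive when any gene has zero stalling")
  }
  m$log2fc <- log2((m$m_kd + alpha) / (m$m_ctr + alpha))
  m
}

#' Rank-test two gene sets' stalling fold changes
#'
#' Two-sided Mann-Whitney U test between the log2 fold changes of two
#' disjoint gene sets. The p-value is exact when the smaller set has at
#' most 8 members and there are no ties, otherwise a tie-corrected normal
#' approximation; the method used is recorded.
#'
#' @param comparison Output of [stalling_log2fc()], or a named numeric
#'   vector of per-gene log2 fold changes.
#' @param set_a,set_b Disjoint character vectors of gene ids.
#' @return List: U (of set_a), p, method, n_a, n_b.
#' @export
compare_gene_sets <- function(comparison, set_a, set_b) {
  fc <- if (is.data.frame(comparison)) {
    setNames(comparison$log2fc, comparison$gene_id)
  } else comparison
  if (length(intersect(set_a, set_b)) > 0L) stop("gene sets must be disjoint")
  xa <- fc[intersect(set_a, names(fc))]
  xb <- fc[intersect(set_b, names(fc))]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) == 0L || length(xb) == 0L) {
    stop("a gene set is empty after the missing-filter")
  }
  ties <- anyDuplicated(c(xa, xb)) > 0L
  exact <- min(length(xa), length(xb)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(
    U = unname(wt$statistic),
    p = wt$p.value,
    method = if (exact) "exact" else "normal approximation, tie-corrected",
    n_a = length(xa), n_b = length(xb)
  )
}
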