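SITES <- c("E", "P", "A", "F1", "F2", "F3")
RIBO_SITES <- c("E", "P", "A")

# codon identity at each of the six resolved positions, one row per read
.assignment_codons <- function(assignments, transcripts) {
  idx <- match(assignments$transcript_id, transcripts$id)
  seqs <- transcripts$sequence[idx]
  cds0 <- transcripts$cds_start[idx]
  cols <- c(E = "e", P = "p", A = "a", F1 = "f1", F2 = "f2", F3 = "f3")
  out <- lapply(cols, function(cl) {
    start <- cds0 + 3L * assignments[[cl]]
    substring(seqs, start + 1L, start + 3L)
  })
  names(out) <- names(cols)
  out
}

.count_matrix <- function(codon_lists) {
  sapply(codon_lists, function(cod) {
    as.integer(table(factor(cod, levels = sense_codons())))
  })
}

#' Per-site codon frequencies
#'
#' Counts the codon identity at each of the six resolved positions (E, P,
#' A and the three flanking codons) over all accepted footprints and
#' normalises each site to frequencies over the 61 sense codons.
#'
#' @param assignments Output of [assign_sites()].
#' @param transcripts The matching `transcript_set`.
#' @return A data.frame of class `site_freq`: site, codon, count, freq
#'   (6 x 61 rows); `n_reads` attribute records the accepted read count.
#' @export
site_frequencies <- function(assignments, transcripts) {
  if (nrow(assignments) == 0L) stop("no site assignments to count")
  counts <- .count_matrix(.assignment_codons(assignments, transcripts))
  freq <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  out <- data.frame(
    site = factor(rep(SITES, each = 61L), levels = SITES),
    codon = rep(sense_codons(), times = 6L),
    count = as.vector(counts),
    freq = as.vector(freq),
    stringsAsFactors = FALSE
  )
  attr(out, "n_reads") <- nrow(assignments)
  class(out) <- c("site_freq", "data.frame")
  out
}

# core of the occupancy ratio on a 61 x 6 count matrix
.occupancy_from_counts <- function(counts, pseudocount = 0) {
  counts <- counts + pseudocount
  freq <- sweep(counts, 2L, pmax(colSums(counts), 1e-300), "/")
  flank_mean <- rowMeans(freq[, c("F1", "F2", "F3"), drop = FALSE])
  occ <- freq[, RIBO_SITES, drop = FALSE] / flank_mean
  occ[flank_mean == 0, ] <- NA_real_
  list(freq = freq, flank_mean = flank_mean, occupancy = occ)
}

#' Codon occupancy ratio
#'
#' The occupancy of codon c at site s (E, P or A) is its frequency at s
#' divided by its mean frequency over the three flanking codons
#' downstream of the A site. Codons with a zero flank mean are reported
#' missing (NA) rather than infinite.
#'
#' @param freqs A `site_freq` table from [site_frequencies()].
#' @param pseudocount Count added to every cell before normalisation
#'   (default 0, i.e. no smoothing).
#' @return A data.frame of class `occupancy_table`: codon, class, site,
#'   count, freq, flank_mean, occupancy (61 x 3 rows).
#' @export
occupancy <- function(freqs, pseudocount = 0) {
  stopifnot(inherits(freqs, "site_freq"))
  counts <- matrix(freqs$count, nrow = 61L,
                   dimnames = list(sense_codons(), SITES))
  if (all(counts[, c("F1", "F2", "F3")] == 0) && pseudocount == 0) {
    stop("all flanking counts are zero; occupancy undefined")
  }
  res <- .occupancy_from_counts(counts, pseudocount)
  out <- data.frame(
    codon = rep(sense_codons(), times = 3L),
    class = rep(unname(classify_codon(sense_codons())), times = 3L),
    site = factor(rep(RIBO_SITES, each = 61L), levels = RIBO_SITES),
    count = as.vector(counts[, RIBO_SITES]),
    freq = as.vector(res$freq[, RIBO_SITES]),
    flank_mean = rep(res$flank_mean, times = 3L),
    occupancy = as.vector(res$occupancy),
    stringsAsFactors = FALSE
  )
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Per-gene codon occupancy
#'
#' Computes the occupancy ratio separately for every gene from that
#' gene's accepted reads (isoforms summed). Genes with fewer than
#' `min_reads` accepted reads are reported missing.
#'
#' @param assignments Output of [assign_sites()] (carries gene ids).
#' @param transcripts The matching `transcript_set`.
#' @param min_reads Minimum accepted reads per gene (default 32).
#' @param pseudocount Per-cell pseudocount for the sparse per-gene tables
#'   (default 0).
#' @return Long data.frame: gene_id, codon, class, site, occupancy,
#'   n_reads; attribute `missing_genes` lists genes below threshold.
#' @export
per_gene_occupancy <- function(assignments, transcripts, min_reads = 32L,
                               pseudocount = 0) {
  codons <- .assignment_codons(assignments, transcripts)
  gene <- assignments$gene_id
  n_per_gene <- table(gene)
  keep_genes <- names(n_per_gene)[n_per_gene >= min_reads]
  missing <- union(names(n_per_gene)[n_per_gene < min_reads],
                   setdiff(unique(transcripts$gene_id), names(n_per_gene)))
  rows <- split(seq_along(gene), gene)[keep_genes]
  per_gene <- lapply(keep_genes, function(g) {
    sel <- rows[[g]]
    counts <- .count_matrix(lapply(codons, `[`, sel))
    dimnames(counts) <- list(sense_codons(), SITES)
    occ <- .occupancy_from_counts(counts, pseudocount)$occupancy
    data.frame(
      gene_id = g,
      codon = rep(sense_codons(), times = 3L),
      class = rep(unname(classify_codon(sense_codons())), times = 3L),
      site = factor(rep(RIBO_SITES, each = 61L), levels = RIBO_SITES),
      occupancy = as.vector(occ),
      n_reads = length(sel),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_gene)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), codon = character(),
                      class = character(),
                      site = factor(character(), levels = RIBO_SITES),
                      occupancy = numeric(), n_reads = integer(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "missing_genes") <- missing
  class(out) <- c("gene_occupancy", "data.frame")
  out
}

#' Summarise occupancy by codon class
#'
#' In `"gene"` mode the unit of observation is a gene: for each gene,
#' class and site, the mean occupancy over that class's codons (NA
#' entries dropped). In `"codon"` mode the unit is a codon of a global
#' [occupancy()] table.
#'
#' @param occ A `gene_occupancy` table (`mode = "gene"`) or an
#'   `occupancy_table` (`mode = "codon"`).
#' @param mode Aggregation unit.
#' @return List with `values` (long data.frame: class, site, unit id,
#'   value) and `summary` (class, site, n, q1, median, q3).
#' @export
class_summary <- function(occ, mode = c("gene", "codon")) {
  mode <- match.arg(mode)
  if (mode == "gene") {
    stopifnot(inherits(occ, "gene_occupancy"))
    d <- occ[!is.na(occ$occupancy), , drop = FALSE]
    key <- paste(d$gene_id, d$class, d$site, sep = "\t")
    m <- tapply(d$occupancy, key, mean)
    first <- !duplicated(key)
    values <- data.frame(class = d$class[first], site = d$site[first],
                         unit = d$gene_id[first],
                         value = as.numeric(m[key[first]]),
                         stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(occ, "occupancy_table"))
    keep <- !is.na(occ$occupancy)
    values <- data.frame(class = occ$class[keep], site = occ$site[keep],
                         unit = occ$codon[keep], value = occ$occupancy[keep],
                         stringsAsFactors = FALSE)
  }
  if (nrow(values) == 0L) stop("no defined occupancy values to summarise")
  summ <- do.call(rbind, lapply(
    split(values, list(values$class, values$site), drop = TRUE),
    function(d) data.frame(
      class = d$class[1L], site = d$site[1L], n = nrow(d),
      q1 = unname(quantile(d$value, 0.25)),
      median = median(d$value),
      q3 = unname(quantile(d$value, 0.75)),
      stringsAsFactors = FALSE
    )))
  rownames(summ) <- NULL
  list(values = values, summary = summ)
}

#' Between-condition occupancy fold change
#'
#' Per gene, class and site: log2 of the ratio of per-gene class-mean
#' occupancies, knockdown over control. Missing on either side propagates
#' to NA.
#'
#' @param og_kd,og_ctr `gene_occupancy` tables for the two conditions.
#' @param log2 If FALSE, return the linear ratio instead.
#' @return Data.frame: gene_id, class, site, value.
#' @export
occupancy_log2fc <- function(og_kd, og_ctr, log2 = TRUE) {
  mk <- class_summary(og_kd, "gene")$values
  mc <- class_summary(og_ctr, "gene")$values
  m <- merge(mk, mc, by = c("unit", "class", "site"),
             suffixes = c("_kd", "_ctr"))
  ratio <- m$value_kd / m$value_ctr
  data.frame(
    gene_id = m$unit, class = m$class, site = m$site,
    value = if (log2) base::log2(ratio) else ratio,
    stringsAsFactors = FALSE
  )
}

#' Compare a gene subpool against a seeded random control
#'
#' Takes the per-gene class-mean occupancies of `gene_set` and of a
#' size-matched random control drawn without replacement from the
#' remaining genes, then rank-tests (Kruskal-Wallis) the two pools per
#' class and site, and the four classes against each other within each
#' pool and site.
#'
#' @param og A `gene_occupancy` table.
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param n_random Control size, default `length(gene_set)`.
#' @param seed Seed for the control draw.
#' @return List: `values` (class, site, unit, value, pool), `pool_tests`
#'   (class, site, statistic, p = gene set vs control), `class_tests`
#'   (pool, site, statistic, p = across classes), `control_genes`.
#' @export
subpool_compare <- function(og, gene_set, n_random = length(gene_set),
                            seed = 1L) {
  vals <- class_summary(og, "gene")$values
  universe <- unique(vals$unit)
  gene_set <- intersect(gene_set, universe)
  if (length(gene_set) == 0L) stop("gene set empty after missing-filter")
  rest <- setdiff(universe, gene_set)
  if (n_random > length(rest)) stop("n_random exceeds available control genes")
  control <- withr::with_seed(seed, sample(rest, n_random))
  vals <- vals[vals$unit %in% c(gene_set, control), , drop = FALSE]
  vals$pool <- ifelse(vals$unit %in% gene_set, "gene_set", "control")
  pool_tests <- do.call(rbind, lapply(
    split(vals, list(vals$class, vals$site), drop = TRUE),
    function(d) {
      kt <- stats::kruskal.test(d$value, factor(d$pool))
      data.frame(class = d$class[1L], site = d$site[1L],
                 statistic = unname(kt$statistic), p = kt$p.value,
                 stringsAsFactors = FALSE)
    }))
  class_tests <- do.call(rbind, lapply(
    split(vals, list(vals$pool, vals$site), drop = TRUE),
    function(d) {
      kt <- stats::kruskal.test(d$value, factor(d$class))
      data.frame(pool = d$pool[1L], site = d$site[1L],
                 statistic = unname(kt$statistic), p = kt$p.value,
                 stringsAsFactors = FALSE)
    }))
  rownames(pool_tests) <- rownames(class_tests) <- NULL
  list(values = vals, pool_tests = pool_tests, class_tests = class_tests,
       control_genes = control)
}
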