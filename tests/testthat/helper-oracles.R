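# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Exact two-sided Mann-Whitney p by enumerating all C(n_a+n_b, n_a)
# labelings of the pooled sample.
mw_enumerate <- function(xa, xb) {
  pooled <- c(xa, xb)
  na <- length(xa)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mu <- na * length(xb) / 2
  us <- apply(utils::combn(length(pooled), na), 2L, u_of)
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Kruskal-Wallis H from the textbook rank formula with tie correction.
kw_h_oracle <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  tt <- table(values)
  corr <- 1 - sum(tt^3 - tt) / (n^3 - n)
  h / corr
}

# All-pairs minimum distance via a full distance matrix.
min_dist_oracle <- function(x, y, enriched) {
  dm <- as.matrix(stats::dist(cbind(x, y)))
  d <- unname(apply(dm[, enriched, drop = FALSE], 1L, min))
  d[enriched] <- 0
  d
}

# One-call toy pipeline: simulate, assign, return pieces.
sim_pipeline <- function(cfg, dwell = dwell_model(), gene_dwell = NULL,
                         offset = NULL, transcripts = NULL) {
  tx <- if (is.null(transcripts)) generate_transcriptome(cfg) else transcripts
  sim <- simulate_footprints(tx, dwell, cfg, gene_dwell = gene_dwell)
  reads <- filter_by_length(sim$reads)
  if (is.null(offset)) {
    offset <- infer_psite_offset(build_start_metaprofile(reads, tx))
  }
  asn <- assign_sites(reads, tx, offset)
  list(tx = tx, sim = sim, reads = reads, offset = offset, assignments = asn)
}

# A tiny hand-built transcript: 30 nt 5'UTR, CDS of 12 codons
# (ATG + 10 internal + TAA), 20 nt 3'UTR.
toy_transcript <- function() {
  internal <- c("AAA", "TGG", "GCT", "CCC", "GAA", "TTT",
                "ATC", "CGA", "GGG", "ACT")
  seqs <- paste0(strrep("C", 30), "ATG", paste(internal, collapse = ""),
                 "TAA", strrep("G", 20))
  transcript_set("toy1", "gene1", seqs, 30L, 30L + 36L)
}
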