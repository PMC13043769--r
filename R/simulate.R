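#' Simulation configuration
#'
#' Bundles every knob of the footprint simulator. Defaults describe the
#' study conditions emulated throughout the test suite: a 200-gene toy
#' transcriptome with uniform sense-codon usage, ribosome-protected
#' fragments of 27-33 nt with a 15 nt 5'-end-to-P-site displacement, and a
#' small initiation-peak component from which the P-site offset is
#' calibrated.
#'
#' @param n_transcripts Number of transcripts (one gene per transcript by
#'   default).
#' @param cds_length_range Range (codons) of the start+internal codon count;
#'   a stop codon is appended on top, so `c(100, 100)` gives a 303 nt CDS.
#' @param codon_usage Named probability vector over the 61 sense codons
#'   (default uniform). Must sum to 1.
#' @param utr5_len,utr3_len UTR lengths in nt. `utr5_len` must be at least
#'   `psite_offset_true + 3` so 5' ends of initiation footprints fit.
#' @param n_reads Number of footprints to emit.
#' @param read_length_distribution Named probability vector over lengths
#'   27..33 nt.
#' @param psite_offset_true Displacement (nt) from a footprint 5' end to the
#'   first nucleotide of its P-site codon. Default 15.
#' @param frame_noise_rate Probability that a 5' end is shifted by +-1 nt
#'   (half each way), breaking the reading frame.
#' @param init_fraction Fraction of footprints drawn from initiation-stage
#'   ribosomes (start codon in the P-site); these create the start-codon
#'   meta-profile peak used for offset calibration and are rejected by
#'   downstream site assignment because their E-site lies outside the CDS.
#' @param per_gene_coverage Positive coverage multiplier, recycled over
#'   genes; transcript pick probability is coverage x codon length.
#' @param seed Integer seed; every generator is deterministic given the
#'   full config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200L,
                       cds_length_range = c(100L, 200L),
                       codon_usage = NULL,
                       utr5_len = 30L, utr3_len = 30L,
                       n_reads = 100000L,
                       read_length_distribution = NULL,
                       psite_offset_true = 15L,
                       frame_noise_rate = 0,
                       init_fraction = 0.10,
                       per_gene_coverage = 1,
                       seed = 1L) {
  if (is.null(codon_usage)) {
    codon_usage <- setNames(rep(1 / 61, 61L), sense_codons())
  }
  if (is.null(read_length_distribution)) {
    read_length_distribution <- setNames(
      c(0.05, 0.15, 0.25, 0.25, 0.15, 0.10, 0.05), as.character(27:33))
  }
  stopifnot(
    abs(sum(codon_usage) - 1) < 1e-9,
    all(names(codon_usage) %in% sense_codons()),
    abs(sum(read_length_distribution) - 1) < 1e-9,
    psite_offset_true >= 0,
    frame_noise_rate >= 0, frame_noise_rate <= 1,
    init_fraction >= 0, init_fraction < 1,
    utr5_len >= psite_offset_true + 3L,
    n_reads >= 0, all(per_gene_coverage > 0)
  )
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    cds_length_range = as.integer(cds_length_range),
    codon_usage = codon_usage,
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    n_reads = as.integer(n_reads),
    read_length_distribution = read_length_distribution,
    psite_offset_true = as.integer(psite_offset_true),
    frame_noise_rate = frame_noise_rate,
    init_fraction = init_fraction,
    per_gene_coverage = per_gene_coverage,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Codon dwell-time model
#'
#' Per-codon A-site sampling weights; a weight of 2 on a codon makes the
#' simulator place twice as many ribosomes (relative to baseline) with
#' that codon in the A-site. Stop codons carry no weight.
#'
#' @param weights Named positive numeric vector over sense codons; codons
#'   not named keep weight 1.
#' @return Named numeric vector over the 61 sense codons, class `dwell_model`.
#' @examples
#' ann <- grep("^A", sense_codons(), value = TRUE)
#' dwell_model(setNames(rep(2, length(ann)), ann))
#' @export
dwell_model <- function(weights = NULL) {
  w <- setNames(rep(1, 61L), sense_codons())
  if (!is.null(weights)) {
    stopifnot(all(names(weights) %in% sense_codons()), all(weights > 0))
    w[names(weights)] <- weights
  }
  structure(w, class = c("dwell_model", "numeric"))
}

#' A dwell model with a uniform multiplier on one codon class
#'
#' @param class One of "ANN", "CNN", "GNN", "UNN".
#' @param multiplier Positive weight applied to every sense codon of the
#'   class.
#' @return A `dwell_model`.
#' @export
class_dwell_model <- function(class = "ANN", multiplier = 2) {
  first <- c(ANN = "A", CNN = "C", GNN = "G", UNN = "T")[[class]]
  cs <- grep(paste0("^", first), sense_codons(), value = TRUE)
  dwell_model(setNames(rep(multiplier, length(cs)), cs))
}

#' Generate a synthetic transcriptome
#'
#' Each CDS starts with ATG, continues with codons drawn i.i.d. from
#' `codon_usage`, and ends with a stop codon drawn uniformly from the
#' three stops; UTRs are random nucleotides. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return A `transcript_set` with ids `tx0001`... and gene ids `g0001`...
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  nt <- cfg$n_transcripts
  rng <- seq(cfg$cds_length_range[1L], cfg$cds_length_range[2L])
  lens <- if (length(rng) == 1L) rep(rng, nt) else sample(rng, nt, replace = TRUE)
  codons <- names(cfg$codon_usage)
  seqs <- vapply(lens, function(L) {
    internal <- sample(codons, L - 1L, replace = TRUE, prob = cfg$codon_usage)
    paste0(
      paste(sample(NT, cfg$utr5_len, replace = TRUE), collapse = ""),
      "ATG", paste(internal, collapse = ""),
      sample(stop_codons(), 1L),
      paste(sample(NT, cfg$utr3_len, replace = TRUE), collapse = "")
    )
  }, character(1L))
  transcript_set(
    id = sprintf("tx%04d", seq_len(nt)),
    gene_id = sprintf("g%04d", seq_len(nt)),
    sequence = seqs,
    cds_start = cfg$utr5_len,
    cds_end = cfg$utr5_len + 3L * (lens + 1L)
  )
}

# Eligible A-site codon indices for a CDS of n codons (stop included):
# skip the first 2 and last 5 codons, and require E-site plus the three
# flanking codons inside the CDS with no stop touched.
.eligible_a <- function(nc) {
  if (nc < 9L) return(integer(0))
  seq.int(2L, nc - 6L)
}

#' Simulate ribosome-protected fragments
#'
#' Places `cfg$n_reads` footprints on the transcript set. Elongation
#' footprints pick a transcript proportional to coverage x codon length,
#' then an A-site codon uniformly over eligible positions re-weighted by
#' the dwell weight of the codon found there; the 5' end sits
#' `psite_offset_true` nt upstream of the P-site codon start, optionally
#' jittered by +-1 nt frame noise. A `cfg$init_fraction` share of
#' footprints instead come from initiation-stage ribosomes with the start
#' codon in the P-site. Lengths are drawn from the 27-33 nt distribution.
#'
#' @param transcripts A `transcript_set`.
#' @param dwell A [dwell_model()] (default uniform).
#' @param cfg A [sim_config()].
#' @param gene_dwell Optional named list (gene_id -> `dwell_model`)
#'   overriding `dwell` for specific genes, so a gene subpool can carry a
#'   codon-class effect within one dataset.
#' @return A list with `reads` (data.frame: read_id, transcript_id,
#'   five_prime 0-based, length) and `truth` (dwell weights, true offset,
#'   expected per-gene read counts, seed).
#' @export
simulate_footprints <- function(transcripts, dwell = dwell_model(), cfg,
                                gene_dwell = NULL) {
  stopifnot(inherits(cfg, "sim_config"), nrow(transcripts) > 0L)
  if (cfg$n_reads <= 0L) stop("n_reads must be positive")
  withr::local_seed(cfg$seed)
  nc <- n_codons(transcripts)
  if (all(lengths(lapply(nc, .eligible_a)) == 0L)) {
    stop("no eligible A-site positions on any transcript")
  }
  cov <- rep_len(cfg$per_gene_coverage, nrow(transcripts))
  pick <- cov * nc
  pick <- pick / sum(pick)

  n_init <- as.integer(round(cfg$init_fraction * cfg$n_reads))
  n_elong <- cfg$n_reads - n_init

  # elongation reads: transcript, then dwell-weighted A-site position
  tx_idx <- sample.int(nrow(transcripts), n_elong, replace = TRUE, prob = pick)
  a_pos <- integer(n_elong)
  for (i in unique(tx_idx)) {
    sel <- which(tx_idx == i)
    elig <- .eligible_a(nc[i])
    w_model <- dwell
    if (!is.null(gene_dwell)) {
      g <- transcripts$gene_id[i]
      if (!is.null(gene_dwell[[g]])) w_model <- gene_dwell[[g]]
    }
    cods <- codon_at(transcripts[i, , drop = FALSE], elig)
    w <- unclass(w_model)[cods]
    w[is.na(w)] <- 0  # stop codons (should not occur in eligible range)
    a_pos[sel] <- if (length(elig) == 1L) elig else
      sample(elig, length(sel), replace = TRUE, prob = w)
  }
  five_elong <- transcripts$cds_start[tx_idx] + 3L * (a_pos - 1L) -
    cfg$psite_offset_true
  if (cfg$frame_noise_rate > 0) {
    u <- stats::runif(n_elong)
    shift <- ifelse(u < cfg$frame_noise_rate / 2, -1L,
                    ifelse(u < cfg$frame_noise_rate, 1L, 0L))
    five_elong <- five_elong + shift
  }

  # initiation reads: start codon in the P-site
  tx_init <- if (n_init > 0L) {
    sample.int(nrow(transcripts), n_init, replace = TRUE, prob = pick)
  } else integer(0)
  five_init <- transcripts$cds_start[tx_init] - cfg$psite_offset_true

  tx_all <- c(tx_init, tx_idx)
  five <- c(five_init, five_elong)
  lens <- as.integer(sample(
    as.integer(names(cfg$read_length_distribution)),
    cfg$n_reads, replace = TRUE, prob = cfg$read_length_distribution))
  # clamp at transcript bounds (UTRs are sized so this is a no-op in practice)
  tlen <- nchar(transcripts$sequence)[tx_all]
  five <- pmax(0L, pmin(five, tlen - lens))

  reads <- data.frame(
    read_id = sprintf("r%07d", seq_len(cfg$n_reads)),
    transcript_id = transcripts$id[tx_all],
    five_prime = as.integer(five),
    length = lens,
    stringsAsFactors = FALSE
  )
  truth <- list(
    dwell = unclass(dwell),
    gene_dwell = if (is.null(gene_dwell)) NULL else lapply(gene_dwell, unclass),
    psite_offset_true = cfg$psite_offset_true,
    expected_reads = setNames(as.numeric(cfg$n_reads * pick),
                              transcripts$gene_id),
    init_fraction = cfg$init_fraction,
    seed = cfg$seed
  )
  list(reads = reads, truth = truth)
}

#' Simulate a two-condition footprint experiment
#'
#' Runs [simulate_footprints()] once per condition (and replicate) on a
#' shared transcriptome and records the true per-gene density log2 fold
#' change (kd over ctr) implied by the two configurations' coverage
#' vectors and read totals.
#'
#' @param transcripts Shared `transcript_set`.
#' @param cfg_ctr,cfg_kd [sim_config()]s; coverage vectors must have equal
#'   effective length over the gene set.
#' @param dwell_ctr,dwell_kd Dwell models per condition.
#' @param n_replicates Replicates per condition; replicate r uses
#'   `cfg$seed + r - 1`.
#' @return List with `ctr` and `kd` (each a list of [simulate_footprints()]
#'   results, one per replicate) and `truth` containing
#'   `true_log2fc` per gene.
#' @export
simulate_condition_pair <- function(transcripts, cfg_ctr, cfg_kd,
                                    dwell_ctr = dwell_model(),
                                    dwell_kd = dwell_model(),
                                    n_replicates = 1L) {
  nc <- n_codons(transcripts)
  exp_reads <- function(cfg) {
    cov <- rep_len(cfg$per_gene_coverage, nrow(transcripts))
    p <- cov * nc
    setNames(cfg$n_reads * p / sum(p), transcripts$gene_id)
  }
  e_ctr <- exp_reads(cfg_ctr)
  e_kd <- exp_reads(cfg_kd)
  run <- function(cfg, dwell) {
    lapply(seq_len(n_replicates), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r - 1L
      simulate_footprints(transcripts, dwell, cfg_r)
    })
  }
  list(
    ctr = run(cfg_ctr, dwell_ctr),
    kd = run(cfg_kd, dwell_kd),
    truth = list(
      true_log2fc = log2(e_kd / e_ctr),
      expected_reads_ctr = e_ctr,
      expected_reads_kd = e_kd,
      psite_offset_true = cfg_ctr$psite_offset_true
    )
  )
}

#' Write footprints as a SAM file in transcript coordinates
#'
#' Minimal 11-column records: flag 0, MAPQ 255, CIGAR `<L>M`, the actual
#' transcript subsequence as SEQ. Coordinates are converted to SAM's
#' 1-based POS.
#'
#' @param reads Read table from [simulate_footprints()].
#' @param transcripts The `transcript_set` the reads were placed on.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, transcripts, path) {
  idx <- match(reads$transcript_id, transcripts$id)
  if (anyNA(idx)) stop("reads reference transcripts absent from the set")
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", transcripts$id, nchar(transcripts$sequence))
  )
  seqs <- substring(transcripts$sequence[idx],
                    reads$five_prime + 1L,
                    reads$five_prime + reads$length)
  body <- paste(reads$read_id, 0L, reads$transcript_id, reads$five_prime + 1L,
                255L, paste0(reads$length, "M"), "*", 0L, 0L, seqs, "*",
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
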