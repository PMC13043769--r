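test_that("generated transcriptomes are deterministic, ATG...stop structured", {
  cfg <- sim_config(n_transcripts = 5L, seed = 1L)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx1, tx2)
  for (i in seq_len(nrow(tx1))) {
    t <- tx1[i, , drop = FALSE]
    class(t) <- class(tx1)
    nc <- n_codons(t)
    expect_equal(codon_at(t, 0L), "ATG")
    expect_true(codon_at(t, nc - 1L) %in% stop_codons())
    expect_false(any(codon_at(t, seq(1L, nc - 2L)) %in% stop_codons()))
  }
  # fixed length range: 100 drawn codons + appended stop = 303 nt CDS
  cfg100 <- sim_config(n_transcripts = 3L, cds_length_range = c(100L, 100L),
                       seed = 2L)
  tx100 <- generate_transcriptome(cfg100)
  expect_true(all(tx100$cds_end - tx100$cds_start == 303L))
})

test_that("internal codons follow the configured usage (binomial bounds)", {
  cfg <- sim_config(n_transcripts = 350L, cds_length_range = c(280L, 320L),
                    seed = 1L)
  tx <- generate_transcriptome(cfg)
  nc <- n_codons(tx)
  internal <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    t <- tx[i, , drop = FALSE]; class(t) <- class(tx)
    codon_at(t, seq(1L, nc[i] - 2L))
  }))
  expect_gt(length(internal), 1e5)
  f <- table(factor(internal, levels = sense_codons())) / length(internal)
  u <- 1 / 61
  se <- sqrt(u * (1 - u) / length(internal))
  # Sidak-style bound for 61 simultaneous binomial checks
  expect_true(all(abs(f - u) < 3.6 * se))
})

test_that("footprint simulation conserves read counts and is seed-determined", {
  cfg <- sim_config(n_transcripts = 10L, n_reads = 10000L, seed = 7L)
  tx <- generate_transcriptome(cfg)
  s1 <- simulate_footprints(tx, dwell_model(), cfg)
  s2 <- simulate_footprints(tx, dwell_model(), cfg)
  expect_identical(s1$reads, s2$reads)
  expect_equal(nrow(s1$reads), 10000L)
  expect_true(all(s1$reads$length %in% 27:33))
  expect_true(all(s1$reads$five_prime >= 0))
  tlen <- nchar(tx$sequence)[match(s1$reads$transcript_id, tx$id)]
  expect_true(all(s1$reads$five_prime + s1$reads$length <= tlen))
})

test_that("with zero frame noise every accepted read is in frame 0", {
  cfg <- sim_config(n_transcripts = 20L, n_reads = 20000L,
                    frame_noise_rate = 0, seed = 3L)
  st <- sim_pipeline(cfg)
  expect_true(all(st$assignments$frame == 0L))
  # only the initiation-stage reads (E-site outside CDS) are rejected
  rej <- attr(st$assignments, "rejections")
  expect_equal(unname(rej["frame"]), 0L)
  expect_equal(unname(rej["outside_cds"]),
               as.integer(round(cfg$init_fraction * cfg$n_reads)))
})

test_that("doubled ANN dwell gives the closed-form A-site ANN share", {
  # share = 2*16 / (2*16 + 45) with uniform usage; tolerance covers both
  # read sampling and transcript composition noise at this depth
  cfg <- sim_config(n_transcripts = 200L, n_reads = 100000L, seed = 1L)
  st <- sim_pipeline(cfg, dwell = class_dwell_model("ANN", 2), offset = 15L)
  tx_idx <- match(st$assignments$transcript_id, st$tx$id)
  a_codons <- substring(
    st$tx$sequence[tx_idx],
    st$tx$cds_start[tx_idx] + 3L * st$assignments$a + 1L,
    st$tx$cds_start[tx_idx] + 3L * st$assignments$a + 3L)
  share <- mean(classify_codon(a_codons) == "ANN")
  expect_equal(share, 32 / 77, tolerance = 0.01 / (32 / 77))
})

test_that("condition pairs record the true per-gene density fold change", {
  tx <- generate_transcriptome(sim_config(n_transcripts = 20L, seed = 9L))
  cfg <- sim_config(n_transcripts = 20L, n_reads = 1000L, seed = 9L)
  # identical configs: true log2FC identically zero
  pair0 <- simulate_condition_pair(tx, cfg, cfg)
  expect_true(all(pair0$truth$true_log2fc == 0))
  # double one gene's coverage and rescale depth so its true ratio is 2
  cov_kd <- rep(1, 20L); cov_kd[3L] <- 2
  z <- sum(cov_kd * n_codons(tx)) / sum(n_codons(tx))
  cfg_kd <- sim_config(n_transcripts = 20L,
                       n_reads = as.integer(round(1000 * z)),
                       per_gene_coverage = cov_kd, seed = 10L)
  pair <- simulate_condition_pair(tx, cfg, cfg_kd)
  expect_equal(unname(pair$truth$true_log2fc["g0003"]), 1, tolerance = 1e-3)
  # changing only the seed changes reads, not the ground truth
  cfg_b <- cfg; cfg_b$seed <- 99L
  pair_b <- simulate_condition_pair(tx, cfg_b, cfg_kd)
  expect_equal(pair_b$truth$true_log2fc, pair$truth$true_log2fc)
  expect_false(identical(pair_b$ctr[[1L]]$reads, pair$ctr[[1L]]$reads))
})

test_that("isodecoder count simulation matches its closed-form group shares", {
  s0 <- simulate_isodecoder_counts(n_isodecoders = 48L, depth = 50000L,
                                   group_effect = 1, seed = 4L)
  s0b <- simulate_isodecoder_counts(n_isodecoders = 48L, depth = 50000L,
                                    group_effect = 1, seed = 4L)
  expect_identical(s0, s0b)
  expect_equal(sum(s0$ctr$count), 50000L)
  expect_equal(sum(s0$kd$count), 50000L)
  expect_equal(s0$truth$expected_group_share_ctr,
               s0$truth$expected_group_share_kd)
  # group_effect = 2 on NNU with uniform group mass: share 0.25 -> 0.4
  s2 <- simulate_isodecoder_counts(n_isodecoders = 64L, depth = 50000L,
                                   group_effect = 2, seed = 5L)
  expect_equal(unname(s2$truth$expected_group_share_kd["NNU"]),
               2 * 0.25 / 1.25)
  grp <- anticodon_group(s2$kd$anticodon)
  obs <- sum(s2$kd$count[grp == "NNU"]) / sum(s2$kd$count)
  se <- sqrt(0.4 * 0.6 / 50000)
  expect_lt(abs(obs - 0.4), 3 * se)
})

test_that("spot grids are deterministic and couple signature to proximity", {
  g1 <- simulate_spot_grid(n_spots = 200L, seed = 8L)
  g2 <- simulate_spot_grid(n_spots = 200L, seed = 8L)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 200L)
  expect_true(any(g1$total_counts < 100L))  # QC filter has work to do
  # near-noise-free, coupled: signature ~ -distance to enriched spots
  g <- simulate_spot_grid(n_spots = 300L, score_noise_sd = 1e-6,
                          coupling = 1, seed = 2L)
  enr <- enriched_spots(g)
  d <- min_distance_to_enriched(g, enr)
  expect_lt(cor(g$signature_score, d, method = "spearman"), -0.95)
})
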