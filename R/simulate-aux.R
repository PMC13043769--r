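#' Simulate tRNA isodecoder count tables for two conditions
#'
#' Draws multinomial read counts over a synthetic isodecoder set for a
#' control and a perturbed condition. In the perturbed condition the
#' sampling mass of isodecoders belonging to `effect_groups` (anticodon
#' groups by 3' base) is multiplied by `group_effect` before
#' renormalisation.
#'
#' @param n_isodecoders Number of isodecoders; anticodons are drawn without
#'   replacement from the 64 triplets (so at most 64).
#' @param depth Total read count per condition.
#' @param group_effect Positive multiplier applied in condition 2.
#' @param effect_groups Character vector of anticodon groups, default "NNU".
#' @param seed Integer seed.
#' @return List with `ctr` and `kd` count data.frames (isodecoder_id,
#'   anticodon, count) and `truth` (expected shares per condition and per
#'   group).
#' @export
simulate_isodecoder_counts <- function(n_isodecoders = 48L, depth = 100000L,
                                       group_effect = 1, effect_groups = "NNU",
                                       seed = 1L) {
  stopifnot(depth > 0, n_isodecoders >= 1L, n_isodecoders <= 64L,
            group_effect > 0)
  withr::local_seed(seed)
  anticodons <- sample(chartr("T", "U", all_codons()), n_isodecoders)
  ids <- paste0("iso-", anticodons)
  grp <- anticodon_group(anticodons)
  mass_ctr <- rep(1 / n_isodecoders, n_isodecoders)
  mass_kd <- mass_ctr * ifelse(grp %in% effect_groups, group_effect, 1)
  mass_kd <- mass_kd / sum(mass_kd)
  draw <- function(mass) {
    data.frame(
      isodecoder_id = ids, anticodon = anticodons,
      count = as.integer(stats::rmultinom(1L, depth, mass)),
      stringsAsFactors = FALSE
    )
  }
  ctr <- draw(mass_ctr)
  kd <- draw(mass_kd)
  group_share <- function(mass) {
    vapply(split(mass, grp), sum, numeric(1L))
  }
  list(
    ctr = ctr, kd = kd,
    truth = list(
      expected_share_ctr = setNames(mass_ctr, ids),
      expected_share_kd = setNames(mass_kd, ids),
      expected_group_share_ctr = group_share(mass_ctr),
      expected_group_share_kd = group_share(mass_kd),
      depth = depth, group_effect = group_effect,
      effect_groups = effect_groups, seed = seed
    )
  )
}

#' Simulate a spatial-transcriptomics spot grid
#'
#' Spots sit on a jittered square grid. The T-cell score decays
#' exponentially with distance to the nearest focus centre plus Gaussian
#' noise; the signature score is `coupling` times the (noise-free) T-cell
#' field plus independent noise. Total transcript counts are drawn so that
#' about `low_count_fraction` of spots fall below 100 counts, exercising
#' the spot QC filter.
#'
#' @param n_spots Number of spots (> 4).
#' @param field_size Side length of the square field (tissue units).
#' @param tcell_focus_centers Two-column matrix of focus coordinates;
#'   default three fixed foci inside the field.
#' @param score_noise_sd Gaussian noise sd on both scores.
#' @param coupling Linear coupling of signature score to the T-cell field.
#' @param low_count_fraction Expected fraction of spots with < 100 counts.
#' @param decay_scale Length scale of the exponential decay (defaults to
#'   `field_size / 5`).
#' @param seed Integer seed.
#' @return A data.frame of class `spot_grid`: spot_id, x, y, total_counts,
#'   tcell_score, signature_score; the generating parameters are stored in
#'   the `truth` attribute.
#' @export
simulate_spot_grid <- function(n_spots = 500L, field_size = 100,
                               tcell_focus_centers = NULL,
                               score_noise_sd = 0.2, coupling = 1,
                               low_count_fraction = 0.1,
                               decay_scale = NULL, seed = 1L) {
  stopifnot(n_spots > 4L, field_size > 0)
  if (is.null(decay_scale)) decay_scale <- field_size / 5
  if (is.null(tcell_focus_centers)) {
    tcell_focus_centers <- field_size * rbind(
      c(0.25, 0.25), c(0.75, 0.35), c(0.4, 0.8))
  }
  withr::local_seed(seed)
  side <- ceiling(sqrt(n_spots))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(n_spots), ]
  step <- field_size / side
  x <- (g$ix - 0.5) * step + stats::rnorm(n_spots, 0, step / 6)
  y <- (g$iy - 0.5) * step + stats::rnorm(n_spots, 0, step / 6)
  d_focus <- apply(tcell_focus_centers, 1L, function(ctr) {
    sqrt((x - ctr[1L])^2 + (y - ctr[2L])^2)
  })
  d_min <- apply(cbind(d_focus), 1L, min)
  field <- exp(-d_min / decay_scale)
  tcell <- field + stats::rnorm(n_spots, 0, score_noise_sd)
  signature <- coupling * field + stats::rnorm(n_spots, 0, score_noise_sd)
  low <- stats::runif(n_spots) < low_count_fraction
  counts <- ifelse(low,
                   sample(20:99, n_spots, replace = TRUE),
                   sample(100:10000, n_spots, replace = TRUE))
  out <- data.frame(
    spot_id = sprintf("spot%04d", seq_len(n_spots)),
    x = x, y = y,
    total_counts = as.integer(counts),
    tcell_score = tcell,
    signature_score = signature,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(
    focus_centers = tcell_focus_centers, coupling = coupling,
    score_noise_sd = score_noise_sd, decay_scale = decay_scale,
    low_count_fraction = low_count_fraction, seed = seed
  )
  class(out) <- c("spot_grid", "data.frame")
  out
}
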