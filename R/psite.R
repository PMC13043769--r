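#' Read footprint alignments from SAM or BAM (transcript coordinates)
#'
#' Only primary, mapped, forward records (flag 0) are used. SAM input is
#' converted on the fly with Rsamtools; read length is taken from the
#' CIGAR-consumed reference span (simulator reads are `<L>M`).
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.frame: read_id, transcript_id, five_prime (0-based),
#'   length.
#' @export
read_footprints <- function(path) {
  if (!file.exists(path)) stop("missing alignment file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth")))[[1L]]
  keep <- res$flag == 0L & !is.na(res$pos)
  data.frame(
    read_id = res$qname[keep],
    transcript_id = as.character(res$rname[keep]),
    five_prime = res$pos[keep] - 1L,
    length = res$qwidth[keep],
    stringsAsFactors = FALSE
  )
}

#' Filter footprints by read length
#'
#' Keeps reads whose length lies in `[min_len, max_len]` inclusive
#' (default 27-33 nt, the RPF size range).
#'
#' @param reads Footprint table (needs a `length` column).
#' @param min_len,max_len Inclusive bounds in nt.
#' @return Filtered table; attribute `retained` holds c(kept, total).
#' @export
filter_by_length <- function(reads, min_len = 27L, max_len = 33L) {
  if (min_len > max_len) stop("min_len exceeds max_len")
  keep <- reads$length >= min_len & reads$length <= max_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "retained") <- c(kept = sum(keep), total = nrow(reads))
  out
}

#' Build the start-codon meta-profile
#'
#' Histogram of the displacement d = cds_start - five_prime over all reads
#' whose 5' end lies within `window` nt upstream of their transcript's
#' start codon. The mode of this profile is the P-site offset.
#'
#' @param reads Footprint table.
#' @param transcripts A `transcript_set`.
#' @param window Two-element inclusive range of d values kept, default
#'   c(5, 45).
#' @return Named integer vector of counts indexed by d, class
#'   `meta_profile`; window stored as attribute.
#' @export
build_start_metaprofile <- function(reads, transcripts, window = c(5L, 45L)) {
  idx <- match(reads$transcript_id, transcripts$id)
  if (anyNA(idx)) stop("reads reference transcripts absent from the set")
  d <- transcripts$cds_start[idx] - reads$five_prime
  d <- d[d >= window[1L] & d <= window[2L]]
  if (length(d) == 0L) stop("no read 5' ends fall inside the window")
  tab <- table(factor(d, levels = seq(window[1L], window[2L])))
  out <- setNames(as.integer(tab), names(tab))
  attr(out, "window") <- window
  class(out) <- "meta_profile"
  out
}

#' Infer the P-site offset from a meta-profile
#'
#' Returns the modal displacement; ties are broken toward the smallest d
#' with a warning.
#'
#' @param profile A `meta_profile` (named counts over d).
#' @return Integer offset in nt.
#' @export
infer_psite_offset <- function(profile) {
  counts <- as.integer(profile)
  if (length(counts) == 0L || sum(counts) == 0L) stop("empty meta-profile")
  top <- which(counts == max(counts))
  d <- as.integer(names(profile))[top]
  if (length(d) > 1L) {
    warning("modal displacement tied at {", paste(d, collapse = ", "),
            "}; taking the smallest")
  }
  min(d)
}

#' Resolve E/P/A-site and flanking codons for footprints
#'
#' Applies the P-site offset to each 5' end, labels the reading frame
#' (raw residue 0 -> frame 0, 1 -> +1, 2 -> -1), discards frames outside
#' `keep_frames`, and derives the codon indices e = p-1, a = p+1 and the
#' three flanking codons a+1..a+3. Frame -1 reads are snapped forward to
#' the nearest codon start. Reads whose sites fall outside the CDS or
#' touch the stop codon are rejected; rejection reasons are counted.
#'
#' @param reads Footprint table.
#' @param transcripts A `transcript_set`.
#' @param offset P-site offset in nt (e.g. from [infer_psite_offset()]).
#' @param keep_frames Frames retained, default c(0, -1).
#' @return Data.frame (read_id, transcript_id, gene_id, frame, e, p, a,
#'   f1, f2, f3); attribute `rejections` is a named count vector with
#'   reasons `frame`, `outside_cds`.
#' @export
assign_sites <- function(reads, transcripts, offset, keep_frames = c(0L, -1L)) {
  stopifnot(offset >= 0)
  idx <- match(reads$transcript_id, transcripts$id)
  if (anyNA(idx)) stop("reads reference transcripts absent from the set")
  cds_start <- transcripts$cds_start[idx]
  nc <- n_codons(transcripts)[idx]
  rel <- reads$five_prime + as.integer(offset) - cds_start
  raw <- ((rel %% 3L) + 3L) %% 3L
  frame <- c(0L, 1L, -1L)[raw + 1L]
  p <- rel %/% 3L + ifelse(frame == -1L, 1L, 0L)
  e <- p - 1L
  f3 <- p + 4L
  keep_frame <- frame %in% keep_frames
  # a..f3 must stay off the stop codon (last CDS codon)
  in_cds <- e >= 0L & f3 <= nc - 2L
  keep <- keep_frame & in_cds
  rejections <- c(
    frame = sum(!keep_frame),
    outside_cds = sum(keep_frame & !in_cds)
  )
  out <- data.frame(
    read_id = reads$read_id[keep],
    transcript_id = reads$transcript_id[keep],
    gene_id = transcripts$gene_id[idx][keep],
    frame = frame[keep],
    e = e[keep], p = p[keep], a = p[keep] + 1L,
    f1 = p[keep] + 2L, f2 = p[keep] + 3L, f3 = p[keep] + 4L,
    stringsAsFactors = FALSE
  )
  attr(out, "rejections") <- rejections
  attr(out, "offset") <- as.integer(offset)
  out
}
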