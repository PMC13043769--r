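#' @import Biostrings
#' @importFrom stats median quantile setNames
#' @importFrom utils read.delim write.table
NULL

NT <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#'
#' @return Character vector of the 64 DNA codons.
#' @export
all_codons <- function() {
  g <- expand.grid(b3 = NT, b2 = NT, b1 = NT, stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

#' Stop codons (DNA alphabet)
#' @return Character vector of the 3 stop codons.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' Sense codons (the 61 codons that encode an amino acid)
#' @return Character vector of the 61 sense codons.
#' @export
sense_codons <- function() setdiff(all_codons(), stop_codons())

.check_triplet <- function(x, what = "codon") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- nchar(x) != 3L | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid ", what, "(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Classify codons by their first base
#'
#' Codons are partitioned into the four classes ANN, CNN, GNN and UNN by
#' their first nucleotide; ANN codons are the ones decoded by
#' t6A-modified tRNAs.
#'
#' @param codon Character vector of codons (DNA or RNA alphabet).
#' @return Character vector of class labels in \{ANN, CNN, GNN, UNN\}.
#' @export
classify_codon <- function(codon) {
  codon <- .check_triplet(codon, "codon")
  c(A = "ANN", C = "CNN", G = "GNN", T = "UNN")[substr(codon, 1L, 1L)]
}

#' Group anticodons by their third (wobble-distal) base
#'
#' Anticodons are grouped by the base at their 3' end into NNU, NNA, NNG
#' and NNC; tRNAs with NNU anticodons are the t6A substrates.
#'
#' @param anticodon Character vector of anticodons, 5'->3' (U or T accepted).
#' @return Character vector of group labels in \{NNU, NNA, NNG, NNC\}.
#' @export
anticodon_group <- function(anticodon) {
  anticodon <- .check_triplet(anticodon, "anticodon")
  c(T = "NNU", A = "NNA", G = "NNG", C = "NNC")[substr(anticodon, 3L, 3L)]
}

#' Codon classification table
#'
#' @return A data.frame with columns `codon`, `class` and `is_stop`,
#'   one row per codon (64 rows).
#' @export
codon_class_table <- function() {
  codons <- all_codons()
  data.frame(
    codon = codons,
    class = unname(classify_codon(codons)),
    is_stop = codons %in% stop_codons(),
    stringsAsFactors = FALSE
  )
}

#' Anticodon group table
#'
#' @return A data.frame with columns `anticodon` (displayed with U) and
#'   `group`, one row per anticodon (64 rows).
#' @export
anticodon_group_table <- function() {
  acs <- all_codons()
  data.frame(
    anticodon = chartr("T", "U", acs),
    group = unname(anticodon_group(acs)),
    stringsAsFactors = FALSE
  )
}

#' Construct a transcript set
#'
#' Validates a set of transcripts against the CDS invariants:
#' 0 <= cds_start < cds_end <= length, CDS length a multiple of 3, and a
#' configurable minimum codon count. Offending records are dropped with a
#' warning; the number dropped is recorded in the `n_dropped` attribute.
#'
#' @param id,gene_id Character vectors.
#' @param sequence Character vector of nucleotide sequences (U normalised
#'   to T, case-folded to upper).
#' @param cds_start,cds_end Integer CDS bounds, 0-based half-open.
#' @param min_codons Minimum number of CDS codons (default 10).
#' @return A data.frame of class `transcript_set` with one row per valid
#'   transcript.
#' @export
transcript_set <- function(id, gene_id, sequence, cds_start, cds_end,
                           min_codons = 10L) {
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  n <- max(length(id), length(sequence))
  id <- rep_len(id, n)
  gene_id <- rep_len(gene_id, n)
  sequence <- rep_len(sequence, n)
  cds_start <- rep_len(as.integer(cds_start), n)
  cds_end <- rep_len(as.integer(cds_end), n)
  len <- nchar(sequence)
  ok <- !is.na(cds_start) & !is.na(cds_end) &
    cds_start >= 0L & cds_start < cds_end & cds_end <= len &
    (cds_end - cds_start) %% 3L == 0L &
    (cds_end - cds_start) %/% 3L >= min_codons
  if (any(!ok)) {
    warning(sum(!ok), " transcript(s) dropped for violating CDS invariants: ",
            paste(utils::head(id[!ok], 5L), collapse = ", "),
            if (sum(!ok) > 5L) ", ..." else "")
  }
  out <- data.frame(
    id = id[ok], gene_id = gene_id[ok], sequence = sequence[ok],
    cds_start = cds_start[ok], cds_end = cds_end[ok],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- sum(!ok)
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Number of CDS codons per transcript
#'
#' @param transcripts A `transcript_set`.
#' @return Integer vector, one entry per transcript.
#' @export
n_codons <- function(transcripts) {
  (transcripts$cds_end - transcripts$cds_start) %/% 3L
}

#' Extract the codon at a given CDS codon index
#'
#' Codon index 0 is the start codon. Vectorised over `k`.
#'
#' @param transcript A single-row `transcript_set`.
#' @param k 0-based codon index (vector allowed).
#' @return Character vector of codons.
#' @export
codon_at <- function(transcript, k) {
  stopifnot(nrow(transcript) == 1L)
  nc <- n_codons(transcript)
  if (any(k < 0L | k >= nc)) {
    stop("codon index out of CDS range [0, ", nc, ")")
  }
  start <- transcript$cds_start + 3L * k
  substring(transcript$sequence, start + 1L, start + 3L)
}

#' Load a transcriptome from FASTA plus a CDS annotation TSV
#'
#' The annotation is a 4-column tab-separated table with header
#' `id  gene_id  cds_start  cds_end` (0-based, half-open, transcript
#' coordinates). Annotation rows whose id is missing from the FASTA are an
#' error; transcripts violating CDS invariants are dropped with a warning.
#'
#' @param fasta_path Path to a FASTA file (ids taken up to first whitespace).
#' @param annotation_path Path to the annotation TSV.
#' @param min_codons Minimum CDS codon count (default 10).
#' @return A `transcript_set`.
#' @export
load_transcriptome <- function(fasta_path, annotation_path, min_codons = 10L) {
  if (!file.exists(fasta_path)) stop("missing FASTA file: ", fasta_path)
  if (!file.exists(annotation_path)) stop("missing annotation file: ", annotation_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  req <- c("id", "gene_id", "cds_start", "cds_end")
  if (!all(req %in% names(ann))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  absent <- setdiff(ann$id, names(seqs))
  if (length(absent) > 0L) {
    stop("annotation id(s) absent from FASTA: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  transcript_set(
    id = ann$id, gene_id = ann$gene_id,
    sequence = as.character(seqs[ann$id]),
    cds_start = ann$cds_start, cds_end = ann$cds_end,
    min_codons = min_codons
  )
}

#' Write a transcriptome as FASTA plus annotation TSV
#'
#' Inverse of [load_transcriptome()]; round-trips byte-identically for
#' valid inputs.
#'
#' @param transcripts A `transcript_set`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the transcript set.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(setNames(transcripts$sequence, transcripts$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(
    transcripts[, c("id", "gene_id", "cds_start", "cds_end")],
    annotation_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(transcripts)
}
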