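#' Frame-distribution entropy
#'
#' Entropy of the P-site frame proportions in base `n = 3`, so the value lies
#' in \[0, 1\]: 0 when all mass is on one frame (perfect periodicity), 1 when
#' mass is uniform over the three frames (no periodicity). `0 * log(0)` is
#' taken as 0.
#'
#' @param frame_props Numeric vector of three non-negative proportions
#'   summing to 1.
#' @param tol Tolerance on the sum-to-one check.
#' @return Entropy in \[0, 1\].
#' @export
frame_entropy <- function(frame_props, tol = 1e-6) {
  stopifnot(length(frame_props) == 3L, all(frame_props >= 0))
  if (abs(sum(frame_props) - 1) > tol) {
    stop("frame proportions must sum to 1 (got ", sum(frame_props), ")")
  }
  p <- frame_props[frame_props > 0]
  h <- -sum(p * log(p) / log(3))
  if (h <= 0) return(0)   # avoids signed zero from the negated sum
  min(h, 1)
}

#' Evidence weights from entropy
#'
#' Splits unit weight between the two footprint-occupancy t-tests and the two
#' codon-usage t-tests: the RPF pair receives `1 - entropy` (split evenly),
#' the codon-usage pair receives `entropy` (split evenly). Periodic
#' footprints (low entropy) therefore dominate; noisy footprints hand the
#' evidence to codon usage.
#'
#' @param entropy Value in \[0, 1\] from [frame_entropy()].
#' @return Named numeric vector `(rpf_01, rpf_02, codon_01, codon_02)`
#'   summing to 1.
#' @export
compute_weights <- function(entropy) {
  stopifnot(entropy >= 0, entropy <= 1)
  c(rpf_01 = (1 - entropy) / 2, rpf_02 = (1 - entropy) / 2,
    codon_01 = entropy / 2, codon_02 = entropy / 2)
}

#' Global P-site frame proportions on annotated CDSs
#'
#' Allocates retained reads to P-sites through the probabilistic offset table
#' and measures the proportion of P-site mass on frames 0/1/2 of the
#' annotated CDSs ((position - CDS start) mod 3), pooled over the metagene
#' transcript set.
#'
#' @param reads Projected reads (from [read_rpf_alignments()]).
#' @param transcripts Metagene transcript set with CDSs.
#' @param offset_table Offset table from [extract_offsets()].
#' @return Numeric vector `(p0, p1, p2)` summing to 1.
#' @export
measure_global_frame_props <- function(reads, transcripts, offset_table) {
  long <- .offsets_long(offset_table)
  reads <- reads[reads$transcript_id %in% names(transcripts), , drop = FALSE]
  m <- merge(reads, long, by = "read_length")
  if (nrow(m) == 0L) stop("no retained reads on annotated CDSs")
  cds_start <- vapply(transcripts, `[[`, integer(1L), "cds_start")
  cds_end <- vapply(transcripts, `[[`, integer(1L), "cds_end")
  psite <- m$tx_pos + m$offset
  inside <- psite >= cds_start[m$transcript_id] &
    psite < cds_end[m$transcript_id]
  m <- m[inside, , drop = FALSE]
  psite <- psite[inside]
  if (nrow(m) == 0L || sum(m$prob) == 0) {
    stop("no P-site mass falls on annotated CDSs; cannot measure frame usage")
  }
  fr <- (psite - cds_start[m$transcript_id]) %% 3L
  mass <- vapply(0:2, function(f) sum(m$prob[fr == f]), numeric(1L))
  mass / sum(mass)
}
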