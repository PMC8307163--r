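#' Read RPF alignments and project their 5' ends onto transcripts
#'
#' Loads primary alignments from a coordinate-sorted, indexed BAM, applies a
#' mapping-quality filter, and projects each read's 5'-end genomic position
#' (alignment start on `+`, alignment end on `-`) into the coordinates of
#' every same-strand transcript whose exons contain it. A read overlapping
#' several transcripts yields one row per transcript.
#'
#' @param bam Path to an indexed BAM file.
#' @param transcripts List of transcript models.
#' @param min_mapq Minimum mapping quality (default 10).
#' @return data.frame with columns `transcript_id`, `tx_pos` (0-based
#'   transcript coordinate of the read 5' end), `read_length`. The numbers of
#'   reads loaded and of reads on chromosomes absent from the annotation are
#'   attached as attributes `n_reads` and `n_unannotated_chrom`.
#' @export
read_rpf_alignments <- function(bam, transcripts, min_mapq = 10L) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index (.bai) not found for: ", bam)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  chrom <- as.character(GenomicAlignments::seqnames(aln))
  strand <- as.character(GenomicAlignments::strand(aln))
  pos5 <- ifelse(strand == "+",
                 GenomicAlignments::start(aln),
                 GenomicAlignments::end(aln))
  read_len <- GenomicAlignments::qwidth(aln)
  tx_chroms <- unique(vapply(transcripts, `[[`, character(1L), "chrom"))
  unann <- !(chrom %in% tx_chroms)
  proj <- .project_points(chrom, pos5, strand, read_len, transcripts)
  attr(proj, "n_reads") <- length(aln)
  attr(proj, "n_unannotated_chrom") <- sum(unann)
  proj
}

.project_points <- function(chrom, pos, strand, read_len, transcripts) {
  out <- vector("list", length(transcripts))
  for (j in seq_along(transcripts)) {
    m <- transcripts[[j]]
    sel <- which(chrom == m$chrom & strand == m$strand)
    if (length(sel) == 0L) next
    tx <- .genome_to_tx(m, pos[sel])
    ok <- !is.na(tx)
    if (!any(ok)) next
    out[[j]] <- data.frame(
      transcript_id = m$transcript_id,
      tx_pos = tx[ok],
      read_length = read_len[sel][ok],
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(0), tx_pos = integer(0),
                      read_length = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Pick the metagene transcript set
#'
#' One transcript per gene: the protein-coding transcript with the longest
#' annotated CDS. Used for metagene profiles, offset extraction and the
#' global frame-proportion measurement.
#'
#' @param transcripts List of transcript models.
#' @return Named list of transcript models (subset).
#' @export
select_metagene_transcripts <- function(transcripts) {
  coding <- Filter(function(m) !is.na(m$cds_start), transcripts)
  if (length(coding) == 0L) return(coding)
  genes <- vapply(coding, `[[`, character(1L), "gene_id")
  cds_len <- vapply(coding, function(m) m$cds_end - m$cds_start, integer(1L))
  keep <- unlist(lapply(split(seq_along(coding), genes), function(ix) {
    ix[which.max(cds_len[ix])]
  }), use.names = FALSE)
  coding[keep]
}

#' Metagene profiles of read 5' ends around annotated start codons
#'
#' For each observed read length, accumulates raw (un-shifted) 5'-end
#' positions of reads falling within the first `window` nt of annotated CDSs,
#' across the metagene transcript set.
#'
#' @param reads Projected reads from [read_rpf_alignments()], or a BAM path.
#' @param transcripts Metagene transcript set (see
#'   [select_metagene_transcripts()]); each must carry a CDS.
#' @param window Window width in nt (default 60).
#' @param min_mapq Passed to [read_rpf_alignments()] when `reads` is a path.
#' @return Named list (by read length) of numeric depth vectors of length
#'   `window`, position 0 = annotated start codon first base. Each vector
#'   carries an `n_reads` attribute.
#' @export
build_metagene <- function(reads, transcripts, window = 60L, min_mapq = 10L) {
  if (is.character(reads)) {
    reads <- read_rpf_alignments(reads, transcripts, min_mapq)
  }
  stopifnot(all(vapply(transcripts, function(m) !is.na(m$cds_start),
                       logical(1L))))
  cds_start <- vapply(transcripts, `[[`, integer(1L), "cds_start")
  reads <- reads[reads$transcript_id %in% names(transcripts), , drop = FALSE]
  if (nrow(reads) == 0L) return(structure(list(), class = "metagene_profiles"))
  rel <- reads$tx_pos - cds_start[reads$transcript_id]
  keep <- rel >= 0L & rel < window
  reads <- reads[keep, , drop = FALSE]
  rel <- rel[keep]
  profiles <- lapply(split(rel, reads$read_length), function(r) {
    structure(tabulate(r + 1L, nbins = window), n_reads = length(r))
  })
  structure(profiles, class = "metagene_profiles")
}

#' Triplet-periodicity test of a metagene profile
#'
#' Treats the depth vector as a 1 Hz-sampled signal and applies the
#' multitaper harmonic F-test; a read length is periodic when the p-value at
#' the Fourier frequency nearest 1/3 cycles per nt falls below `p_cutoff`.
#' The test is scale-invariant in the profile.
#'
#' @param depth Numeric depth vector (one metagene profile).
#' @param nw,k Multitaper time-bandwidth product and taper count.
#' @param p_cutoff Significance threshold (default 0.01).
#' @return list with `p_value`, `passed`, `frequency` (tested bin) and
#'   `peak_frequency` (frequency of the maximal F statistic, excluding DC).
#' @export
test_periodicity <- function(depth, nw = 3, k = 5, p_cutoff = 0.01) {
  if (all(depth == 0)) {
    return(list(p_value = 1, passed = FALSE, frequency = NA_real_,
                peak_frequency = NA_real_))
  }
  spec <- harmonic_ftest(depth, nw = nw, k = k)
  i <- which.min(abs(spec$frequency - 1 / 3))
  nondc <- spec[spec$frequency > 0, , drop = FALSE]
  list(
    p_value = spec$p[i],
    passed = is.finite(spec$p[i]) && spec$p[i] < p_cutoff,
    frequency = spec$frequency[i],
    peak_frequency = nondc$frequency[which.max(nondc$F)]
  )
}

#' Periodicity screen over all read lengths
#'
#' @param profiles Output of [build_metagene()].
#' @inheritParams test_periodicity
#' @return data.frame with columns `read_length`, `n_reads`, `p_value`,
#'   `passed`.
#' @export
screen_read_lengths <- function(profiles, nw = 3, k = 5, p_cutoff = 0.01) {
  res <- lapply(names(profiles), function(len) {
    tp <- test_periodicity(profiles[[len]], nw = nw, k = k,
                           p_cutoff = p_cutoff)
    data.frame(read_length = as.integer(len),
               n_reads = attr(profiles[[len]], "n_reads"),
               p_value = tp$p_value, passed = tp$passed,
               stringsAsFactors = FALSE)
  })
  if (length(res) == 0L) {
    return(data.frame(read_length = integer(0), n_reads = integer(0),
                      p_value = numeric(0), passed = logical(0)))
  }
  do.call(rbind, res)
}

#' Probabilistic P-site offset table
#'
#' For each retained read length, builds the distribution of distances from
#' read 5' ends to annotated start codons (reads overlapping a start codon
#' only) and reports the three highest-depth distances as offsets with
#' probabilities proportional to their depths. The modal distance ranks
#' first; ranks 2 and 3 are the next two highest-depth distances within
#' mode +/- 3 nt; ties prefer the smaller distance. Lengths with fewer than
#' `min_reads` start-overlapping reads fall back to the canonical offset.
#'
#' @param reads Projected reads (from [read_rpf_alignments()]) or a BAM path.
#' @param transcripts Metagene transcript set with CDSs.
#' @param retained_lengths Integer vector of read lengths that passed the
#'   periodicity screen.
#' @param min_reads Minimum start-overlapping reads per length (default 30).
#' @param fallback_offset Canonical fallback offset (default 12 nt).
#' @param min_mapq Passed to [read_rpf_alignments()] when `reads` is a path.
#' @return data.frame with one row per length: `read_length`, `offset1..3`,
#'   `prob1..3`, `n_reads`, `fallback`.
#' @export
extract_offsets <- function(reads, transcripts, retained_lengths,
                            min_reads = 30L, fallback_offset = 12L,
                            min_mapq = 10L) {
  if (length(retained_lengths) == 0L) {
    stop("no read length was retained; cannot extract offsets")
  }
  if (is.character(reads)) {
    reads <- read_rpf_alignments(reads, transcripts, min_mapq)
  }
  cds_start <- vapply(transcripts, `[[`, integer(1L), "cds_start")
  reads <- reads[reads$transcript_id %in% names(transcripts), , drop = FALSE]
  rows <- lapply(sort(retained_lengths), function(L) {
    r <- reads[reads$read_length == L, , drop = FALSE]
    d <- cds_start[r$transcript_id] - r$tx_pos
    # read [x, x+L) overlaps the start codon [cds_start, cds_start+3)
    d <- d[d >= 0L & d < L]
    if (length(d) < min_reads) {
      message("read length ", L, ": only ", length(d),
              " reads overlap start codons; using fallback offset ",
              fallback_offset)
      return(data.frame(read_length = L,
                        offset1 = fallback_offset,
                        offset2 = fallback_offset - 1L,
                        offset3 = fallback_offset + 1L,
                        prob1 = 1, prob2 = 0, prob3 = 0,
                        n_reads = length(d), fallback = TRUE))
    }
    tab <- table(d)
    dist <- as.integer(names(tab))
    depth <- as.integer(tab)
    mode_i <- order(-depth, dist)[1L]
    d1 <- dist[mode_i]
    in_win <- which(abs(dist - d1) <= 3L & dist != d1)
    in_win <- in_win[order(-depth[in_win], dist[in_win])]
    chosen_d <- dist[c(mode_i, head(in_win, 2L))]
    chosen_n <- depth[c(mode_i, head(in_win, 2L))]
    # pad with unobserved neighbours (zero depth) to keep three slots
    pad <- setdiff(d1 + c(1L, -1L, 2L, -2L, 3L), chosen_d)
    pad <- pad[pad >= 0L]
    while (length(chosen_d) < 3L) {
      chosen_d <- c(chosen_d, pad[1L]); pad <- pad[-1L]
      chosen_n <- c(chosen_n, 0L)
    }
    p <- chosen_n / sum(chosen_n)
    data.frame(read_length = L,
               offset1 = chosen_d[1L], offset2 = chosen_d[2L],
               offset3 = chosen_d[3L],
               prob1 = p[1L], prob2 = p[2L], prob3 = p[3L],
               n_reads = length(d), fallback = FALSE)
  })
  do.call(rbind, rows)
}

# offset table -> long form (read_length, offset, prob)
.offsets_long <- function(offset_table) {
  do.call(rbind, lapply(seq_len(nrow(offset_table)), function(i) {
    data.frame(
      read_length = offset_table$read_length[i],
      offset = c(offset_table$offset1[i], offset_table$offset2[i],
                 offset_table$offset3[i]),
      prob = c(offset_table$prob1[i], offset_table$prob2[i],
               offset_table$prob3[i])
    )
  }))
}
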