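#' Assemble spliced transcript models from a genome and annotation
#'
#' Reads a reference genome (FASTA) and an annotation (GTF), splices exon
#' sequences into 5'->3' transcript sequences (minus-strand transcripts are
#' reverse-complemented), and maps any annotated CDS into transcript
#' coordinates. All transcript coordinates are 0-based, half-open; the GTF's
#' 1-based inclusive genomic coordinates are converted on read.
#'
#' The CDS span is normalized to include the stop codon: when the triplet
#' immediately downstream of the annotated CDS is a stop codon the span is
#' extended by 3 nt. A CDS whose length is not a multiple of 3 is trimmed at
#' its 3' end to the largest multiple of 3, with a warning.
#'
#' @param genome Path to a FASTA file, or a named [Biostrings::DNAStringSet].
#' @param annotation Path to a GTF file, or a [GenomicRanges::GRanges] as
#'   returned by [rtracklayer::import()].
#' @return A named list of `TranscriptModel` objects (class
#'   `"transcript_model"`), each a list with elements `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `exons` (a `GRanges`, ascending genomic
#'   order), `spliced_seq` (character), `cds_start`/`cds_end` (0-based
#'   half-open transcript coordinates, `NA` when no CDS is annotated) and
#'   `biotype`.
#' @export
assemble_transcripts <- function(genome, annotation) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation, format = "gtf")
  }
  feat <- annotation
  exons <- feat[feat$type == "exon"]
  if (length(exons) == 0L) stop("annotation contains no exon features")
  missing_chrom <- setdiff(
    unique(as.character(GenomicRanges::seqnames(exons))), names(genome)
  )
  if (length(missing_chrom) > 0L) {
    stop("annotation references chromosome(s) absent from the genome: ",
         paste(missing_chrom, collapse = ", "))
  }
  cds <- feat[feat$type == "CDS"]

  exon_tx <- as.character(exons$transcript_id)
  cds_tx <- as.character(cds$transcript_id)
  exon_seqs <- .exon_seqs(genome, exons)

  tx_ids <- unique(exon_tx)
  models <- vector("list", length(tx_ids))
  names(models) <- tx_ids
  for (tid in tx_ids) {
    idx <- which(exon_tx == tid)
    ex <- exons[idx]
    o <- order(GenomicRanges::start(ex))
    ex <- ex[o]
    idx <- idx[o]
    strand <- as.character(GenomicRanges::strand(ex))[1L]
    if (!strand %in% c("+", "-")) {
      warning("transcript ", tid, " has no strand; skipped")
      next
    }
    # getSeq already reverse-complemented minus-strand exons; transcript order
    # on the minus strand is descending genomic order
    seq_order <- if (strand == "+") seq_along(idx) else rev(seq_along(idx))
    spliced <- as.character(
      Biostrings::DNAStringSet(
        paste(as.character(exon_seqs[idx][seq_order]), collapse = "")
      )
    )
    gene_id <- as.character(ex$gene_id)[1L]
    biotype <- .feature_biotype(ex)
    m <- list(
      transcript_id = tid,
      gene_id = gene_id,
      chrom = as.character(GenomicRanges::seqnames(ex))[1L],
      strand = strand,
      exons = ex,
      spliced_seq = spliced,
      cds_start = NA_integer_,
      cds_end = NA_integer_,
      biotype = biotype
    )
    cidx <- which(cds_tx == tid)
    if (length(cidx) > 0L) {
      span <- .cds_to_tx_span(m, cds[cidx])
      m$cds_start <- span[1L]
      m$cds_end <- span[2L]
      m <- .normalize_cds(m)
    }
    class(m) <- "transcript_model"
    models[[tid]] <- m
  }
  models[!vapply(models, is.null, logical(1L))]
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "none" else paste0("[", x$cds_start, ", ", x$cds_end, ")")
  cat(sprintf("TranscriptModel %s (%s) %s:%s %d exon(s), %d nt, CDS %s, biotype %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exons), nchar(x$spliced_seq), cds, x$biotype))
  invisible(x)
}

# strand-aware exon sequences (DNAStringSet), aligned with `exons`
.exon_seqs <- function(genome, exons) {
  out <- Biostrings::DNAStringSet(rep("", length(exons)))
  for (ch in unique(as.character(GenomicRanges::seqnames(exons)))) {
    idx <- which(as.character(GenomicRanges::seqnames(exons)) == ch)
    r <- IRanges::IRanges(GenomicRanges::start(exons)[idx],
                          GenomicRanges::end(exons)[idx])
    if (any(IRanges::end(r) > length(genome[[ch]]))) {
      stop("exon outside chromosome ", ch)
    }
    out[idx] <- Biostrings::extractAt(genome[[ch]], r)
  }
  minus <- as.character(GenomicRanges::strand(exons)) == "-"
  if (any(minus)) {
    out[minus] <- Biostrings::reverseComplement(out[minus])
  }
  out
}

.feature_biotype <- function(gr) {
  m <- S4Vectors::mcols(gr)
  for (key in c("transcript_biotype", "gene_biotype", "source")) {
    if (key %in% names(m)) {
      v <- as.character(m[[key]])[1L]
      if (!is.na(v) && nzchar(v)) return(v)
    }
  }
  NA_character_
}

# genomic position (1-based) -> transcript coordinate (0-based)
.genome_to_tx <- function(model, gpos) {
  ex <- model$exons
  st <- GenomicRanges::start(ex)
  en <- GenomicRanges::end(ex)
  w <- en - st + 1L
  if (model$strand == "+") {
    off <- cumsum(c(0L, w))[seq_along(w)]
    i <- findInterval(gpos, st)
    ok <- i >= 1L & gpos <= en[pmax(i, 1L)]
    out <- rep(NA_integer_, length(gpos))
    out[ok] <- off[i[ok]] + (gpos[ok] - st[i[ok]])
    out
  } else {
    # transcript 5' end is the highest genomic coordinate
    off <- cumsum(c(0L, rev(w)))[seq_along(w)]  # offsets for exons in descending order
    ex_desc_start <- rev(st)
    ex_desc_end <- rev(en)
    i <- findInterval(-gpos, -ex_desc_end)  # first exon (descending) with end >= gpos
    ok <- i >= 1L & gpos >= ex_desc_start[pmax(i, 1L)]
    out <- rep(NA_integer_, length(gpos))
    out[ok] <- off[i[ok]] + (ex_desc_end[i[ok]] - gpos[ok])
    out
  }
}

.cds_to_tx_span <- function(model, cds_gr) {
  gpos <- c(GenomicRanges::start(cds_gr), GenomicRanges::end(cds_gr))
  tx <- .genome_to_tx(model, gpos)
  if (anyNA(tx)) {
    stop("CDS of transcript ", model$transcript_id, " falls outside its exons")
  }
  c(min(tx), max(tx) + 1L)
}

.normalize_cds <- function(model) {
  n <- nchar(model$spliced_seq)
  # include the stop codon when it directly follows the annotated CDS
  if (model$cds_end + 3L <= n) {
    trip <- substr(model$spliced_seq, model$cds_end + 1L, model$cds_end + 3L)
    if (trip %in% STOP_CODONS) model$cds_end <- model$cds_end + 3L
  }
  len <- model$cds_end - model$cds_start
  if (len %% 3L != 0L) {
    warning("CDS of transcript ", model$transcript_id,
            " is not a multiple of 3; trimming 3' end")
    model$cds_end <- model$cds_start + (len %/% 3L) * 3L
  }
  model
}

#' Genome-wide codon usage of annotated CDSs
#'
#' Tallies every in-frame sense triplet of every annotated CDS and normalizes
#' to relative frequencies over the 64 triplets. The terminal stop codon is
#' excluded from counting; triplets containing ambiguity codes are skipped.
#'
#' @param transcripts List of transcript models from [assemble_transcripts()].
#' @return Named numeric vector of length 64 (codon usage table), summing to 1.
#' @export
compute_codon_usage <- function(transcripts) {
  seqs <- character(0)
  for (m in transcripts) {
    if (is.na(m$cds_start)) next
    s <- substr(m$spliced_seq, m$cds_start + 1L, m$cds_end)
    if (nchar(s) >= 3L &&
        substr(s, nchar(s) - 2L, nchar(s)) %in% STOP_CODONS) {
      s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) >= 3L) seqs <- c(seqs, s)
  }
  if (length(seqs) == 0L) {
    stop("no annotated CDS in the input; codon usage cannot be computed")
  }
  counts <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(seqs), step = 3
  ))
  counts / sum(counts)
}

#' Enumerate candidate ORFs on a transcript
#'
#' Scans the spliced transcript sequence in all three frames. For every stop
#' codon, every upstream in-frame start codon with no intervening in-frame
#' stop yields one candidate. The stop codon is included in `length_nt`.
#'
#' @param model A transcript model.
#' @param start_codons Allowed start codons, a subset of ATG/CTG/GTG/TTG.
#' @param min_length_nt Minimum candidate length in nt including the stop
#'   codon (default 9, i.e. at least two sense codons).
#' @return data.frame with columns `transcript_id`, `start_pos`, `stop_pos`
#'   (0-based transcript coordinates of the first base of the start and stop
#'   codons), `start_codon`, `frame`, `length_nt`.
#' @export
enumerate_candidates <- function(model, start_codons = "ATG",
                                 min_length_nt = 9L) {
  stopifnot(all(start_codons %in% NUG_STARTS))
  s <- model$spliced_seq
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    starts1 <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (length(starts1) == 0L) next
    codons <- substring(s, starts1, starts1 + 2L)
    stop_i <- which(codons %in% STOP_CODONS)
    start_i <- which(codons %in% start_codons)
    if (length(stop_i) == 0L || length(start_i) == 0L) next
    # for each start, the first stop at or after it
    nxt <- stop_i[findInterval(start_i - 1L, stop_i) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    start_i <- start_i[ok]; nxt <- nxt[ok]
    start_pos <- starts1[start_i] - 1L
    stop_pos <- starts1[nxt] - 1L
    len <- stop_pos + 3L - start_pos
    keep <- len >= min_length_nt
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = model$transcript_id,
      start_pos = start_pos[keep],
      stop_pos = stop_pos[keep],
      start_codon = codons[start_i][keep],
      frame = f,
      length_nt = len[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(0), start_pos = integer(0),
                      stop_pos = integer(0), start_codon = character(0),
                      frame = integer(0), length_nt = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start_pos, res$stop_pos), , drop = FALSE]
}

#' Enumerate candidate ORFs across a transcript set
#'
#' @inheritParams enumerate_candidates
#' @param transcripts List of transcript models.
#' @return Row-bound data.frame of per-transcript candidates.
#' @export
enumerate_all_candidates <- function(transcripts, start_codons = "ATG",
                                     min_length_nt = 9L) {
  do.call(rbind, lapply(transcripts, enumerate_candidates,
                        start_codons = start_codons,
                        min_length_nt = min_length_nt))
}

# map a transcript interval [s, e) (0-based) to genomic blocks (GRanges)
.tx_span_to_genome <- function(model, s, e) {
  ex <- model$exons
  w <- GenomicRanges::end(ex) - GenomicRanges::start(ex) + 1L
  if (model$strand == "+") {
    g_start <- GenomicRanges::start(ex)
    offs <- cumsum(c(0L, w))[seq_along(w)]
  } else {
    g_start <- rev(GenomicRanges::start(ex))
    g_end <- rev(GenomicRanges::end(ex))
    w <- rev(w)
    offs <- cumsum(c(0L, w))[seq_along(w)]
  }
  blocks <- list()
  for (i in seq_along(w)) {
    lo <- max(s, offs[i]); hi <- min(e, offs[i] + w[i])
    if (lo >= hi) next
    if (model$strand == "+") {
      gs <- g_start[i] + (lo - offs[i]); ge <- g_start[i] + (hi - offs[i]) - 1L
    } else {
      ge <- g_end[i] - (lo - offs[i]); gs <- g_end[i] - (hi - offs[i]) + 1L
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, blocks)
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(m[, 1L], m[, 2L]),
                         strand = model$strand)
}

#' Export candidate or predicted ORFs as BED12
#'
#' @param orfs data.frame with at least `transcript_id`, `start_pos`,
#'   `stop_pos` columns (transcript coordinates).
#' @param transcripts List of transcript models.
#' @param file Output path.
#' @param name_col Column used for the BED name field.
#' @return Invisibly, the path written.
#' @export
export_bed12 <- function(orfs, transcripts, file, name_col = "transcript_id") {
  lines <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    m <- transcripts[[orfs$transcript_id[i]]]
    gr <- .tx_span_to_genome(m, orfs$start_pos[i], orfs$stop_pos[i] + 3L)
    gr <- GenomicRanges::sort(gr)
    cs <- GenomicRanges::start(gr) - 1L
    ce <- GenomicRanges::end(gr)
    lines[i] <- paste(
      as.character(GenomicRanges::seqnames(gr))[1L], min(cs), max(ce),
      paste0(orfs[[name_col]][i], ":", orfs$start_pos[i], "-",
             orfs$stop_pos[i] + 3L),
      0, m$strand, min(cs), max(ce), "0,0,0", length(gr),
      paste0(paste(ce - cs, collapse = ","), ","),
      paste0(paste(cs - min(cs), collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(lines, file)
  invisible(file)
}
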