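#' Synthetic codon usage bias
#'
#' A fixed, deterministic skewed usage table over the 61 sense codons
#' (geometric decay, ratio 0.93, over the alphabetically ordered sense
#' codons). The spread between the most- and least-used codon (roughly 7% to
#' 0.1%) is in the range observed in compact eukaryotic genomes. Stop codons
#' get zero weight.
#'
#' @return Named numeric vector over the 64 triplets summing to 1.
#' @export
default_codon_usage <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all64 <- sort(all64)
  sense <- setdiff(all64, STOP_CODONS)
  w <- stats::setNames(numeric(64), all64)
  w[sense] <- 0.93^(seq_along(sense) - 1)
  w / sum(w)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genome and footprint generator.
#' Defaults describe the standard fixture: 50 translated protein-coding
#' genes plus 50 untranslated candidate-bearing non-coding transcripts,
#' canonical 28-nt footprints with a 12-nt P-site offset, frame fidelity 0.9
#' and no trimming noise.
#'
#' @param seed Integer RNG seed (all outputs deterministic given the seed).
#' @param n_coding,n_noncoding,n_te,n_pseudogene Gene counts per biotype.
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param cds_codons Length-2 range of CDS lengths in sense codons
#'   (start codon included, stop excluded).
#' @param intron_every Every k-th coding gene gets one intron (0 = none).
#' @param intron_len Intron length (nt).
#' @param read_length_dist Named probability vector over read lengths,
#'   e.g. `c("28" = 1)` or a peak-32 mixture.
#' @param true_offset Planted 5'-end-to-P-site distance (nt, default 12).
#' @param frame_fidelity Fraction of reads whose 5' end sits exactly at the
#'   planted offset; the remainder is jittered by +/- 1-2 nt.
#' @param reads_per_cds Footprints generated per translated ORF.
#' @param start_pause Occupancy multiplier of the start codon relative to
#'   the other sense codons (default 5), emulating ribosome stalling at
#'   initiation; offset training rests on this elevated start-codon depth.
#' @param noise_fraction Fraction of reads subjected to end trimming.
#' @param trim_range Trim sizes (nt), a subset of 1:5.
#' @param combine_noise If `TRUE`, trimmed copies are added to the original
#'   reads instead of replacing them.
#' @param n_uorf,n_dorf Number of coding genes additionally carrying a
#'   translated upstream/downstream ORF in their UTR.
#' @param codon_usage Usage table the translated sense codons are drawn
#'   from.
#' @param min_read_length Reads that trimming would take below this length
#'   are left untrimmed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_coding = 50L, n_noncoding = 50L,
                       n_te = 0L, n_pseudogene = 0L,
                       utr5_len = 60L, utr3_len = 60L,
                       cds_codons = c(60L, 120L),
                       intron_every = 3L, intron_len = 60L,
                       read_length_dist = c("28" = 1),
                       true_offset = 12L, frame_fidelity = 0.9,
                       reads_per_cds = 300L, start_pause = 5,
                       noise_fraction = 0,
                       trim_range = 1:5, combine_noise = FALSE,
                       n_uorf = 0L, n_dorf = 0L,
                       codon_usage = default_codon_usage(),
                       min_read_length = 15L) {
  stopifnot(abs(sum(read_length_dist) - 1) < 1e-9,
            noise_fraction >= 0, noise_fraction <= 1,
            all(trim_range %in% 1:5),
            frame_fidelity >= 0, frame_fidelity <= 1,
            cds_codons[1L] >= 10L, cds_codons[2L] >= cds_codons[1L])
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n sense codons drawn from a usage table (first codon forced to ATG)
.biased_cds <- function(n_codons, usage) {
  sense <- setdiff(names(usage), STOP_CODONS)
  p <- usage[sense] / sum(usage[sense])
  body <- sample(sense, n_codons - 1L, replace = TRUE, prob = p)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# untranslated ORF span: uniform (unbiased) sense codons
.uniform_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all64 <- sort(as.vector(outer(outer(bases, bases, paste0), bases, paste0)))
  sense <- setdiff(all64, STOP_CODONS)
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE),
          sample(STOP_CODONS, 1L)), collapse = "")
}

#' Simulate a reference genome, annotation and truth set
#'
#' Builds a toy genome on one chromosome: protein-coding genes (5' UTR, a
#' CDS of sense codons drawn from the configured skewed usage table, 3' UTR;
#' alternating strands; every k-th gene split by one intron) plus
#' untranslated non-coding / transposable-element / pseudogene transcripts
#' carrying an unbiased planted candidate ORF. The last in-frame triplet of
#' each coding 5' UTR is forced to a stop codon, the common situation that
#' bounds start-codon search upstream of the annotated start. Writes FASTA,
#' GTF and a truth TSV; deterministic under the configured seed.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return list with paths (`fasta`, `gtf`, `truth_file`), the `truth`
#'   data.frame (planted translated ORFs and their categories), the genome
#'   (`DNAStringSet`), the internal transcript `models`, and `cfg`.
#' @export
simulate_reference <- function(cfg, out_dir = tempfile("simref")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(cfg$seed, {
    chrom_parts <- character(0)
    gpos <- 0L                       # 0-based running chromosome length
    gtf <- character(0)
    truth <- list()
    models <- list()
    biotypes <- c(rep("protein_coding", cfg$n_coding),
                  rep("non_coding", cfg$n_noncoding),
                  rep("transposable_element", cfg$n_te),
                  rep("pseudogene", cfg$n_pseudogene))
    uorf_genes <- seq_len(min(cfg$n_uorf, cfg$n_coding))
    dorf_genes <- seq_len(min(cfg$n_dorf, cfg$n_coding))
    for (g in seq_along(biotypes)) {
      bt <- biotypes[g]
      gid <- sprintf("G%04d", g)
      tid <- sprintf("T%04d", g)
      strand <- if (g %% 2L == 0L) "-" else "+"
      planted <- list()
      if (bt == "protein_coding") {
        n_cod <- sample(cfg$cds_codons[1L]:cfg$cds_codons[2L], 1L)
        utr5 <- .rand_nt(cfg$utr5_len)
        # in-frame stop directly upstream of the annotated start
        if (cfg$utr5_len >= 3L) {
          substr(utr5, cfg$utr5_len - 2L, cfg$utr5_len) <- "TAA"
        }
        if (g %in% uorf_genes && cfg$utr5_len >= 60L) {
          # 12 sense codons + stop, placed deep enough that footprints
          # with the canonical offset still fit on the transcript
          usq <- .biased_cds(12L, cfg$codon_usage)
          substr(utr5, 14L, 13L + nchar(usq)) <- usq
          planted <- c(planted, list(list(start = 13L,
                                          stop = 13L + nchar(usq) - 3L,
                                          category = "uORF")))
        }
        cds <- .biased_cds(n_cod, cfg$codon_usage)
        utr3 <- .rand_nt(cfg$utr3_len)
        if (g %in% dorf_genes && cfg$utr3_len >= 60L) {
          dsq <- .biased_cds(12L, cfg$codon_usage)
          off <- cfg$utr5_len + nchar(cds)
          substr(utr3, 4L, 3L + nchar(dsq)) <- dsq
          planted <- c(planted, list(list(start = off + 3L,
                                          stop = off + 3L + nchar(dsq) - 3L,
                                          category = "dORF")))
        }
        tx_seq <- paste0(utr5, cds, utr3)
        cds_start <- cfg$utr5_len
        cds_end <- cfg$utr5_len + nchar(cds)        # stop included
        planted <- c(planted, list(list(start = cds_start,
                                        stop = cds_end - 3L,
                                        category = "annotated")))
      } else {
        # untranslated transcript with a planted unbiased candidate ORF
        n_cod <- sample(30L:50L, 1L)
        lead <- .rand_nt(cfg$utr5_len)
        orf <- .uniform_orf(n_cod)
        tail_ <- .rand_nt(cfg$utr3_len)
        tx_seq <- paste0(lead, orf, tail_)
        cds_start <- NA_integer_; cds_end <- NA_integer_
      }
      n <- nchar(tx_seq)
      # exon structure: one intron for every intron_every-th coding gene
      has_intron <- bt == "protein_coding" && cfg$intron_every > 0L &&
        g %% cfg$intron_every == 0L
      brk <- if (has_intron) as.integer(n %/% 2L) else n
      intron <- if (has_intron) {
        paste0("GT", .rand_nt(cfg$intron_len - 4L), "AG")
      } else ""
      sense_gene <- paste0(substr(tx_seq, 1L, brk), intron,
                           substr(tx_seq, brk + 1L, n))
      lg <- nchar(sense_gene)
      # sense-strand 0-based intervals of the exons within the gene segment
      ex_sense <- if (has_intron) {
        rbind(c(0L, brk), c(brk + nchar(intron), lg))
      } else rbind(c(0L, lg))
      if (strand == "+") {
        seg <- sense_gene
        ex_g <- cbind(gpos + ex_sense[, 1L] + 1L, gpos + ex_sense[, 2L])
      } else {
        seg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sense_gene)))
        ex_g <- cbind(gpos + lg - ex_sense[, 2L] + 1L,
                      gpos + lg - ex_sense[, 1L])
        ex_g <- ex_g[rev(seq_len(nrow(ex_g))), , drop = FALSE]
      }
      exons <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(ex_g[, 1L], ex_g[, 2L]), strand = strand)
      model <- list(transcript_id = tid, gene_id = gid, chrom = "chr1",
                    strand = strand, exons = exons, spliced_seq = tx_seq,
                    cds_start = cds_start, cds_end = cds_end, biotype = bt)
      class(model) <- "transcript_model"
      models[[tid]] <- model

      attr_str <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";', gid, tid, bt)
      feat <- function(type, s, e) {
        sprintf("chr1\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                type, s, e, strand, attr_str)
      }
      gtf <- c(gtf, feat("transcript", min(ex_g[, 1L]), max(ex_g[, 2L])))
      for (i in seq_len(nrow(ex_g))) {
        gtf <- c(gtf, feat("exon", ex_g[i, 1L], ex_g[i, 2L]))
      }
      if (!is.na(cds_start)) {
        # GTF convention: CDS features exclude the stop codon
        cds_blocks <- .tx_span_to_genome(model, cds_start, cds_end - 3L)
        for (i in seq_along(cds_blocks)) {
          gtf <- c(gtf, feat("CDS", GenomicRanges::start(cds_blocks)[i],
                             GenomicRanges::end(cds_blocks)[i]))
        }
      }
      for (pl in planted) {
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid,
          start_pos = pl$start, stop_pos = pl$stop,
          start_codon = substr(tx_seq, pl$start + 1L, pl$start + 3L),
          category = pl$category, stringsAsFactors = FALSE)
      }
      chrom_parts <- c(chrom_parts, seg, .rand_nt(100L))
      gpos <- gpos + lg + 100L
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chrom_parts, collapse = ""), "chr1"))
    fasta <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fasta)
    gtf_file <- file.path(out_dir, "annotation.gtf")
    writeLines(gtf, gtf_file)
    truth <- do.call(rbind, truth)
    truth_file <- file.path(out_dir, "truth.tsv")
    write.table(truth, truth_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(dir = out_dir, fasta = fasta, gtf = gtf_file,
         truth = truth, truth_file = truth_file,
         genome = genome, models = models, cfg = cfg)
  })
}

#' Trim read ends (noise injection)
#'
#' Randomly trims 1-5 nt from the 5' or 3' end of a configurable fraction of
#' reads, mimicking heterogeneous RNase digestion. A 5'-end trim of k nt
#' shifts the read's transcript 5' position by +k; a 3' trim only shortens
#' it. Reads that a trim would take below `min_read_length` are left
#' untrimmed and counted in attribute `n_skipped`.
#'
#' @param reads data.frame with `transcript_id`, `tx_pos`, `read_length`.
#' @param noise_fraction Fraction of reads selected for trimming.
#' @param trim_range Trim sizes to draw from (subset of 1:5).
#' @param combine If `TRUE`, the trimmed copies are appended to the original
#'   reads rather than replacing them.
#' @param ends Which end to trim: `"both"` (random), `"five_prime"`,
#'   `"three_prime"`.
#' @param min_read_length Minimum surviving read length.
#' @return data.frame of reads; attribute `n_trimmed` and `n_skipped`.
#' @export
inject_noise <- function(reads, noise_fraction, trim_range = 1:5,
                         combine = FALSE,
                         ends = c("both", "five_prime", "three_prime"),
                         min_read_length = 15L) {
  ends <- match.arg(ends)
  stopifnot(all(trim_range %in% 1:5), noise_fraction >= 0,
            noise_fraction <= 1)
  n <- nrow(reads)
  if (n == 0L || noise_fraction == 0) {
    return(structure(reads, n_trimmed = 0L, n_skipped = 0L))
  }
  sel <- which(runif(n) < noise_fraction)
  noisy <- reads[sel, , drop = FALSE]
  k <- if (length(trim_range) == 1L) {
    rep(trim_range, length(sel))
  } else sample(trim_range, length(sel), replace = TRUE)
  side <- switch(ends,
    both = sample(c("five_prime", "three_prime"), length(sel),
                  replace = TRUE),
    rep(ends, length(sel)))
  ok <- noisy$read_length - k >= min_read_length
  shift5 <- side == "five_prime" & ok
  noisy$tx_pos[shift5] <- noisy$tx_pos[shift5] + k[shift5]
  noisy$read_length[ok] <- noisy$read_length[ok] - k[ok]
  if (combine) {
    out <- rbind(reads, noisy[ok, , drop = FALSE])
  } else {
    out <- reads
    out[sel, ] <- noisy
  }
  structure(out, n_trimmed = sum(ok), n_skipped = sum(!ok))
}

#' Simulate aligned ribosome footprints
#'
#' Places footprints codon-by-codon along every planted translated ORF:
#' the P-site codon is drawn uniformly over the ORF's sense codons, the read
#' length from the configured distribution, and the 5' end sits exactly
#' `true_offset` nt upstream of the P-site for a `frame_fidelity` fraction of
#' reads (+/- 1-2 nt jitter otherwise). Optional end-trimming noise is
#' applied, and reads are written as spliced, coordinate-sorted, indexed BAM
#' alignments against the simulated genome (no aligner involved; positions
#' are exact by construction).
#'
#' @param reference Output of [simulate_reference()].
#' @param out_dir Where to write the BAM (default: the reference directory).
#' @return list with `bam` (path) and `reads` (the transcript-space read
#'   table after noise injection).
#' @export
simulate_rpfs <- function(reference, out_dir = reference$dir) {
  cfg <- reference$cfg
  models <- reference$models
  withr::with_seed(cfg$seed + 1L, {
    lens <- as.integer(names(cfg$read_length_dist))
    rows <- list()
    for (i in seq_len(nrow(reference$truth))) {
      tr <- reference$truth[i, ]
      m <- models[[tr$transcript_id]]
      n_cod <- (tr$stop_pos - tr$start_pos) %/% 3L
      n_reads <- cfg$reads_per_cds
      wts <- c(cfg$start_pause, rep(1, n_cod - 1L))
      codon <- sample.int(n_cod, n_reads, replace = TRUE,
                          prob = wts / sum(wts)) - 1L
      P <- tr$start_pos + 3L * codon
      L <- if (length(lens) == 1L) {
        rep(lens, n_reads)
      } else sample(lens, n_reads, replace = TRUE,
                    prob = cfg$read_length_dist)
      x <- P - cfg$true_offset
      jit <- runif(n_reads) >= cfg$frame_fidelity
      x[jit] <- x[jit] + sample(c(-2L, -1L, 1L, 2L), sum(jit),
                                replace = TRUE)
      keep <- x >= 0L & x + L <= nchar(m$spliced_seq)
      rows[[i]] <- data.frame(transcript_id = tr$transcript_id,
                              tx_pos = x[keep], read_length = L[keep],
                              stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, rows)
    reads <- inject_noise(reads, cfg$noise_fraction, cfg$trim_range,
                          combine = cfg$combine_noise,
                          min_read_length = cfg$min_read_length)
    bam <- write_rpf_bam(reads, models, reference$genome,
                         file.path(out_dir, "rpf"))
    list(bam = bam, reads = reads)
  })
}

#' Write transcript-space reads as an aligned, indexed BAM
#'
#' Maps each read's transcript interval through the exon structure to
#' genomic blocks (introducing `N` CIGAR gaps across introns) and writes a
#' coordinate-sorted, indexed BAM.
#'
#' @param reads data.frame with `transcript_id`, `tx_pos`, `read_length`.
#' @param models Named list of transcript models (simulated or assembled).
#' @param genome Named `DNAStringSet`.
#' @param prefix Output path prefix (the BAM becomes `<prefix>.bam`).
#' @return Path to the BAM file.
#' @export
write_rpf_bam <- function(reads, models, genome, prefix) {
  chrom_len <- Biostrings::width(genome)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), chrom_len))
  chrom_str <- lapply(as.character(genome), identity)
  recs <- vector("list", length(unique(reads$transcript_id)))
  ri <- 0L
  for (tid in unique(reads$transcript_id)) {
    m <- models[[tid]]
    # exon arrays in transcript order
    ex <- m$exons
    gs <- GenomicRanges::start(ex); ge <- GenomicRanges::end(ex)
    if (m$strand == "-") { o <- order(-gs); gs <- gs[o]; ge <- ge[o] }
    w <- ge - gs + 1L
    off <- cumsum(c(0L, w))[seq_along(w)]
    sel <- which(reads$transcript_id == tid)
    x <- reads$tx_pos[sel]; L <- reads$read_length[sel]
    pos <- integer(length(sel)); cig <- character(length(sel))
    seqf <- character(length(sel))
    for (j in seq_along(sel)) {
      s <- x[j]; e <- s + L[j]
      bs <- integer(0); be <- integer(0)
      for (i in seq_along(w)) {
        lo <- max(s, off[i]); hi <- min(e, off[i] + w[i])
        if (lo >= hi) next
        if (m$strand == "+") {
          bs <- c(bs, gs[i] + (lo - off[i]))
          be <- c(be, gs[i] + (hi - off[i]) - 1L)
        } else {
          bs <- c(bs, ge[i] - (hi - off[i]) + 1L)
          be <- c(be, ge[i] - (lo - off[i]))
        }
      }
      o <- order(bs); bs <- bs[o]; be <- be[o]
      bw <- be - bs + 1L
      cg <- paste0(bw[1L], "M")
      if (length(bw) > 1L) {
        for (q in 2:length(bw)) {
          cg <- paste0(cg, bs[q] - be[q - 1L] - 1L, "N", bw[q], "M")
        }
      }
      pos[j] <- bs[1L]
      cig[j] <- cg
      seqf[j] <- paste(substring(chrom_str[[m$chrom]], bs, be),
                       collapse = "")
    }
    flag <- if (m$strand == "+") 0L else 16L
    ri <- ri + 1L
    recs[[ri]] <- paste(sprintf("r%s_%06d", tid, seq_along(sel)), flag,
                        m$chrom, pos, 255L, cig, "*", 0L, 0L, seqf,
                        vapply(nchar(seqf), strrep, character(1L),
                               x = "I"),
                        "NH:i:1", sep = "\t")
  }
  sam <- paste0(prefix, ".sam")
  writeLines(c(header, unlist(recs[seq_len(ri)])), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
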