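#' Run the full ORF-calling workflow
#'
#' Executes the six-step workflow: (1) assemble transcripts, compute codon
#' usage and enumerate candidate ORFs; (2) build per-read-length metagene
#' profiles and screen lengths with the multitaper periodicity test; (3)
#' extract probabilistic P-site offsets; (4) measure the global frame
#' proportions, their entropy and the four evidence weights; (5) allocate
#' P-sites, run the four frame-comparison t-tests per candidate and combine
#' them with the weighted chi-square statistic under the stepwise search;
#' (6) classify the called ORFs.
#'
#' When no read length passes the periodicity screen the pipeline warns and
#' proceeds with all observed lengths retained and entropy forced to 1, so
#' the calls rest on codon usage alone.
#'
#' @param genome Path to the reference FASTA.
#' @param gtf Path to the annotation GTF.
#' @param bam Path to the coordinate-sorted, indexed RPF BAM.
#' @param start_codons Allowed start codons (default `"ATG"`; add near
#'   cognates `"CTG"`, `"GTG"`, `"TTG"` to search NUG starts).
#' @param alpha Combined p-value threshold (default 0.001).
#' @param fdr Benjamini-Hochberg threshold (default 1e-4).
#' @param min_mapq Minimum mapping quality (default 10).
#' @param nw,k Multitaper parameters (default NW = 3, K = 5).
#' @param periodicity_cutoff p-value cutoff of the periodicity screen
#'   (default 0.01).
#' @param min_length_nt Minimum candidate length including stop (default 9).
#' @param min_reads_for_offset Minimum start-overlapping reads per length
#'   before the offset falls back to the canonical 12 nt.
#' @param var_equal Equal-variance t-tests (default) or Welch.
#' @param out_dir If given, reports (periodicity, offsets, weights, ORF
#'   table, category summary, BED12) are written there.
#' @return list with `orfs` (called, classified ORF table), `periodicity`,
#'   `offsets`, `frame_props`, `entropy`, `weights`, `summary` (per-category
#'   counts) and `n_reads`.
#' @export
run_pipeline <- function(genome, gtf, bam, start_codons = "ATG",
                         alpha = 0.001, fdr = 1e-4, min_mapq = 10L,
                         nw = 3, k = 5, periodicity_cutoff = 0.01,
                         min_length_nt = 9L, min_reads_for_offset = 30L,
                         var_equal = TRUE, out_dir = NULL) {
  transcripts <- assemble_transcripts(genome, gtf)
  usage <- compute_codon_usage(transcripts)
  candidates <- enumerate_all_candidates(transcripts, start_codons,
                                         min_length_nt)
  meta_tx <- select_metagene_transcripts(transcripts)

  reads <- read_rpf_alignments(bam, transcripts, min_mapq)
  message(attr(reads, "n_reads"), " primary alignments loaded; ",
          attr(reads, "n_unannotated_chrom"),
          " on unannotated chromosomes")
  meta_reads <- reads[reads$transcript_id %in% names(meta_tx), , drop = FALSE]

  profiles <- build_metagene(meta_reads, meta_tx)
  periodicity <- screen_read_lengths(profiles, nw = nw, k = k,
                                     p_cutoff = periodicity_cutoff)
  retained <- periodicity$read_length[periodicity$passed]
  force_codon_only <- FALSE
  if (length(retained) == 0L) {
    warning("no read length passed the periodicity screen; ",
            "retaining all lengths with entropy forced to 1 ",
            "(codon usage drives the calls)")
    retained <- unique(meta_reads$read_length)
    force_codon_only <- TRUE
  }
  offsets <- extract_offsets(meta_reads, meta_tx, retained,
                             min_reads = min_reads_for_offset)
  retained_reads <- reads[reads$read_length %in% retained, , drop = FALSE]
  if (force_codon_only) {
    frame_props <- rep(1 / 3, 3)
  } else {
    frame_props <- measure_global_frame_props(meta_reads, meta_tx, offsets)
  }
  entropy <- frame_entropy(frame_props)
  weights <- compute_weights(entropy)
  message(sprintf(
    "frame proportions %.3f/%.3f/%.3f, entropy %.3f, RPF weight %.2f",
    frame_props[1], frame_props[2], frame_props[3], entropy, 1 - entropy))

  psites <- allocate_psites(retained_reads, transcripts, offsets)
  calls <- call_orfs(candidates, transcripts, psites, usage, weights,
                     alpha = alpha, fdr = fdr, var_equal = var_equal)
  calls <- classify_orfs(calls, transcripts)
  calls$gene_id <- vapply(calls$transcript_id, function(tid) {
    transcripts[[tid]]$gene_id
  }, character(1L))
  summary_tab <- table(factor(calls$category, levels = orf_categories()))

  res <- list(orfs = calls, periodicity = periodicity, offsets = offsets,
              frame_props = frame_props, entropy = entropy,
              weights = weights, summary = summary_tab,
              n_reads = attr(reads, "n_reads"),
              transcripts = transcripts, usage = usage)
  if (!is.null(out_dir)) write_run_reports(res, out_dir)
  res
}

#' Write the run reports of a pipeline result
#'
#' Emits `periodicity.tsv`, `offsets.tsv`, `weights.tsv`, `orfs.tsv`,
#' `category_summary.tsv`, `orfs.bed` and nucleotide/peptide FASTA files of
#' the called ORFs.
#'
#' @param res Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_run_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) {
    write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(res$periodicity, "periodicity.tsv")
  tsv(res$offsets, "offsets.tsv")
  tsv(data.frame(p0 = res$frame_props[1], p1 = res$frame_props[2],
                 p2 = res$frame_props[3], entropy = res$entropy,
                 w_rpf_01 = res$weights[1], w_rpf_02 = res$weights[2],
                 w_codon_01 = res$weights[3], w_codon_02 = res$weights[4]),
      "weights.tsv")
  tsv(res$orfs, "orfs.tsv")
  tsv(as.data.frame(res$summary), "category_summary.tsv")
  if (nrow(res$orfs) > 0L) {
    export_bed12(res$orfs, res$transcripts, file.path(out_dir, "orfs.bed"))
    nt <- vapply(seq_len(nrow(res$orfs)), function(i) {
      m <- res$transcripts[[res$orfs$transcript_id[i]]]
      substr(m$spliced_seq, res$orfs$start_pos[i] + 1L,
             res$orfs$stop_pos[i] + 3L)
    }, character(1L))
    ids <- paste0(res$orfs$transcript_id, ":", res$orfs$start_pos, "-",
                  res$orfs$stop_pos + 3L, ":", res$orfs$category)
    nt_set <- Biostrings::DNAStringSet(stats::setNames(nt, ids))
    Biostrings::writeXStringSet(nt_set, file.path(out_dir, "orfs_nt.fa"))
    aa <- Biostrings::translate(nt_set, if.fuzzy.codon = "solve")
    Biostrings::writeXStringSet(aa, file.path(out_dir, "orfs_aa.fa"))
  }
  invisible(out_dir)
}
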