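# shared fixtures; heavy simulation runs are memoized per session

.fixture_env <- new.env(parent = emptyenv())

# a transcript model built directly (single + strand exon spanning the seq)
make_tx <- function(seq, cds_start = NA_integer_, cds_end = NA_integer_,
                    biotype = "protein_coding", id = "T1", gene = "G1") {
  m <- list(
    transcript_id = id, gene_id = gene, chrom = "chr1", strand = "+",
    exons = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(1L, nchar(seq)), strand = "+"),
    spliced_seq = seq, cds_start = cds_start, cds_end = cds_end,
    biotype = biotype
  )
  class(m) <- "transcript_model"
  m
}

tx_list <- function(...) {
  ms <- list(...)
  stats::setNames(ms, vapply(ms, `[[`, character(1L), "transcript_id"))
}

# independent brute-force ORF scan: for every allowed start codon, walk
# codon-by-codon to the first in-frame stop
scan_orfs_oracle <- function(seq, starts, min_len = 9L) {
  n <- nchar(seq)
  out <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    if (!substr(seq, i, i + 2L) %in% starts) next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(seq, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        if (j + 2L - i + 1L >= min_len) {
          out[[length(out) + 1L]] <- c(start = i - 1L, stop = j - 1L)
        }
        break
      }
      j <- j + 3L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), stop = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# standard simulated dataset (pipeline run included), memoized
standard_run <- function(noise = 0) {
  key <- sprintf("run_noise%03d", round(noise * 100))
  if (!exists(key, envir = .fixture_env)) {
    cfg <- sim_config(noise_fraction = noise)
    ref <- simulate_reference(cfg, file.path(tempdir(), key))
    sim <- simulate_rpfs(ref)
    res <- suppressMessages(suppressWarnings(
      run_pipeline(ref$fasta, ref$gtf, sim$bam)))
    assign(key, list(ref = ref, sim = sim, res = res), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

orf_key <- function(d) paste(d$transcript_id, d$start_pos, d$stop_pos)

recovery_stats <- function(run) {
  truth <- run$ref$truth
  calls <- run$res$orfs
  list(
    recall = mean(orf_key(truth) %in% orf_key(calls)),
    n_false = sum(!(orf_key(calls) %in% orf_key(truth))),
    n_calls = nrow(calls)
  )
}
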