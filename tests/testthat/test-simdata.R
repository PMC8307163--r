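test_that("reference simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_coding = 10L, n_noncoding = 5L)
  r1 <- simulate_reference(cfg, tempfile("det1"))
  r2 <- simulate_reference(cfg, tempfile("det2"))
  expect_identical(readLines(r1$fasta), readLines(r2$fasta))
  expect_identical(readLines(r1$gtf), readLines(r2$gtf))
  expect_identical(r1$truth, r2$truth)
  s1 <- simulate_rpfs(r1)
  s2 <- simulate_rpfs(r2)
  expect_identical(s1$reads, s2$reads)
})

test_that("simulated annotation round-trips through the transcript assembler", {
  cfg <- sim_config(n_coding = 12L, n_noncoding = 4L, n_te = 2L,
                    n_pseudogene = 2L)
  ref <- simulate_reference(cfg, tempfile("rt"))
  tx <- assemble_transcripts(ref$fasta, ref$gtf)
  expect_length(tx, 20L)
  for (tid in names(ref$models)) {
    expect_equal(tx[[tid]]$spliced_seq, ref$models[[tid]]$spliced_seq,
                 label = tid)
    expect_equal(tx[[tid]]$cds_start, ref$models[[tid]]$cds_start)
    expect_equal(tx[[tid]]$cds_end, ref$models[[tid]]$cds_end)
  }
  expect_equal(sum(grepl("transposable", readLines(ref$gtf)) &
                     grepl("\ttranscript\t", readLines(ref$gtf))), 2L)
})

test_that("planted codon usage is recovered from the simulated genome", {
  cfg <- sim_config(n_coding = 120L, n_noncoding = 0L,
                    cds_codons = c(100L, 150L), intron_every = 4L)
  ref <- simulate_reference(cfg, tempfile("usage"))
  tx <- assemble_transcripts(ref$fasta, ref$gtf)
  u <- compute_codon_usage(tx)
  planted <- cfg$codon_usage
  n_codons <- sum(vapply(tx, function(m) {
    (m$cds_end - m$cds_start) / 3 - 1
  }, numeric(1)))
  expect_gt(n_codons, 10000)
  # first CDS codon is always ATG, so allow the forced-start excess on ATG
  dev <- abs(u - planted[names(u)])
  expect_lt(max(dev[names(dev) != "ATG"]), 0.01)
  expect_lt(dev[["ATG"]], 0.02)
})

test_that("noise injection trims the requested fraction from the chosen end", {
  reads <- data.frame(transcript_id = "T1", tx_pos = rep(50L, 100),
                      read_length = rep(28L, 100))
  same <- inject_noise(reads, 0)
  expect_identical(same$tx_pos, reads$tx_pos)
  # deterministic mode: every read trimmed 3 nt at the 5' end
  withr::with_seed(1, {
    all3 <- inject_noise(reads, 1, trim_range = 3L, ends = "five_prime")
  })
  expect_true(all(all3$tx_pos == 53L))
  expect_true(all(all3$read_length == 25L))
  # binomial bound on the trimmed count at fraction 0.5
  big <- data.frame(transcript_id = "T1", tx_pos = rep(50L, 10000),
                    read_length = rep(28L, 10000))
  withr::with_seed(2, half <- inject_noise(big, 0.5))
  n_tr <- attr(half, "n_trimmed")
  expect_gt(n_tr, 5000 - 2.58 * sqrt(10000 * 0.25))
  expect_lt(n_tr, 5000 + 2.58 * sqrt(10000 * 0.25))
  # combine mode appends the noisy copies
  withr::with_seed(3, comb <- inject_noise(big, 0.5, combine = TRUE))
  expect_equal(nrow(comb), 10000 + attr(comb, "n_trimmed"))
  # reads too short to trim are left alone
  short <- data.frame(transcript_id = "T1", tx_pos = 0L, read_length = 16L)
  withr::with_seed(4, res <- inject_noise(short, 1, trim_range = 5L))
  expect_equal(res$read_length, 16L)
  expect_equal(attr(res, "n_skipped"), 1L)
})

test_that("simulated footprints recover the planted offset through the BAM", {
  cfg <- sim_config(n_coding = 10L, n_noncoding = 0L, frame_fidelity = 1,
                    reads_per_cds = 200L)
  ref <- simulate_reference(cfg, tempfile("off"))
  sim <- simulate_rpfs(ref)
  tx <- assemble_transcripts(ref$fasta, ref$gtf)
  reads <- read_rpf_alignments(sim$bam, tx)
  expect_equal(attr(reads, "n_reads"), nrow(sim$reads))
  meta <- select_metagene_transcripts(tx)
  off <- extract_offsets(reads, meta, 28L)
  expect_equal(off$offset1, 12L)
  # BAM round trip preserves the transcript-space 5' ends
  got <- reads[order(reads$transcript_id, reads$tx_pos), ]
  want <- sim$reads[order(sim$reads$transcript_id, sim$reads$tx_pos), ]
  expect_equal(got$tx_pos, want$tx_pos)
  expect_equal(got$read_length, want$read_length)
})

test_that("uniform frame jitter drives the measured entropy towards 1", {
  cfg <- sim_config(n_coding = 10L, n_noncoding = 0L, frame_fidelity = 1 / 3,
                    reads_per_cds = 500L, start_pause = 1)
  ref <- simulate_reference(cfg, tempfile("jit"))
  sim <- simulate_rpfs(ref)
  off <- data.frame(read_length = 28L, offset1 = 12L, offset2 = 11L,
                    offset3 = 13L, prob1 = 1, prob2 = 0, prob3 = 0,
                    n_reads = 0L, fallback = FALSE)
  meta <- ref$models[vapply(ref$models, function(m) !is.na(m$cds_start),
                            logical(1))]
  fp <- measure_global_frame_props(sim$reads, meta, off)
  expect_gt(frame_entropy(fp), 0.95)
})
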