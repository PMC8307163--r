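write_toy_reference <- function(dir, minus = FALSE) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "g.fa")
  gtf <- file.path(dir, "a.gtf")
  # chr1: 60 nt; gene A: single exon 1-9 "ATGAAATAG"
  chr1 <- paste0("ATGAAATAG", strrep("C", 51))
  writeLines(c(">chr1", chr1), fa)
  attr1 <- 'gene_id "gA"; transcript_id "tA"; gene_biotype "protein_coding";'
  lines <- c(
    paste("chr1\ttoy\texon\t1\t9\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\ttoy\tCDS\t1\t6\t.\t+\t.", attr1, sep = "\t")
  )
  if (minus) {
    # gene B on minus strand, two exons 20-28 and 40-48
    attr2 <- 'gene_id "gB"; transcript_id "tB"; gene_biotype "protein_coding";'
    lines <- c(lines,
      paste("chr1\ttoy\texon\t20\t28\t.\t-\t.", attr2, sep = "\t"),
      paste("chr1\ttoy\texon\t40\t48\t.\t-\t.", attr2, sep = "\t"))
  }
  writeLines(lines, gtf)
  list(fa = fa, gtf = gtf, chr1 = chr1)
}

test_that("single-exon plus-strand transcript splices to the genomic sequence", {
  toy <- write_toy_reference(tempfile("toyp"))
  tx <- assemble_transcripts(toy$fa, toy$gtf)
  expect_named(tx, "tA")
  expect_equal(tx$tA$spliced_seq, "ATGAAATAG")
  # CDS 1-6 plus the following TAG stop is normalized into the span
  expect_equal(tx$tA$cds_start, 0L)
  expect_equal(tx$tA$cds_end, 9L)
})

test_that("minus-strand multi-exon transcript is the reverse complement of its exons", {
  toy <- write_toy_reference(tempfile("toym"), minus = TRUE)
  tx <- assemble_transcripts(toy$fa, toy$gtf)
  e1 <- substr(toy$chr1, 20, 28)
  e2 <- substr(toy$chr1, 40, 48)
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(e1, e2))))
  expect_equal(tx$tB$spliced_seq, expected)
  # round trip: genomic 5' end of the transcript maps to coordinate 0
  expect_equal(.genome_to_tx(tx$tB, 48L), 0L)
  expect_equal(.genome_to_tx(tx$tB, 40L), 8L)
  expect_equal(.genome_to_tx(tx$tB, 28L), 9L)
  expect_true(is.na(.genome_to_tx(tx$tB, 30L)))
})

test_that("annotation referencing an absent chromosome is a hard error", {
  toy <- write_toy_reference(tempfile("toyz"))
  bad <- file.path(dirname(toy$gtf), "bad.gtf")
  writeLines(c(readLines(toy$gtf),
               "chrZ\ttoy\texon\t1\t9\t.\t+\t.\tgene_id \"gZ\"; transcript_id \"tZ\";"),
             bad)
  expect_error(assemble_transcripts(toy$fa, bad), "chrZ")
})

test_that("codon usage counts in-frame sense codons, stop excluded", {
  t1 <- make_tx("ATGAAATAG", cds_start = 0L, cds_end = 9L)
  u <- compute_codon_usage(tx_list(t1))
  expect_equal(unname(u["ATG"]), 0.5)
  expect_equal(unname(u["AAA"]), 0.5)
  expect_equal(sum(u), 1)
  expect_equal(sum(u > 0), 2L)
  # duplicating a CDS does not change frequencies
  t2 <- make_tx("ATGAAATAG", cds_start = 0L, cds_end = 9L, id = "T2")
  expect_equal(compute_codon_usage(tx_list(t1, t2)), u)
})

test_that("codon usage matches a brute-force tally and is input-order invariant", {
  withr::with_seed(42, {
    seqs <- replicate(5, {
      n_cod <- sample(20:40, 1)
      paste(c("ATG", sample(setdiff(names(default_codon_usage()),
                                    c("TAA", "TAG", "TGA")),
                            n_cod, replace = TRUE), "TAA"), collapse = "")
    })
  })
  txs <- lapply(seq_along(seqs), function(i) {
    make_tx(seqs[i], cds_start = 0L, cds_end = nchar(seqs[i]),
            id = paste0("T", i))
  })
  txs <- stats::setNames(txs, vapply(txs, `[[`, character(1), "transcript_id"))
  u <- compute_codon_usage(txs)
  # oracle: count triplets by hand with substring + table
  trips <- unlist(lapply(seqs, function(s) {
    body <- substr(s, 1, nchar(s) - 3)
    substring(body, seq(1, nchar(body) - 2, 3), seq(3, nchar(body), 3))
  }))
  tab <- table(trips) / length(trips)
  expect_equal(unname(u[names(tab)]), unname(as.numeric(tab)))
  expect_equal(compute_codon_usage(rev(txs)), u)
})

test_that("a CDS that is not a multiple of 3 is trimmed with a warning", {
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  writeLines(c(">c", paste0("ATGAAAA", strrep("G", 20))), fa)
  a <- 'gene_id "g"; transcript_id "t";'
  writeLines(c(paste("c\ttoy\texon\t1\t27\t.\t+\t.", a, sep = "\t"),
               paste("c\ttoy\tCDS\t1\t7\t.\t+\t.", a, sep = "\t")), gtf)
  expect_warning(tx <- assemble_transcripts(fa, gtf), "multiple of 3")
  expect_equal((tx$t$cds_end - tx$t$cds_start) %% 3L, 0L)
})

test_that("candidate enumeration handles the minimal and nested cases", {
  t1 <- make_tx("ATGAAATAG")
  c1 <- enumerate_candidates(t1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$start_pos, 0L)
  expect_equal(c1$length_nt, 9L)   # stop codon included in the span
  # two in-frame starts sharing one stop
  t2 <- make_tx("ATGATGAAATAG", id = "T2")
  c2 <- enumerate_candidates(t2)
  expect_equal(nrow(c2), 2L)
  expect_equal(sort(c2$start_pos), c(0L, 3L))
  expect_equal(unique(c2$stop_pos), 9L)
})

test_that("enumeration agrees with an exhaustive scan oracle on random sequences", {
  starts <- c("ATG", "CTG", "GTG", "TTG")
  for (seed in 1:5) {
    withr::with_seed(seed, s <- random_seq(300))
    got <- enumerate_candidates(make_tx(s), start_codons = starts)
    want <- scan_orfs_oracle(s, starts)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$start_pos, got$stop_pos),
                    paste(want$start, want$stop))
    # every emitted candidate revalidates its own invariants
    for (i in seq_len(nrow(got))) {
      expect_true(substr(s, got$start_pos[i] + 1, got$start_pos[i] + 3)
                  %in% starts)
      expect_true(substr(s, got$stop_pos[i] + 1, got$stop_pos[i] + 3)
                  %in% c("TAA", "TAG", "TGA"))
      expect_equal((got$stop_pos[i] - got$start_pos[i]) %% 3L, 0L)
      inner <- seq(got$start_pos[i] + 3L, got$stop_pos[i] - 3L, by = 3L)
      if (got$stop_pos[i] - got$start_pos[i] > 3L) {
        inner_cod <- substring(s, inner + 1L, inner + 3L)
        expect_false(any(inner_cod %in% c("TAA", "TAG", "TGA")))
      }
    }
  }
})
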