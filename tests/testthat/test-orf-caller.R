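simple_offsets <- function(p = c(1, 0, 0), o = c(12L, 11L, 13L)) {
  data.frame(read_length = 28L, offset1 = o[1], offset2 = o[2],
             offset3 = o[3], prob1 = p[1], prob2 = p[2], prob3 = p[3],
             n_reads = 0L, fallback = FALSE)
}

test_that("P-site allocation follows the offset probabilities exactly", {
  t1 <- make_tx(strrep("A", 100), cds_start = 0L, cds_end = 99L)
  r1 <- data.frame(transcript_id = "T1", tx_pos = 0L, read_length = 28L)
  ps <- allocate_psites(r1, tx_list(t1), simple_offsets())
  expect_equal(ps$T1[13], 1)          # position 12, 0-based
  expect_equal(sum(ps$T1), 1)
  ps2 <- allocate_psites(r1, tx_list(t1),
                         simple_offsets(p = c(0.5, 0.25, 0.25)))
  expect_equal(ps2$T1[c(12, 13, 14)], c(0.25, 0.5, 0.25))
})

test_that("allocated P-site mass is conserved", {
  t1 <- make_tx(strrep("A", 500), cds_start = 0L, cds_end = 498L)
  withr::with_seed(2, pos <- sample(0:400, 1000, replace = TRUE))
  reads <- data.frame(transcript_id = "T1", tx_pos = pos, read_length = 28L)
  ps <- allocate_psites(reads, tx_list(t1),
                        simple_offsets(p = c(0.6, 0.25, 0.15)))
  expect_equal(sum(ps$T1), 1000, tolerance = 1e-6)
  expect_equal(attr(ps, "total_mass"), 1000, tolerance = 1e-6)
})

test_that("codon-usage vectors window the three frames of the candidate", {
  u <- default_codon_usage()
  v <- codon_test_vectors("ATGAAATAG", u)
  expect_equal(v$frame0, unname(u[c("ATG", "AAA")]))
  expect_equal(v$frame1, unname(u[c("TGA", "AAT")]))
  expect_equal(v$frame2, unname(u[c("GAA", "ATA")]))
})

test_that("codon-usage vectors agree with a sliding-window oracle", {
  withr::with_seed(8, {
    s <- paste(c("ATG", sample(setdiff(names(default_codon_usage()),
                                       c("TAA", "TAG", "TGA")), 28,
                               replace = TRUE), "TAA"), collapse = "")
  })
  u <- default_codon_usage()
  v <- codon_test_vectors(s, u)
  for (f in 0:2) {
    st <- seq(1 + f, nchar(s) - 2, by = 3)
    trips <- substring(s, st, st + 2)
    if (f == 0) trips <- trips[-length(trips)]
    expect_equal(v[[paste0("frame", f)]], unname(u[trips]))
  }
  # ambiguity codes disqualify a triplet
  s_n <- paste0("ATG", "ANA", substr(s, 7, nchar(s)))
  vn <- codon_test_vectors(s_n, u)
  expect_length(vn$frame0, length(v$frame0) - 1L)
})

test_that("RPF vectors are jointly Z-scored and flag absent evidence", {
  # uniform depth: no frame signal, p-values 1
  d <- rep(2, 60)
  rv <- rpf_test_vectors(d, 0L, 57L)
  expect_false(rv$no_evidence)
  expect_equal(rv$frame0, rep(0, 19))
  pv <- candidate_pvalues(paste(rep("ATGAAAAAAGCGCCATTT", 1), collapse = ""),
                          d, 0L, 15L, default_codon_usage())
  expect_equal(unname(pv["rpf_01"]), 1)
  # all mass on frame 0 dominates the other frames
  d2 <- rep(c(5, 0, 0), 20)
  rv2 <- rpf_test_vectors(d2, 0L, 57L)
  expect_true(all(rv2$frame0 > rv2$frame1))
  expect_true(all(rv2$frame0 > rv2$frame2))
  # joint Z-scoring: mean 0, sd 1 over all values
  expect_equal(mean(c(rv2$frame0, rv2$frame1, rv2$frame2)), 0)
  expect_equal(sd(c(rv2$frame0, rv2$frame1, rv2$frame2)), 1)
  # no coverage at all
  rv3 <- rpf_test_vectors(rep(0, 60), 0L, 57L)
  expect_true(rv3$no_evidence)
})

test_that("a planted periodic profile yields a decisive RPF t-test", {
  withr::with_seed(4, {
    d <- as.vector(rbind(5 + rpois(50, 2), rpois(50, 0.3), rpois(50, 0.3)))
  })
  rv <- rpf_test_vectors(d, 0L, 150L)
  p <- t.test(rv$frame0, rv$frame1, alternative = "greater",
              var.equal = TRUE)$p.value
  expect_lt(p, 1e-6)
})

test_that("the weighted combiner reproduces its analytic anchors", {
  # identical p-values: the four tests carry no extra information, k = 2
  ct <- combine_pvalues(rep(0.01, 4), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(ct$k, 2)
  # independent tests at equal weight: k = 8, Fisher's method
  withr::with_seed(6, {
    for (i in 1:25) {
      p <- runif(4)
      ct <- combine_pvalues(p, rep(0.25, 4))
      expect_equal(ct$k, 8)
      fisher <- pchisq(-2 * sum(log(p)), df = 8, lower.tail = FALSE)
      expect_lt(abs(ct$p_combined - fisher), 1e-9)
    }
  })
  # single-test degeneracy
  ct1 <- combine_pvalues(c(0.03, 0.5, 0.9, 0.2), c(1, 0, 0, 0))
  expect_equal(ct1$k, 2)
  expect_equal(ct1$p_combined, 0.03, tolerance = 1e-12)
  expect_error(combine_pvalues(rep(0.1, 4), rep(0.3, 4)), "sum to 1")
})

test_that("the combined p-value is monotone in each input p-value", {
  w <- c(0.28, 0.28, 0.22, 0.22)
  rho <- matrix(0.3, 4, 4); diag(rho) <- 1
  base <- c(0.01, 0.2, 0.05, 0.5)
  for (i in 1:4) {
    grid <- seq(0.001, 0.999, length.out = 30)
    pc <- vapply(grid, function(g) {
      p <- base; p[i] <- g
      combine_pvalues(p, w, rho)$p_combined
    }, numeric(1))
    expect_true(all(diff(pc) >= -1e-12))
  }
})

test_that("k stays within [2, 8] for arbitrary weights and correlations", {
  withr::with_seed(10, {
    for (i in 1:30) {
      w <- runif(4); w <- w / sum(w)
      r <- runif(6)
      rho <- diag(4)
      rho[lower.tri(rho)] <- r
      rho <- rho + t(rho) - diag(diag(rho))
      p <- runif(4)
      k <- combine_pvalues(p, w, rho)$k
      expect_gte(k, 2); expect_lte(k, 8)
    }
  })
})

test_that("stepwise search prefers long AUG candidates but falls through", {
  grp <- data.frame(
    start_codon = c("ATG", "ATG", "CTG"),
    length_nt = c(60L, 30L, 90L),
    p_rpf_01 = c(1e-8, 1e-9, 1e-9), p_rpf_02 = c(1e-8, 1e-9, 1e-9),
    p_codon_01 = c(1e-6, 1e-7, 1e-7), p_codon_02 = c(1e-6, 1e-7, 1e-7)
  )
  w <- rep(0.25, 4)
  # longest AUG passes: returned even though the CUG candidate is longer
  res <- stepwise_search(grp, w)
  expect_equal(res$hit, 1L)
  # longest fails, next AUG passes
  grp2 <- grp
  grp2[1, c("p_rpf_01", "p_rpf_02", "p_codon_01", "p_codon_02")] <- 0.5
  res2 <- stepwise_search(grp2, w)
  expect_equal(res2$hit, 2L)
  # all AUG candidates fail: the near-cognate candidate is reachable
  grp3 <- grp2
  grp3[2, c("p_rpf_01", "p_rpf_02", "p_codon_01", "p_codon_02")] <- 0.5
  res3 <- stepwise_search(grp3, w)
  expect_equal(res3$hit, 3L)
  # nothing passes
  grp4 <- grp3
  grp4[3, c("p_rpf_01", "p_rpf_02", "p_codon_01", "p_codon_02")] <- 0.5
  expect_true(is.na(stepwise_search(grp4, w)$hit))
})
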