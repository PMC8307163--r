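#' Probabilistic P-site allocation
#'
#' Distributes each read's unit mass over its three possible P-sites
#' according to the offset probabilities for its length: a read of length L
#' with 5' end at transcript position x adds `prob_j` at `x + offset_j`.
#' Mass falling outside the transcript is dropped (counted in the
#' `mass_dropped` attribute).
#'
#' @param reads Projected reads (from [read_rpf_alignments()]).
#' @param transcripts List of transcript models to build profiles for.
#' @param offset_table Offset table from [extract_offsets()].
#' @return Named list (by transcript) of numeric P-site depth vectors of the
#'   transcript length, with attributes `total_mass` and `mass_dropped`.
#' @export
allocate_psites <- function(reads, transcripts, offset_table) {
  long <- .offsets_long(offset_table)
  reads <- reads[reads$transcript_id %in% names(transcripts), , drop = FALSE]
  m <- merge(reads, long, by = "read_length")
  tx_len <- vapply(transcripts, function(t) nchar(t$spliced_seq), integer(1L))
  psite <- m$tx_pos + m$offset
  inside <- psite >= 0L & psite < tx_len[m$transcript_id] & m$prob > 0
  dropped <- sum(m$prob[!inside])
  m <- m[inside, , drop = FALSE]
  psite <- psite[inside]
  profiles <- lapply(names(transcripts), function(tid) numeric(tx_len[[tid]]))
  names(profiles) <- names(transcripts)
  if (nrow(m) > 0L) {
    agg <- rowsum(m$prob, group = paste(m$transcript_id, psite, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    tid <- vapply(key, `[[`, character(1L), 1L)
    pos <- as.integer(vapply(key, `[[`, character(1L), 2L))
    for (u in unique(tid)) {
      sel <- tid == u
      profiles[[u]][pos[sel] + 1L] <- agg[sel, 1L]
    }
  }
  structure(profiles, total_mass = sum(m$prob), mass_dropped = dropped)
}

#' Codon-usage vectors for the three frames of a candidate ORF
#'
#' Frame 0 holds the usage of the candidate's sense codons (terminal stop
#' excluded); frames 1 and 2 hold the usage of the +1/+2-shifted triplets
#' over the same nucleotide span, dropping triplets truncated at the span
#' edge or containing ambiguity codes.
#'
#' @param orf_seq Candidate nucleotide sequence including the stop codon.
#' @param usage Codon usage table from [compute_codon_usage()].
#' @return list of numeric vectors `frame0`, `frame1`, `frame2`.
#' @export
codon_test_vectors <- function(orf_seq, usage) {
  n <- nchar(orf_seq)
  stopifnot(n %% 3L == 0L, n >= 6L)
  out <- lapply(0:2, function(f) {
    st <- seq.int(1L + f, by = 3L, length.out = (n - f) %/% 3L)
    trips <- substring(orf_seq, st, st + 2L)
    if (f == 0L && trips[length(trips)] %in% STOP_CODONS) {
      trips <- trips[-length(trips)]
    }
    u <- usage[trips]
    as.numeric(u[!is.na(u)])
  })
  names(out) <- c("frame0", "frame1", "frame2")
  out
}

#' Z-scored per-codon P-site depth vectors for the three frames
#'
#' Sums P-site mass at positions congruent to 0/1/2 (mod 3) within each sense
#' codon of the candidate and jointly Z-scores all `3 * n_codon` values
#' (mean 0, sd 1) before splitting into the frame vectors. A candidate with
#' no P-site mass (or constant depth) yields all-zero vectors and is flagged.
#'
#' @param depth P-site depth vector of the host transcript.
#' @param start_pos,stop_pos 0-based transcript coordinates of the first base
#'   of the start and stop codons.
#' @return list with `frame0`, `frame1`, `frame2` and logical `no_evidence`.
#' @export
rpf_test_vectors <- function(depth, start_pos, stop_pos) {
  span <- depth[(start_pos + 1L):stop_pos]   # sense codons, stop excluded
  m <- matrix(span, ncol = 3L, byrow = TRUE)
  no_ev <- sum(span) == 0
  s <- sd(span)
  if (no_ev || s == 0) {
    z <- matrix(0, nrow(m), 3L)
  } else {
    z <- (m - mean(span)) / s
  }
  list(frame0 = z[, 1L], frame1 = z[, 2L], frame2 = z[, 3L],
       no_evidence = no_ev)
}

# one-sided two-sample t-test p(frame0 > other); degenerate data -> 1
.frame_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) return(1)
  p <- tryCatch(
    t.test(a, b, alternative = "greater", var.equal = var_equal)$p.value,
    error = function(e) 1
  )
  if (!is.finite(p)) 1 else p
}

#' Four frame-comparison p-values for one candidate ORF
#'
#' @param orf_seq Candidate sequence (with stop codon).
#' @param depth P-site depth vector of the host transcript.
#' @param start_pos,stop_pos Candidate coordinates (0-based, transcript).
#' @param usage Codon usage table.
#' @param var_equal Equal-variance t-tests (default) or Welch.
#' @return Named numeric vector `(rpf_01, rpf_02, codon_01, codon_02)`.
#' @export
candidate_pvalues <- function(orf_seq, depth, start_pos, stop_pos, usage,
                              var_equal = TRUE) {
  rv <- rpf_test_vectors(depth, start_pos, stop_pos)
  if (rv$no_evidence) {
    p_r01 <- 1; p_r02 <- 1
  } else {
    p_r01 <- .frame_ttest(rv$frame0, rv$frame1, var_equal)
    p_r02 <- .frame_ttest(rv$frame0, rv$frame2, var_equal)
  }
  cv <- codon_test_vectors(orf_seq, usage)
  p_c01 <- .frame_ttest(cv$frame0, cv$frame1, var_equal)
  p_c02 <- .frame_ttest(cv$frame0, cv$frame2, var_equal)
  c(rpf_01 = p_r01, rpf_02 = p_r02, codon_01 = p_c01, codon_02 = p_c02)
}

#' Weighted chi-square combination of four p-values
#'
#' Combines the four frame-comparison p-values as `M = -2 * sum(w_i log p_i)`
#' with `sum(w) = 1`. `M` is referred to a scaled chi-square `2 chisq_k / k`
#' whose effective degrees of freedom `k` are moment-matched from the weights
#' and the pairwise correlations of the tests:
#' `k = 2 / (sum(w^2) + sum_{i != j} w_i w_j rho_ij)`, clamped to \[2, 8\].
#' Identical p-values give `k = 2`; independent tests at equal weights give
#' `k = 8`, where the combination coincides with Fisher's method.
#'
#' @param p Four p-values.
#' @param w Four weights summing to 1.
#' @param rho 4x4 correlation matrix between the tests (default identity).
#' @return list with `M`, `k`, `p_combined` and the input `p`.
#' @export
combine_pvalues <- function(p, w, rho = diag(4)) {
  stopifnot(length(p) == 4L, length(w) == 4L, all(w >= 0),
            all(p >= 0), all(p <= 1))
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  pc <- pmin(pmax(p, 1e-300), 1)
  M <- -2 * sum(w * log(pc))
  if (max(p) - min(p) < 1e-12) {
    k <- 2
  } else {
    cross <- (w %o% w) * rho
    denom <- sum(cross) - sum(diag(cross)) + sum(w^2)
    k <- if (denom <= 0) 8 else 2 / denom
    k <- min(max(k, 2), 8)
  }
  list(p = p, M = M, k = k,
       p_combined = pchisq(k * M / 2, df = k, lower.tail = FALSE))
}

# empirical correlation of the -2 log p series across candidates,
# negatives and missing values floored at 0
.estimate_rho <- function(pmat) {
  if (nrow(pmat) < 3L) return(diag(4))
  x <- -2 * log(pmin(pmax(pmat, 1e-300), 1))
  rho <- suppressWarnings(cor(x))
  rho[!is.finite(rho)] <- 0
  rho[rho < 0] <- 0
  diag(rho) <- 1
  rho
}

#' Stepwise longest-candidate search within one stop-codon group
#'
#' Candidates sharing a (transcript, frame, stop codon) are evaluated
#' longest-first, with every AUG-start candidate taking priority over every
#' near-cognate-start candidate; the first candidate whose combined p-value
#' falls below `alpha` is returned.
#'
#' @param group data.frame of candidates of one group with columns
#'   `start_codon`, `length_nt` and the four p-value columns.
#' @param w Weights (see [compute_weights()]).
#' @param rho 4x4 test correlation matrix.
#' @param alpha Significance threshold (default 0.001).
#' @return list with `hit` (row index into `group` or `NA`), `test` (the
#'   [combine_pvalues()] result for the hit) and `best_p` (smallest combined
#'   p-value among evaluated candidates).
#' @export
stepwise_search <- function(group, w, rho = diag(4), alpha = 0.001) {
  ord <- order(group$start_codon != "ATG", -group$length_nt)
  best_p <- Inf
  for (i in ord) {
    ct <- combine_pvalues(
      c(group$p_rpf_01[i], group$p_rpf_02[i],
        group$p_codon_01[i], group$p_codon_02[i]), w, rho)
    best_p <- min(best_p, ct$p_combined)
    if (ct$p_combined < alpha) {
      return(list(hit = i, test = ct, best_p = best_p))
    }
  }
  list(hit = NA_integer_, test = NULL, best_p = best_p)
}

#' Call translated ORFs from candidates, P-site profiles and codon usage
#'
#' Runs the four frame-comparison t-tests for every candidate, estimates the
#' between-test correlations from the full candidate set (first pass),
#' combines p-values with the entropy-derived weights (second pass) under the
#' stepwise per-stop-codon search, and applies a Benjamini-Hochberg filter
#' over the per-group best p-values.
#'
#' @param candidates Candidate table from [enumerate_all_candidates()].
#' @param transcripts List of transcript models.
#' @param psites P-site profiles from [allocate_psites()].
#' @param usage Codon usage table.
#' @param weights Four weights from [compute_weights()].
#' @param alpha Per-ORF threshold on the combined p-value (default 0.001).
#' @param fdr Benjamini-Hochberg threshold (default 1e-4).
#' @param var_equal Equal-variance t-tests (default) or Welch.
#' @return data.frame of called ORFs with candidate columns, the four
#'   p-values, `M`, `k`, `p_combined` and `p_adj`; the estimated correlation
#'   matrix is attached as attribute `rho`.
#' @export
call_orfs <- function(candidates, transcripts, psites, usage, weights,
                      alpha = 0.001, fdr = 1e-4, var_equal = TRUE) {
  if (nrow(candidates) == 0L) return(.empty_calls())
  pm <- matrix(NA_real_, nrow(candidates), 4L,
               dimnames = list(NULL, c("p_rpf_01", "p_rpf_02",
                                       "p_codon_01", "p_codon_02")))
  for (i in seq_len(nrow(candidates))) {
    tid <- candidates$transcript_id[i]
    m <- transcripts[[tid]]
    seq_i <- substr(m$spliced_seq, candidates$start_pos[i] + 1L,
                    candidates$stop_pos[i] + 3L)
    pm[i, ] <- candidate_pvalues(seq_i, psites[[tid]],
                                 candidates$start_pos[i],
                                 candidates$stop_pos[i], usage, var_equal)
  }
  cand <- cbind(candidates, as.data.frame(pm))
  rho <- .estimate_rho(pm)
  grp <- paste(cand$transcript_id, cand$frame, cand$stop_pos, sep = "\r")
  hits <- list()
  group_best <- numeric(0)
  group_hit <- integer(0)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    res <- stepwise_search(cand[rows, , drop = FALSE], weights, rho, alpha)
    group_best <- c(group_best, res$best_p)
    if (!is.na(res$hit)) {
      row <- cand[rows[res$hit], , drop = FALSE]
      row$M <- res$test$M
      row$k <- res$test$k
      row$p_combined <- res$test$p_combined
      hits[[length(hits) + 1L]] <- row
      group_hit <- c(group_hit, length(group_best))
    }
  }
  if (length(hits) == 0L) return(structure(.empty_calls(), rho = rho))
  calls <- do.call(rbind, hits)
  padj_all <- p.adjust(group_best, method = "BH")
  calls$p_adj <- padj_all[group_hit]
  calls <- calls[calls$p_adj < fdr, , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, rho = rho)
}

.empty_calls <- function() {
  data.frame(transcript_id = character(0), start_pos = integer(0),
             stop_pos = integer(0), start_codon = character(0),
             frame = integer(0), length_nt = integer(0),
             p_rpf_01 = numeric(0), p_rpf_02 = numeric(0),
             p_codon_01 = numeric(0), p_codon_02 = numeric(0),
             M = numeric(0), k = numeric(0), p_combined = numeric(0),
             p_adj = numeric(0), stringsAsFactors = FALSE)
}
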