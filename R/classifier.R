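#' ORF categories
#'
#' The eleven categories a called ORF can receive, in precedence order:
#' biotype carve-outs first (`teORF` for transposable-element transcripts,
#' `pORF` for pseudogenes, `ncsORF` for non-coding transcripts or genes
#' without an annotated CDS), then positional labels relative to the
#' annotated CDS (`annotated`, `truncated`, `extended`, `ouORF`, `uORF`,
#' `odORF`, `dORF`, `internal`).
#'
#' @return Character vector of the 11 category names.
#' @export
orf_categories <- function() {
  c("annotated", "truncated", "extended", "uORF", "ouORF", "dORF", "odORF",
    "ncsORF", "internal", "teORF", "pORF")
}

.TE_BIOTYPES <- c("transposable_element", "transposon", "TE")

#' Classify one predicted ORF
#'
#' Assigns exactly one category from its transcript-coordinate span relative
#' to the annotated CDS (stop codon included in both spans) and the host
#' transcript's biotype. Classification never looks at p-values.
#'
#' Positional rules on a coding transcript: identical span is `annotated`;
#' sharing the annotated start or stop boundary is `truncated` (shorter) or
#' `extended` (longer); fully inside the 5' UTR is `uORF`, and `ouORF` when
#' the span reaches across the annotated start codon; the mirror cases in
#' the 3' UTR are `dORF` and `odORF`; anything else inside the CDS is
#' `internal`.
#'
#' @param start_pos,stop_pos Candidate coordinates (0-based transcript
#'   coordinates of the first base of the start and stop codons).
#' @param model Host transcript model.
#' @return One of [orf_categories()].
#' @export
classify_orf <- function(start_pos, stop_pos, model) {
  bt <- model$biotype
  if (!is.na(bt)) {
    if (bt %in% .TE_BIOTYPES) return("teORF")
    if (grepl("pseudogene", bt, ignore.case = TRUE)) return("pORF")
  }
  if (is.na(model$cds_start)) return("ncsORF")
  if (!is.na(bt) && !bt %in% c("protein_coding", "mRNA")) return("ncsORF")
  s <- start_pos
  e <- stop_pos + 3L                 # ORF span end, stop included
  cs <- model$cds_start
  ce <- model$cds_end                # CDS span end, stop included
  len <- e - s
  clen <- ce - cs
  if (s == cs && e == ce) return("annotated")
  if (s == cs || e == ce) {
    return(if (len < clen) "truncated" else "extended")
  }
  if (s < cs && e > cs) return("ouORF")
  if (e <= cs) return("uORF")
  if (s < ce && e > ce) return("odORF")
  if (s >= ce) return("dORF")
  "internal"
}

#' Classify a table of ORFs
#'
#' @param orfs data.frame with `transcript_id`, `start_pos`, `stop_pos`.
#' @param transcripts List of transcript models.
#' @return `orfs` with a `category` column added.
#' @export
classify_orfs <- function(orfs, transcripts) {
  orfs$category <- vapply(seq_len(nrow(orfs)), function(i) {
    classify_orf(orfs$start_pos[i], orfs$stop_pos[i],
                 transcripts[[orfs$transcript_id[i]]])
  }, character(1L))
  orfs
}
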