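---
title: "Noise-tolerant ORF calling from ribosome footprints: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-tolerant ORF calling from ribosome footprints: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocall)
```

## The problem

Ribosome profiling (Ribo-seq) sequences the ~28–34 nt mRNA fragments
protected by translating ribosomes (ribosome-protected footprints, RPFs).
Because ribosomes step codon by codon, the 5′ ends of high-quality
footprints recur every third nucleotide, and this triplet periodicity is
the main evidence most ORF predictors use to decide which reading frame of
a transcript is translated. Obtaining periodic footprints, however, demands
a highly optimized digestion protocol. Footprints from non-model organisms,
from membrane-bound polysomes, or from simplified library preparations are
frequently longer than the canonical 28 nt and only weakly periodic, and
frame-based callers degrade badly on them.

`ribocall` addresses this by treating footprint periodicity as one of two
exchangeable lines of evidence. For a candidate ORF it asks two questions:

* do P-sites pile up on frame 0 rather than frames 1 and 2? (footprint
  occupancy), and
* are the frame-0 triplets more plausible as codons than the shifted
  triplets, under the genome-wide codon usage of annotated CDSs? (sequence
  composition).

Each question is posed as two one-sided two-sample t-tests (frame 0 vs. 1,
frame 0 vs. 2), giving four p-values per candidate. How much each pair of
tests contributes is decided by the data themselves, through the entropy of
the observed frame distribution.

## Workflow

**1. Reference model.** The annotation (GTF) and genome (FASTA) are turned
into spliced transcript models; minus-strand transcripts are
reverse-complemented so everything downstream works in 5′→3′ transcript
coordinates (0-based, half-open; the GTF's 1-based inclusive coordinates
are converted on read). Genome-wide codon usage is tallied over all
annotated CDSs — every in-frame sense triplet counts, the terminal stop
codon does not, and triplets containing ambiguity codes are skipped.
Candidate ORFs are enumerated in all three frames of every transcript: for
each stop codon, every upstream in-frame start codon with no intervening
stop opens one candidate. The stop codon is part of the reported span but
never of the test vectors, since it is not a translated codon. Candidates
shorter than two sense codons (9 nt including the stop) are dropped — the
frame t-tests are degenerate below that. The default start set is `ATG`;
near-cognates (`CTG`, `GTG`, `TTG`) can be enabled.

**2. Periodicity screen.** For each read length, the raw 5′-end positions
of reads falling in the first 60 nt of annotated CDSs are accumulated into
a metagene profile (one transcript per gene, the longest coding isoform).
The profile is treated as a 60-point signal sampled at 1 Hz and tested with
Thomson's multitaper harmonic F-test; a length is retained when the p-value
at the Fourier bin at 1/3 Hz — the frequency of a 3-nt step pattern — is
below 0.01. The DPSS (Slepian) tapers are computed from the standard
symmetric tridiagonal eigenproblem, with time–bandwidth product NW = 3 and
K = 5 tapers, common practice for short series and exposed as parameters.
On a 60-point series the Fourier grid contains 1/3 exactly, so no
interpolation is involved. The F statistic is scale-invariant, so only the
shape of the profile matters, not sequencing depth.

**3. P-site offsets.** The distance from a footprint's 5′ end to the
P-site is trained on reads overlapping annotated start codons, where
initiating ribosomes stall and depth is locally elevated. Rather than a
single offset per read length, the three highest-depth distances (the mode,
plus the two strongest distances within ±3 nt of it) become a probabilistic
offset table; heterogeneous digestion then spreads a read's unit mass over
three plausible P-sites instead of forcing a hard, possibly wrong, choice.
Ties prefer the smaller distance. A read length with fewer than 30
start-overlapping reads falls back to the canonical 12-nt offset with
probability 1.

**4. Entropy weighting.** All retained reads are allocated to P-sites
through the offset table, and the proportions $p_0, p_1, p_2$ of P-site
mass on the three frames of annotated CDSs are measured globally. Their
entropy in base 3,

$$H = \sum_{i=0}^{2} -p_i \log_3 p_i \in [0, 1],$$

is 0 for perfectly periodic data and 1 for frame-uniform data
($0\log 0 = 0$). The four test weights are then
$w_\text{rpf} = (1-H)/2$ for each footprint test and $w_\text{codon} = H/2$
for each codon-usage test, so $\sum w_i = 1$. The even split within each
pair is our choice; nothing in the method suggests an asymmetry between
the 0-vs-1 and 0-vs-2 comparisons. Entropy is computed once per dataset:
it is a property of library quality, and computing it per ORF would let the
statistic confound itself.

**5. Combination and search.** Per candidate, P-site depth is summed per
codon position and frame, jointly Z-scored across the candidate span
(local scoring keeps the test focused on the hypothesis; a transcript-wide
scale would import unrelated coverage structure), and compared between
frames by equal-variance one-sided t-tests (Welch optional). Codon-usage
values are windowed the same way over the three frame offsets of the span.
The four p-values combine into

$$M = -2 \sum_{i=1}^{4} w_i \ln p_i,$$

which is referred to a scaled chi-square $2\chi^2_k/k$. The effective
degrees of freedom come from moment matching,
$k = 2 (\sum_i w_i)^2 / (\sum_i w_i^2 + \sum_{i\neq j} w_i w_j \rho_{ij})$,
clamped to $[2, 8]$: four identical tests give $k = 2$; four independent
tests at equal weight give $k = 8$, where the statistic reduces exactly to
Fisher's method (our tests verify agreement to below $10^{-9}$). The
pairwise correlations $\rho_{ij}$ are estimated empirically as Pearson
correlations of the $-2\ln p_i$ series over all candidates in a first pass
(negative estimates floored at 0) and applied in a second pass, which keeps
the procedure deterministic on fixed input. Candidates sharing a stop codon
are searched stepwise, longest first, with every `ATG` candidate ranked
before every near-cognate candidate; the first candidate with combined
$p < \alpha = 0.001$ is reported. A Benjamini–Hochberg pass over the
per-stop-group best p-values then keeps calls with adjusted $p < 10^{-4}$.
Both thresholds are exposed; their interaction (α filter first, BH second)
is our reading of the two stated cutoffs.

**6. Classification.** Each call receives exactly one of 11 categories.
Biotype carve-outs come first — `teORF` (transposable element), `pORF`
(pseudogene), `ncsORF` (non-coding transcript or no annotated CDS) — then
position against the annotated CDS: `annotated` (identical span),
`truncated`/`extended` (sharing the start or stop boundary, shorter/longer),
`uORF`/`ouORF` (inside the 5′ UTR / reaching across the annotated start),
`dORF`/`odORF` (the 3′-UTR mirror cases), and `internal` for anything else
inside the CDS. Sharing at least one annotated boundary is required for
`truncated`/`extended`; in-frame nested ORFs sharing neither boundary are
`internal`. Classification depends only on coordinates and biotype.

If no read length passes the periodicity screen, the pipeline warns,
retains all observed lengths and forces entropy to 1: calls then rest on
codon usage alone. At entropy 1 the output is provably independent of
footprint positions (the RPF tests carry zero weight, and the
moment-matching for $k$ involves only the codon pair), which our suite
checks by shuffling P-site profiles.

## The synthetic data generator

The generator exists so the whole pipeline can be exercised and its
parameter recovery quantified without external downloads. Its defaults
define the standard test conditions:

* 50 translated protein-coding genes (CDS 60–120 codons drawn from a fixed
  skewed codon table, 60-nt UTRs, alternating strands, every third gene
  split by one 60-nt intron) and 50 untranslated non-coding transcripts
  carrying an unbiased candidate ORF of 30–50 codons;
* 28-nt footprints, 300 per translated ORF, 5′ ends 12 nt upstream of the
  P-site; frame fidelity 0.9 (the remainder jittered ±1–2 nt);
* a 5× occupancy multiplier at the start codon, emulating the initiation
  stall that offset training rests on in real libraries;
* optional noise: a configurable fraction of reads trimmed by 1–5 nt from
  a random end (5′ trims shift the frame), either replacing the originals
  or appended to them.

The synthetic codon bias is geometric (ratio 0.93 over the alphabetically
ordered sense codons), spanning roughly 7% to 0.1% per codon — a spread
comparable to compact eukaryotic genomes. The last in-frame triplet of each
coding 5′ UTR is forced to a stop codon, the common real-genome situation
that bounds the upstream start search; without it, chance upstream in-frame
`ATG`s would make N-terminal extension calls a coin flip on synthetic
UTRs, which is a property of random sequence rather than of the method.
Reads are emitted as already-aligned, spliced, coordinate-sorted and
indexed BAM records computed exactly from the known genome; no aligner is
in the loop. All outputs are deterministic given the seed.

What the generator does **not** emulate: sequencing errors, untemplated
additions, multi-mapping, isoform complexity beyond one transcript per
gene, amplification duplicates, nucleotide-composition biases of real
genomes, and the long-tailed coverage of real expression. Passing tests on
this fixture therefore demonstrate internal correctness and the intended
statistical behavior, not field performance on real libraries.

## Numerical choices and edge cases

* p-values entering the combiner are clipped to $[10^{-300}, 1]$; identical
  p-values are detected at tolerance $10^{-12}$ and force $k = 2$.
* Z-scoring a zero-variance (or zero-coverage) span yields all-zero
  vectors; the candidate's footprint p-values are then 1 and codon usage
  decides — this is the mechanism behind tolerance of sparse coverage.
* An all-zero metagene profile gets p = 1 (not periodic). Degenerate
  t-tests (constant data) return p = 1.
* CDSs whose annotated length is not a multiple of 3 are trimmed at the 3′
  end with a warning; the stop codon is folded into the CDS span when it
  directly follows the annotated CDS.
* Offset ties prefer the smaller distance; missing offset slots are padded
  with zero-probability neighbours so the table always holds three
  distinct, non-negative offsets summing to probability 1.
* Reads whose P-site mass would fall outside the transcript lose that
  mass; the allocator reports it separately so conservation is checkable.

## Problem sizes used in the test suite

The suite runs the full pipeline on the standard fixture (100 transcripts,
~17,000 reads; under a minute on one CPU) twice — clean and at 50% trimming
noise — and verifies: recovery of at least 90% of the 50 planted ORFs with
at most 5% false calls; noise recovery within 10 points of the clean run;
recovery of the planted codon table within 0.01 per codon (~15,000 codons)
and of a planted offset mixture within 0.05 (10,000 reads); P-site mass
conservation to $10^{-6}$; and the analytic anchors of the entropy and the
combiner. DPSS tapers are checked against values computed independently
with SciPy.

## Known limitations

* The moment-matching estimator for $k$ reproduces the two printed anchor
  regimes ($k = 2$ identical, $k = 8$ independent) but intermediate
  behavior depends on the empirical correlation estimate; other estimators
  of the same family would give slightly different $k$.
* Codon-usage evidence is only as informative as the genome's bias; on
  genomes with weak codon bias the noise-tolerance margin shrinks.
* Short ORFs (≲ 10 codons) carry few values per frame vector, and their
  combined p-values sit near the FDR boundary; recall for such ORFs is
  inherently modest, consistent with the difficulty of sORF calling
  generally.
* One transcript per gene is used for metagene and entropy measurement
  (the longest coding isoform); genes whose footprints derive mostly from
  a shorter isoform are summarized imperfectly.
* No handling of stop-codon read-through, frameshifts, or selenocysteine.
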