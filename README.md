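# ribocall

Noise-tolerant prediction of translated open reading frames (ORFs) from
ribosome profiling (Ribo-seq) data.

## The problem

Ribo-seq sequences ribosome-protected footprints (RPFs), and the 3-nt
periodicity of footprint 5′ ends is the usual evidence that a reading
frame is translated. But periodic footprints require a highly optimized
protocol; libraries from non-model organisms, membrane-bound polysomes or
simplified preparations yield longer, weakly periodic footprints on which
frame-based callers fail. `ribocall` is for analysts working with exactly
such libraries: it measures how periodic the data actually are and
automatically re-balances the evidence between footprint occupancy and
codon usage, so calls degrade gracefully instead of collapsing as
periodicity is lost.

## Method in brief

For every candidate ORF (each in-frame start codon upstream of each stop
codon), four one-sided two-sample t-tests are run: P-site depth on frame 0
vs. frames 1 and 2, and codon usage of frame-0 triplets vs. the shifted
triplets. The four p-values are combined with a weighted chi-square
statistic

$$M = -2 \sum_{i=1}^{4} w_i \ln p_i, \qquad \sum_i w_i = 1,$$

referred to $2\chi^2_k/k$ with effective degrees of freedom
$k \in [2, 8]$ moment-matched from the weights and the empirical
between-test correlations ($k = 8$ with equal weights and independent
tests reduces exactly to Fisher's method; $k = 2$ when the four tests are
identical). The weights come from the entropy (base 3) of the global
P-site frame distribution, $H = \sum_i -p_i \log_3 p_i$: footprint tests
carry weight $(1-H)/2$ each, codon-usage tests $H/2$ each — periodic data
drive the calls, noisy data hand the evidence to sequence composition.
Read lengths are screened beforehand with a multitaper (DPSS) harmonic
F-test at 1/3 Hz on start-codon metagene profiles, and P-site offsets per
read length are probabilistic (top three distances from read 5′ ends to
annotated start codons). Calls use a stepwise longest-first search per
stop codon with AUG priority, $\alpha = 0.001$, and a Benjamini–Hochberg
filter at $10^{-4}$. Each call is classified into one of 11 categories
(annotated, truncated, extended, uORF, ouORF, dORF, odORF, ncsORF,
internal, teORF, pORF).

A synthetic-data module generates a toy genome, GTF, and aligned,
indexed footprint BAMs — including an end-trimming noise protocol — so the
entire pipeline is testable at desk scale.

## Worked example

```r
library(ribocall)

cfg <- sim_config(seed = 1)                     # 50 coding + 50 non-coding genes
ref <- simulate_reference(cfg, "demo")          # writes FASTA, GTF, truth TSV
sim <- simulate_rpfs(ref)                       # writes sorted, indexed BAM
res <- run_pipeline(ref$fasta, ref$gtf, sim$bam, out_dir = "demo/out")

res$periodicity
#>   read_length n_reads      p_value passed
#> 1          28    3460 7.602854e-10   TRUE
res$offsets[, 1:7]
#>   read_length offset1 offset2 offset3     prob1    prob2      prob3
#> 1          28      12       9      11 0.7985075 0.173774 0.02771855
round(c(res$frame_props, entropy = res$entropy), 3)
#>                         entropy
#> 0.878   0.048   0.074    0.412
res$weights
#>    rpf_01    rpf_02  codon_01  codon_02
#> 0.2942085 0.2942085 0.2057915 0.2057915
head(res$orfs[, c("transcript_id", "start_pos", "stop_pos", "category", "M", "k", "p_combined")], 3)
#>   transcript_id start_pos stop_pos  category         M        k   p_combined
#> 1         T0001        60      408 annotated 123.88844 2.162137 1.212435e-29
#> 2         T0002        60      330 annotated 109.39838 2.162137 3.026233e-26
#> 3         T0003        60      345 annotated  89.58343 2.162137 1.335287e-21
```

Reading this output: the single simulated read length (28 nt) shows strong
periodicity (F-test p ≈ 8e-10 at 1/3 Hz) and trains the canonical 12-nt
P-site offset with probability 0.80. With 87.8% of P-site mass on frame 0
the entropy is 0.41, so footprint tests carry weight 0.29 each and
codon-usage tests 0.21 each. All 50 planted ORFs are recovered as
`annotated` (the `summary` element tabulates categories), with no false
calls on the 50 untranslated transcripts. On real data the same
`run_pipeline(genome.fa, annotation.gtf, footprints.bam)` call applies;
`out_dir` receives the periodicity report, offset table, weights, the ORF
table (four p-values, M, k, combined and BH-adjusted p per call), BED12
and nucleotide/peptide FASTA. A thin command-line front end is installed
under `exec/`:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","ribocall",package="ribocall"))') \
  call --genome ref.fa --gtf ann.gtf --bam rpf.bam --out out/
```

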