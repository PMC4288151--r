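# oriterscan

Coverage-based detection of large segmental duplications on circular
bacterial chromosomes, and analysis of origin/terminus gene-expression
domains.

## The problem

During laboratory evolution, bacteria sometimes adapt by duplicating a
multi-megabase chromosomal segment rather than by point mutation. In a
population of genomic DNA molecules in which a tandem duplication of an
origin-centred segment is present at prevalence *f*, short-read sequencing
coverage of that segment is elevated by the factor 1 + *f* relative to the
rest of the chromosome, with sharp boundaries at the repeat elements (e.g.
identical IS2 copies) that mediate the duplication by unequal recombination.
`oriterscan` implements the computations needed to detect, localize and
quantify such an event from read depth, to propagate the gene-dosage effect
correctly into differential expression, and to relate expression changes to
chromosome architecture:

- **Mode normalization** of per-bin coverage (default 200-nt bins): counts
  are scaled so the modal coverage level maps to log2 = 0, which is robust
  when a large fraction of the chromosome has altered copy number.
- **The Rc statistic**: the ratio of mean linear-scale coverage of the
  origin-centred segment to that of the rest of the chromosome. Under a
  duplication at prevalence *f*, E\[Rc\] = 1 + *f*; under a deletion of the
  complementary segment at prevalence *q*, E\[Rc\] = 1/(1 − *q*).
- **Breakpoint detection** by minimum within-segment sum of squares over
  circular two-segmentations, exhaustively over user-supplied candidate
  boundaries (repeat-element positions) or by a fast two-stage scan.
- **Scenario weighing**: with *k* of *n* sampled clones displaying the
  coverage pattern, Binomial(*n*, *p*) likelihoods compare the duplication
  and deletion explanations of an observed population Rc.
- **Dosage-aware differential expression**: per-sample size factors from the
  histogram mode of per-gene counts restricted to the *non-amplified* part
  of the genome, followed by an exact conditional binomial test with the
  fixed calling rule |log2FC| ≥ 1 and P ≤ 1e-5.
- **Positional gene-set enrichment**: permutation test (gene labels shuffled
  over fixed gene locations) for over-representation of a gene set in
  sliding circular windows at several window sizes.
- **Expression domains**: pairwise Pearson correlations across a
  multi-condition expression compendium, classification at PCC ≥ 0.5 /
  ≤ −0.5, 100-kb bin-pair count matrices, and extraction of the two-domain
  partition (origin-centred vs terminus-centred) that maximizes
  cross-domain anti-correlation plus within-domain correlation.

A synthetic-data module (`simulate_population_coverage()`,
`simulate_de_counts()`, `simulate_compendium()`) generates every input with
planted ground truth, so the whole pipeline is testable end to end.

## Worked example

Simulate a clone in which 80% of genomic DNA molecules carry a 2-Mb
origin-centred duplication of a 4.6-Mb chromosome, then recover the event:

```r
library(oriterscan)

chrom <- preset_chromosome("full")      # 4.6-Mb circular chromosome
seg   <- preset_dup_segment(chrom)      # 2-Mb origin-centred segment

trk  <- simulate_population_coverage(chrom, seg, prevalence = 0.8,
                                     mean_depth = 250, seed = 42)
norm <- mode_normalize(trk)
bp   <- detect_breakpoints(norm)
bp
#> <rc_result> Rc = 1.7949; segment [0, 2e+06); mean in/out = 1.8237 / 1.0160
glance(bp)
#> # A tibble: 1 × 7
#>      rc boundary_1 boundary_2 mean_in mean_out  n_in n_out
#>   <dbl>      <dbl>      <dbl>   <dbl>    <dbl> <int> <int>
#> 1  1.79          0    2000000    1.82     1.02 10000 13000

infer_prevalence(bp$Rc, "duplication")
#> [1] 0.7948972
```

The scan recovers the planted boundaries (positions 0 and 2,000,000)
exactly and an Rc of 1.79, i.e. an estimated duplication prevalence of
~0.79 for a planted 0.80. Weighing duplication against deletion for 3
pattern-positive clones among 16 sampled, at prevalences 25% vs 7%:

```r
scenario_likelihood_ratio(16, 3, p_dup = 0.25, p_del = 0.07)
#> <scenario_lr> k = 3 of n = 16 clones; P(dup, p=0.25) = 0.2079; P(del, p=0.07) = 0.07478; ratio = 2.780
```

The duplication scenario is about three times more likely.

## Documentation

The methods vignette (`vignettes/oriterscan-methods.Rmd`) describes the
models, the tunable parameters and their defaults, what the synthetic data
do and do not emulate, and the numerical choices (histogram-mode estimation,
pseudocounts, tie-breaking, minimum segment length).
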