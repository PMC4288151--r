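---
title: "Models and methods behind oriterscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oriterscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriterscan)
```

`oriterscan` analyses read-depth evidence for large segmental duplications
on circular bacterial chromosomes and the transcriptional consequences of
such events. This vignette is the package's account of the underlying
models, the parameters that matter, and the numerical and design choices
made where more than one reasonable option existed.

## Coordinate conventions

All internal coordinates are 0-based, half-open `[start, end)`, on a single
circular replicon. GFF3 input (1-based, inclusive) is converted on read;
BED and bedGraph are already 0-based half-open. A `genomic_segment` with
`start >= end` wraps through the coordinate origin. Gene position, wherever
a single point is needed (bin assignment, window membership, domain
assignment), is the midpoint `floor((start + end)/2)` — symmetric in the
gene limits and independent of strand, which no computation in the package
uses. The terminal bin of a tiling that does not divide the replicon length
evenly is kept (so the tiling is an exact partition) but flagged partial
and excluded from every statistic, so it can neither drag the mode nor bias
segment means.

## Coverage model and mode normalization

Coverage is the number of reads whose first mapped base falls in each
non-overlapping bin (200 nt by default — fine enough to localize breakpoints
to a few hundred bp, coarse enough that per-bin counts at typical depths
are in the hundreds). The population model treats each genomic DNA molecule
as carrying the duplication with probability $f$; since a tandem
duplication doubles the copy number of the segment on a carrier molecule,
the expected relative coverage of the segment is $1 + f$, and per-bin
counts are modelled as independent Poisson draws around
$\mathrm{depth}\cdot(1+f)$ inside the segment and $\mathrm{depth}$ outside.
For a deletion at prevalence $q$ the deleted segment drops to
$\mathrm{depth}\cdot(1-q)$. Per-bin Poisson counts are the sufficient
statistics of uniform read sampling for everything downstream, which is why
the generator emits bins rather than reads (a read-start mode,
`simulate_read_starts()`, exists to exercise the binning code).

Normalization divides by the **mode** of the per-bin count distribution
rather than its mean or median: when ~40% of the chromosome is amplified,
the mean is pulled up and even the median can sit inside the amplified mass,
but the most common coverage level still identifies the single-copy state.
The mode is estimated from a fixed-width histogram of $\log_2(c+1)$ with
cell width 0.1, taking the midpoint of the fullest cell (ties go to the
lower cell, a deterministic choice) and back-transforming. Consequences to
be aware of:

- the estimate is quantized: anything derived from a *single* mode factor
  is reproducible only up to half a cell (~3.5% on the linear scale);
- the $+1$ pseudocount makes $\log_2$ defined at zero counts; at depth 250
  it biases ratios by under 0.5%;
- the Rc statistic is a ratio of means of the *same* normalized track, so
  the mode factor cancels and Rc is insensitive to the quantization — the
  tests assert scale invariance of Rc to within 2%.

`mode_normalize(track, restrict_to = segment)` estimates the mode from a
subset of bins while normalizing all of them; this is how normalization
against only the non-amplified portion of a genome is expressed.

## Rc, breakpoints and pattern classification

`compute_rc()` takes arithmetic means on the linear (de-logged) scale —
"average coverage" — inside and outside the origin segment and reports
their ratio. `infer_prevalence()` inverts the forward model exactly
($f = Rc - 1$, $q = 1 - 1/Rc$) and clips to $[0,1]$; an Rc below 1 raises
an error rather than silently reinterpreting the complementary segment as
amplified, because that situation usually means the caller's segment
orientation is flipped.

`detect_breakpoints()` estimates the two boundaries as the circular
two-segmentation minimizing the total within-segment sum of squared
$\log_2$ values — the standard least-squares change-point criterion, on the
scale on which multiplicative noise is approximately homoscedastic. Two
search modes:

- **candidate mode**: all ordered pairs of user-supplied boundary
  coordinates (typically repeat-element positions) are scored exhaustively;
- **scan mode**: a coarse pass over every 10th bin boundary followed by a
  stride-1 refinement within ±20 bins of the coarse optimum. A full-scale
  23,000-bin track scans in a few seconds; tracks of ≤ 5,000 bins use the
  exact stride-1 search directly.

Scan mode enforces a minimum segment length (default 5% of the bins).
Without it, the least-squares optimum of a *structureless* track isolates
the single most extreme bin, producing a spurious segment with Rc ≈ 1.2–1.3
from pure Poisson noise; with the floor, structureless tracks yield Rc
within a few percent of 1, while any variant large enough to be of interest
here (a multi-megabase duplication) is far above the floor. Ties are broken
deterministically toward the smallest first boundary, then the shortest
segment. The reported `ori_segment` is always the higher-coverage side, so
Rc ≥ 1 by construction.

`classify_pattern()` calls a track pattern-positive at Rc ≥ 1.5
(inclusive). The threshold corresponds to the low end of the Rc range
observed in clones carrying such duplications (Rc 1.5–1.8, i.e. 60–80%
of molecules); it is a documented, adjustable choice, not a fitted value.

## Scenario likelihoods

An observed population Rc of ~1.2 is explained by a duplication at
prevalence ~25% or, under the calibration used in the worked examples, a
deletion at 7%. Given $k$ pattern-positive clones among $n$
sampled, each scenario's probability is the Binomial($n$, $p$) mass at $k$,
and `scenario_likelihood_ratio()` reports their ratio; at $n=16$, $k=3$,
$p_{dup}=0.25$, $p_{del}=0.07$ the ratio is 2.78 — the duplication scenario
about three times as likely. Note that under this package's own deletion
model ($Rc = 1/(1-q)$), the prevalence explaining Rc = 1.2 would be
$q \approx 0.17$, not 7%; the 7% figure is accepted verbatim as a
calibration input to the likelihood ratio rather than rederived, and the
discrepancy is surfaced here rather than hidden. No prior over scenarios is
applied (a Bayesian treatment is a non-goal).

## Dosage-aware differential expression

Reads are counted per gene by the position of their first mapped base
(half-open gene intervals; on overlapping annotations the gene earliest by
coordinate takes precedence; unassigned reads are reported). Per-sample
normalization factors are the histogram mode (same estimator and cell width
as for coverage) of per-gene counts across only the genes whose midpoint
lies **outside** the amplified segment. Restricting the mode keeps the
factors anchored to the single-copy transcriptional state: a 1.8× dosage
over 40% of the genome then shifts neither the factors of the amplified
strain nor those of the strains compared against it, and the tests verify
that unchanged, non-amplified genes come out at median |log2FC| ≤ 0.1.
For use inside fold changes, the raw mode factors are rescaled by their
geometric mean across samples, making them dimensionless and centred at 1
like conventional size factors; this keeps the 0.5 pseudocount in

$$\log_2 FC = \log_2\frac{x_A/S_A + 0.5}{x_B/S_B + 0.5}$$

a mild regularizer rather than a distortion (the raw mode is on the scale
of a typical gene's count, hundreds, and dividing by it would compress all
normalized counts toward the pseudocount).

Significance uses the two-sided exact binomial test of the pooled count
$x_A$ out of $x_A + x_B$ against $p_0 = S_A/(S_A+S_B)$ — the exact
conditional test under Poisson sampling. This is a deliberate substitution
for empirical-Bayes dispersion modelling (edgeR/limma-style fits are an
explicit non-goal): it makes the bespoke parts — the restricted-mode
factors and the fixed 2-fold / P ≤ 1e-5 calling rule, with no
multiple-testing correction — fully specified and testable end to end. The
cost is anticonservativeness under overdispersion: with negative-binomial
noise the exact test's P-values are too small. The generator's
`dispersion = "nb"` preset exists to demonstrate exactly that, and callers
with overdispersed replicates should treat the P-values as descriptive
ranks, not error rates.

## Positional enrichment

Windows of several sizes (default 100, 200, 400, 800 kb; step = half the
window) slide circularly over the chromosome; each window's observed count
of set-G genes (by midpoint) is compared with counts under `n_perm`
permutations of the gene-label-to-location assignment — locations fixed,
labels shuffled, so gene density along the chromosome is preserved
exactly. The permutation P-value uses the add-one convention
$P = (1 + \#\{null \ge obs\})/(1 + N)$, bounded away from zero, and a
window is significant at $P < \alpha$ (default 0.01) with no cross-window
correction by default (a Benjamini–Hochberg column is optional). With
count-valued statistics the test is conservative when windows hold few
genes — ties between null and observed counts inflate P — so sparse
annotations lose power before they lose validity; at realistic bacterial
gene density (~0.9 genes/kb) the empirical type-I rate sits near the
nominal 0.01, as the test suite measures.

## Expression domains

Each gene's expression vector across the compendium's conditions
(~300 in the emulated setting) is correlated with every other gene's
(Pearson, computed in blocks so no dense gene × gene matrix is ever held);
pairs at PCC ≥ 0.5 are classified correlated, ≤ −0.5 anti-correlated, both
thresholds inclusive. Constant genes have no defined correlation and their
pairs are excluded and reported. Counts of classified pairs are accumulated
into symmetric 100-kb bin-pair matrices C and A (within-bin pairs on the
diagonal), and the two-domain structure is extracted by exhaustive search
over all circular two-partitions of the bin ring, maximizing

$$\sum_{\text{cross-domain pairs}} A_{ij} \; + \sum_{\text{within-domain pairs}} C_{ij},$$

ties toward the smallest boundary indices. The scored two-partition is this
package's formalization of reading the two blocks off the bin-pair
heatmaps; it is validated only on synthetic compendia with planted domains,
where it recovers boundaries within ±1 bin at loading $a = 3$,
noise SD 1, 300 conditions.

The compendium generator plants exactly one latent factor:
$y_{gc} = \mu_g + s_g\,a\,z_c + \varepsilon_{gc}$ with $s_g = \pm 1$ by
domain. Cross-domain pairs then have population correlation
$-a^2/(a^2+\sigma^2)$ (−0.9 at the defaults), and a null compendium
($a=0$) classifies fewer than 0.1% of pairs at 300 conditions. Real
compendia differ in ways the generator deliberately ignores: correlated
regulon structure unrelated to position, condition clusters (replicates,
time courses) that break exchangeability, and multiple overlapping spatial
scales. Passing the planted-truth tests therefore shows the estimator
recovers a dominant two-domain signal when one exists, not that every
bacterial compendium contains one.

## Synthetic presets and problem sizes

The full-scale preset is a 4.6-Mb circular chromosome (23,000 bins of
200 nt, 46 bins of 100 kb) with the origin at 1.0 Mb, terminus at 3.3 Mb
and a 2-Mb duplication segment `[0, 2e6)` centred on the origin — the
geometry of the motivating experimental system, with read depth 250 per
bin. The desk-scale preset is the same geometry at 10% size (460 kb, 2,300
bins), used by most unit tests for speed. Test problem sizes — 20 seeded
replicates for breakpoint recovery at prevalence 0.5 and depth 100, 2,000
null genes for the false-positive check, 50 random gene sets of 400 among
4,000 genes for the enrichment type-I rate, 300–400 genes for compendium
checks — were chosen once as the smallest sizes at which the relevant
binomial/Poisson confidence intervals are decisive.

## Known limitations

- The Poisson coverage model has no replication-origin gradient (multifork
  replication), GC bias or mappability structure; Rc on real exponential-
  phase data should be computed against a matched parent rather than a
  flat expectation when such gradients are strong.
- The deletion scenario models coverage loss only; it does not attempt to
  reproduce whatever more detailed simulation produced the 7% calibration
  (see the scenario-likelihood section).
- The exact binomial DE test is anticonservative under overdispersion, by
  design and documented above.
- Breakpoint resolution is one bin (200 nt by default); sub-bin breakpoints
  and repeat-internal structure are out of scope.
- Single replicon only; plasmids or secondary chromosomes need separate
  runs.
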