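---
title: "Conditional fitness profiling from Tn-seq: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional fitness profiling from Tn-seq: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofit)
```

## The problem

A Himar1 mariner transposon library disrupts (nearly) every nonessential
gene of a bacterial genome, one insert per clone, inserting exclusively at
TA dinucleotides. Passaging the pooled library for ~20–25 generations with
and without a selective stressor, and sequencing the insertion junctions
before and after outgrowth, turns changes in each insert's read frequency
into an estimate of the fitness cost (or benefit) of disrupting the gene
that carries it. Comparing arms (± stressor) identifies *conditionally*
important genes; comparing strains (wild type vs a mutant that cannot
metabolize the stressor) separates genes needed during degradation of the
compound from genes needed merely in its presence. A companion RNA-seq arm
asks how much of the transcriptional stress response is actually useful,
by checking whether expression changes line up with fitness importance.

`cofit` implements this full analysis as composable functions plus a
synthetic-data generator with known ground truth, so every statistical
property of the pipeline can be validated end to end.

## The fitness model

For one insert, let $N_0$ and $N_f$ be its relative read frequencies at
the start and end of the outgrowth and $d$ the fold-expansion of the whole
population. The per-insert fitness is the serial-passage,
expansion-corrected statistic

$$
W \;=\; \frac{\ln\!\big(N_f\, d / N_0\big)}{\ln\!\big((1-N_f)\, d / (1-N_0)\big)},
$$

on a scale where a neutral disruption has $W = 1$ (its frequency is
unchanged), $W < 1$ is detrimental and $W > 1$ beneficial. The numerator
is the log absolute growth of the insert; the denominator the log growth
of everything else. The exact algebraic form of the statistic used by the
original MaGenTa-style Tn-seq analyses is adopted here as the standard
choice consistent with the neutral-equals-one scale; it is an assumption
of this package, documented as such.

The generator uses the *same* growth law in reverse: an insert in a gene
with true fitness $W$ multiplies by $2^W$ per generation, so after $G$
generations its abundance is scaled by $2^{WG}$ and a fully neutral
population expands by $d = 2^G$. With sequencing noise disabled the
estimator inverts the simulation exactly (to machine precision, which the
test suite asserts at $10^{-9}$); this closed-form consistency is the
package's primary correctness anchor.

Two practical rules:

* **Extinct inserts.** An insert with zero reads after outgrowth is not
  dropped — dropping extinct inserts censors exactly the strongest
  fitness defects and biases detrimental genes toward neutral. Its final
  frequency is floored at $0.5/\text{(library total)}$ and the value is
  flagged `floored`.
* **Expansion factor.** $d$ defaults to $2^G$; when the simulator reports
  the realized expansion of a library, that value is used. With real data
  the measured culture expansion should be supplied.

## Gene level: aggregation and the five-way classification

Per-insert $W$ values are computed within each replicate library and
pooled, unweighted, into one per-gene sample; the gene's fitness is the
arithmetic mean. Pooling per-insert values (rather than averaging per
replicate first) preserves the sample size that the downstream t tests
rely on; replicate agreement is monitored separately by `replicate_qc()`
(Pearson correlation of gene-level means between replicate pairs).

Classification uses the observed insert count and the gene length:

| category     | rule                                                  |
|--------------|-------------------------------------------------------|
| detrimental  | mean $W < 0.95$ (with $\geq 4$ inserts)                |
| beneficial   | mean $W > 1.05$ (with $\geq 4$ inserts)                |
| neutral      | $0.95 \le$ mean $W \le 1.05$                           |
| lethal       | $< 4$ inserts in a gene $> 400$ bp                     |
| insufficient | $< 4$ inserts in a gene $\le 400$ bp                   |

Boundary values (exactly 0.95 or 1.05) are neutral: the outer classes are
defined by strict inequalities. A long gene that the library failed to hit
at least four times is apparently lethal to disrupt; for short genes the
same sparsity is uninformative, since a short gene offers few TA sites to
begin with. A gene of exactly 400 bp falls in the short-gene
(insufficient) branch. Insert-to-gene assignment uses the literal gene
body by default (`edge_trim = 0`); a trim fraction can exclude insertions
near gene ends, where disruption sometimes fails to abolish function.

## Conditional and strain comparisons

`compare_arms()` tests, per gene, the per-insert $W$ samples of the two
arms with a Welch two-sample t test and calls significance only when both
gates pass: $|\Delta W| > 0.05$ *and* $p$ below the Bonferroni-corrected
level $\alpha/m$, with $m$ the number of genes actually testable (at least
two inserts in each arm) in this run — the correction adapts to the data
set rather than hard-coding any particular genome's gene count. The
per-insert t-test unit is a documented assumption: inserts are the only
sampling unit that yields p values of the magnitude these designs produce.
When both samples are constant and equal, the degenerate t statistic is
defined as $p = 1$ (no evidence of a difference). Genes failing the
two-insert precondition are reported descriptively, flagged `untestable`,
and never significant — lethal genes are handled by the classification,
not the t test.

A gene is *conditionally detrimental* when it is significant with
$\Delta W < 0$ (selective arm minus reference) and classified neutral in
the reference arm, so that the effect is attributable to the condition
and not to the disruption per se; conditionally beneficial genes are the
mirror image.

`compare_strains()` removes each strain's background disruption cost by
subtracting the no-selection arm within strain, t-tests the two strains'
under-selection samples against each other, and flags a gene as
*degradation-dependent detrimental* when its disruption is
significant-detrimental in the wild type's own arm comparison but not in
the mutant's — the signature of genes that matter only while the stressor
is actually being metabolized.

## The transcriptomics arm

Genes below 1 count-per-million in fewer samples than the smallest group
are filtered. The differential-expression test is a deliberately
self-contained negative-binomial Wald test: median-of-ratios library-size
normalization; log2 fold change from normalized group means with a
pseudocount of 0.5; per-gene dispersion by the method of moments, floored
at $10^{-8}$ and *moderated* by shrinking toward the genome-wide median
with 10 prior degrees of freedom; and a normal Wald test of the log-mean
difference with delta-method variance $(1/\mu + \alpha)/n$ summed over
groups. The moderation is essential at triplicate scale: the raw
per-gene moment estimate is so variable at $n = 3$ that an unmoderated
Wald test is visibly miscalibrated, while widening the reference
distribution instead (a t with 4 degrees of freedom) makes small
adjusted p values unreachable and destroys power. Shrinkage toward a
common value is the standard resolution in this field. The test makes no
claim of numerical equivalence to any specific DE package; the
downstream statistics only need well-calibrated $(p, \log_2\text{FC}, q)$,
which the null-simulation tests verify (Kolmogorov–Smirnov distance of
null p values from uniform below 0.05).

Significance gates are strict, matching the conventional ">2-fold at
FDR < 0.01" phrasing: $|\log_2\text{FC}| > 1$ and BH $q < 0.01$.

Cross-stressor overlap is summarized two ways. The Spearman rank
correlation of log2 fold changes is computed over the **union** of genes
significant at FDR < 0.01 in either contrast (no fold gate): the union
retains more information than the intersection and is the documented
choice where the convention is ambiguous. The *shared fraction* is the
percentage of one stressor's fully gated (fold + FDR) genes that pass the
same gate in the other stressor with the same sign — "shared" is not a
standardized quantity, so this operationalization is stated rather than
assumed comparable to any particular published percentage. Ties in
Spearman use average ranks, the standard convention for count-derived
data.

Concordance labels combine the two arms: a gene whose disruption is
significantly detrimental under the stressor and which is significantly
upregulated responds *appropriately*; significant downregulation of such
a gene is *counterproductive*; genes with significantly beneficial
disruption are mirrored; everything else is unclassified.

## What the generator emulates — and what it does not

`generate_genome()` lays out non-overlapping genes (lognormal lengths,
median ~800 bp with a tail below 400 bp to exercise the short-gene rule)
separated by intergenic spacers (15% of the genome by default) on an
i.i.d. random sequence at 64% GC. Each gene draws a fitness class from a
mixture — 75% neutral ($W = 1$ exactly), 10% detrimental
($W \in [0.6, 0.9]$), 5% beneficial ($W \in [1.1, 1.2]$), 10% essential
(zero viable inserts) — with exact (largest-remainder) class counts.
`simulate_library()` hits 87% of the TA sites outside essential genes,
gives inserts symmetric-Dirichlet abundance weights, and draws t0 reads
as one multinomial at the configured depth (500,000 reads by default,
about 20 reads per insert — a deliberately scaled-down stand-in for
multi-million-read libraries that preserves per-insert coverage within
an order of magnitude). Outgrowth applies the growth law above for 22
generations by default (configurable; optionally drawn uniformly from
[20, 25]) and re-sequences multinomially; optional Gamma overdispersion
stands in for bottleneck and jackpot effects, which are otherwise not
modeled because real passaging schedules are rarely reported. In
two-arm experiments each arm draws its own t0 sequencing sample from the
shared library composition — sharing a single t0 draw would correlate
the arms' measurement noise and distort the t test's calibration.

Two realism notes. First, beneficial effect sizes are kept mild and rare
by design: relative fitness is measured against the rest of the
population, and a simulated library in which several genes gain large
benefits over 20+ generations is taken over by those inserts, dragging
every other gene's apparent $W$ below 1 — real beneficial disruptions
are few and modest, which is exactly why the neutral-equals-one scale
works. Second, an i.i.d. sequence at genomic GC overestimates the TA
density of real coding sequence (codon structure depletes TA), so the
simulated insert density per bp is somewhat higher than in a real
genome at the same GC; the quantity that drives statistical behavior,
inserts per gene, is matched or exceeded.

The RNA-seq generator draws lognormal baselines, NB counts at dispersion
0.05, and triplicate samples per condition. Each condition's true
log2 fold-change vector is
$\sqrt{\rho}\,\text{shared} + \sqrt{1-\rho}\,\text{private}$ over a
common mask of stress-responsive genes (25% of genes by default), making
the expected correlation between two conditions' true responses equal to
$\rho$ — a construction, not a mechanistic model of co-regulation. What
passing tests on these data show is that the *pipeline's statistics are
calibrated and recover known structure*; they do not show that any
specific biological data set satisfies the generators' assumptions
(independent genes, common dispersion, no batch effects, no
PCR/positional bias).

## Numerical and reproducibility choices

* All randomness flows from one top-level seed through documented
  per-stage substreams, so identical (config, seed) reproduces every
  output file byte for byte and adding a stage never shifts another
  stage's draws.
* Internal arithmetic on coordinates is 0-based half-open only where
  convenient; every external interface (GFF3, site tables, reports) is
  1-based inclusive, and round-trip tests pin boundary genes at position
  1 and at the sequence end.
* TA sites are identified by the 1-based position of the T; TA is its own
  reverse complement, so one strandless coordinate suffices.
* Problem sizes used by the validation suite: 1,000-gene genomes at
  500,000 reads/library for recovery (20 runs); 200-gene all-neutral
  genomes for t-test calibration (20 runs, ~4,000 tests); 40-gene
  two-strain designs for the degradation-dependence pattern (100 runs);
  2,000-gene expression matrices for DE calibration and overlap (10 and
  20 runs). These sizes give the binomial/KS margins the assertions
  need while keeping a full validation run around a minute.

## Known limitations

* The fitness statistic's exact historical form is an assumption (see
  above); any re-analysis against published per-gene values should
  confirm the formula variant first.
* Per-insert t tests treat inserts within a gene as independent samples;
  polar effects on operons and local insertion biases violate this in
  real data.
* The DE test is a calibrated stand-in, not a re-implementation of any
  specific published tool; exact per-gene p values will differ from
  edgeR/DESeq2-style analyses even on identical counts.
* Genes overlapping on opposite strands are assigned jointly (with a
  warning); the fitness of a shared insert conflates the two genes.
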