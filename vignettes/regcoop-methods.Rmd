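---
title: "regcoop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regcoop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcoop)
```

# The scientific problem

Tumor genomes recurrently amplify chromosomal regions, and genes inside
those regions whose expression tracks their copy number are candidate
causal drivers. When such a driver is a transcription factor, its
action is shaped by partner factors that co-occupy chromatin, by the
direct target program the pair regulates, and — on the inherited side —
by risk variants that fall inside the factors' binding sites and
modulate nearby gene expression. `regcoop` implements this whole chain
as composable, individually tested operations, and ships a
synthetic-cohort generator so that every stage can be validated against
planted truth without access to any patient-level dataset.

# Models and statistics

## Driver prioritization

Copy-number calls are integer codes (−2 deep loss … +2 amplification).
For gene $g$ the amplification frequency is the fraction of samples
with code $\ge 1$ (gain and amplification pooled; $\ge 2$ available).
The copy-number/expression association is the Pearson product-moment
correlation between the numeric code and expression, restricted to
codes $\{0,1,2\}$. Losses are excluded by default because the
association of interest is dosage gain driving expression; deletions
follow different (often region-level) dynamics and would distort the
linearity assumption. Two-sided p-values use
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Candidacy requires frequency
$\ge$ 5%, $r > 0$, and Benjamini–Hochberg FDR $< 0.05$ computed over
*all* genes with a defined correlation — filtering before FDR would
bias the multiplicity correction. No significance rule was inherited
for the correlation, so BH at 0.05 is this package's documented
default, configurable. Candidates are ranked ascending by essentiality
score (loss-of-function screens report lower = more essential); ties
break lexicographically so ranks are reproducible.

## Co-occupancy

Two factors' peak sets are merged internally, then a region is
*common* iff it overlaps $\ge 1$ bp of the other set. One base pair is
the default because no minimum-overlap fraction is part of the method
definition; a configurable minimum and a summit-distance mode exist
for sensitivity analysis. Fractions are directional
($n_\text{common}/n$ per set). The differential-peak filter keeps
$p < 10^{-4}$ and fold change $> 4$, both strict — a peak exactly at a
threshold is dropped.

## Joint direct targets and signature scoring

A gene is a joint direct target iff (i) it passes FDR $< 0.1$ in
*both* knockdown DE tables with the same response direction, and
(ii) at least one peak of *each* factor overlaps its promoter window
TSS ± 5 kb (strand-symmetric, clipped at position 0). The two factors'
peaks need not overlap each other. Direction concordance is the
default reading of "common dysregulated genes"; plain intersection is
available because the definition is ambiguous.

Signature scores are
$s_j = \sum_g w_g z_{gj}$ with $z_{gj}$ the per-gene z-score across
the supplied matrix (so normalization is always within-cohort). The
joint-target weights are $\pm 1$ by mean knockdown response direction
— direction-aware but magnitude-free, since no weight magnitudes are
defined anywhere; orientation flips so the score tracks factor
*activity* (a gene down upon knockdown is factor-activated, weight
+1). Zero-variance and absent panel genes are skipped with a warning;
an empty effective panel scores 0 and is flagged rather than erroring,
so cohort-level loops degrade gracefully.

## Germline risk layer

LD is the squared Pearson correlation of allele dosages
(composite LD) — it needs no phasing, and precomputed LD tables can be
supplied instead. Proxy expansion is inclusive at $r^2 \ge 0.5$ within
1 Mb of each tag; tags are their own proxies.

SNP-in-binding-site enrichment uses a permutation design: observed =
risk SNPs inside a region category; null = counts of equally sized
draws without replacement from a user-supplied background pool;
fold = observed/mean(null);
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$.
No enrichment statistic was inherited; permutation against an explicit
pool is distribution-free and honest about SNP ascertainment. The +1
convention keeps $p \ge 1/(1+n_\text{perm})$ and makes the test valid
(conservative under ties) — see the calibration note below.

Allele-affinity deltas score a position probability matrix as
$\sum_i \log_2(p_i(b_i)/q(b_i))$ over every placement covering the
SNP, on both strands, separately for the two allele-substituted
sequences; the delta is risk-minus-other, so positive = risk allele
preferred. Allelic imbalance is the exact two-sided binomial test
against 0.5 (sum of point probabilities $\le$ the observed one). qPCR
quantities invert the standard curve,
$Q = 10^{(C_t - \text{intercept})/\text{slope}}$, normalized to the
loading control's quantity from the same curve; amplification
efficiency is implicit in the fitted slope.

## Survival

Kaplan–Meier, log-rank and single-covariate Cox regression delegate to
the `survival` package (Breslow ties by default, Efron available);
the package's own contribution is the stratification layer and its tie
rules: median splits send exact median ties to "low" (deterministic,
no random assignment); copy-number splits compare gain/amplification
(code $\ge 1$) to diploid, setting losses to `NA`; the
genotype-within-stratum scheme median-splits the gene first (after the
optional deep-loss exclusion, which always precedes any median
computation) and compares homozygous-risk TT against TC/CC within one
stratum, TT-vs-CC mode available; Gleason subgroups are ≤6 / 7 / ≥8.
Complete separation in Cox is flagged as non-convergent rather than
reported as a huge finite HR.

# The synthetic world

The generator defaults *are* the validation regimes: 200 samples ×
2000 genes with 20 planted drivers (target $r = 0.4$, amplification
frequency 0.10); 10,000 vs 7,321 peaks with planted co-occupancy
fraction 0.655; 50 joint targets among 5,000 genes with DE-only,
bound-only and single-factor-bound decoys; LD blocks of 10 SNPs with a
per-haplotype flip noise of 0.027 (targeting within-block
$r^2 \approx 0.8$; 0 gives exactly 1); risk SNPs at 3× background
density inside common regions; allelic ratio 0.7 at depth 500;
exponential survival with HR 2 and 30% censoring. Where no value was
stated anywhere, the choice was made once and documented here:
expression noise sd 1 (log2-scale units), baseline hazard 0.02 per
month (median survival ~3 years in the low-risk group), genotypes in
Hardy–Weinberg proportions at risk-allele frequency 0.4, decoy counts
100/100/200.

Mechanics worth knowing:

- Peaks are placed one per 2-kb slot of a 3 × 10 Mb toy genome, so
  emitted sets are non-overlapping by construction and the planted
  co-occupancy fraction is recovered essentially exactly — the
  recovery tests validate the classifier, not placement noise.
- The knockdown generator sizes its own toy genome from the gene count
  (spacing $2\cdot\text{flank} + 2$ kb), because 5,000 non-colliding
  10-kb promoter windows need ~60 Mb and the 3 × 10 Mb default genome
  is kept for the peak and germline layers.
- The cohort's driver expression is `baseline + β·code + noise` with
  β solved analytically from the target correlation and the code
  distribution's variance, so the planted effect size is exact in
  expectation rather than tuned.
- One master seed fans out to named substreams
  (`cohort`, `peaks`, `knockdown`, `germline`), so adding a generator
  never perturbs another's draws, and every generator is a pure
  function of its config.

What a green test does **not** establish: real cohorts have
segment-level (not per-gene independent) copy number, LD maps with
long-range structure, peak-width and signal biases, confounded
clinical covariates, and batch effects — none of which are emulated.
Green means the *operations* are correct on data satisfying their
stated models.

# Numerical choices and edge cases

- Coordinates are 0-based half-open everywhere; VCF input positions
  are converted on read. Point membership is
  $\text{start} \le \text{pos} < \text{end}$.
- Zero-variance vectors make correlations undefined: flagged `NA` and
  excluded from candidacy, never silently 0.
- A zero margin in a 2×2 association yields $p = 1$ and an undefined
  OR; a single zero cell applies the Haldane 0.5 correction to the
  sample OR (the exact p is unaffected).
- The empirical permutation p is discrete and, under ties,
  conservative. A uniformity check against it therefore needs enough
  count granularity: the acceptance calibration uses a 40,000-SNP pool
  with 2,000-SNP draws (~150 expected in-region, tie mass ~3%). With
  small pools (200 of 4,000, ~15 expected) the same correctly
  implemented statistic fails a KS uniformity test purely through
  discreteness — a property of the check's resolution, not of the
  method.
- Cox iterations run to $|\Delta\ell| < 10^{-10}$ (cap 50); estimates
  with $|\hat\beta| > 15$ or non-finite variance are flagged
  non-convergent (monotone likelihood).

# Known limitations

Region-level amplification calling, haplotype-phased LD, eQTL database
querying, DE model fitting and peak calling are out of scope by
design: the package consumes calls, DE tables and peaks. Multivariable
Cox models and competing risks are not implemented; reported HRs are
single-stratification. The permutation enrichment inherits whatever
ascertainment bias the supplied background pool carries.
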