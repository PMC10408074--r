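# regcoop

An R toolkit for integrative regulatory cancer genomics: it links
somatic copy-number amplification, gene expression, CRISPR-screen
essentiality, two transcription factors' chromatin occupancy, paired
knockdown transcriptomics, inherited risk variants and clinical
survival into one tested analysis pipeline, exercisable end to end on
synthetic cohorts with planted ground truth.

## Who it is for

Computational biologists asking questions of the form: *which amplified
genes are plausibly causal drivers in this tumor cohort? do two
transcription factors co-occupy chromatin and co-regulate a direct
target program? do GWAS risk variants concentrate in their binding
sites, and which genes do those variants regulate? does any of this
stratify patient outcome?* Each question is one module; the modules
compose.

## What it computes

- **Interval engine** (`peak_set`, `read_bed`, `merge_intervals`,
  `intersect_intervals`, `promoter_windows`,
  `assign_points_to_peaks`) — 0-based half-open (BED) coordinates
  throughout; overlap = at least 1 bp unless configured otherwise.
- **Driver prioritization** — per-gene amplification frequency from
  GISTIC-style codes (−2…+2); Pearson correlation *r* between
  copy-number code (restricted to {0, 1, 2}) and expression with a
  t-distributed two-sided p on n − 2 df; candidates require frequency
  ≥ 5%, *r* > 0 and Benjamini–Hochberg FDR < 0.05 over the tested gene
  universe; candidates rank ascending by essentiality score (lower =
  more essential; rank 1 = strongest dependency).
- **Co-occupancy** — merged-peak classification into common/unique
  regions for two factors with per-direction fractions
  (n_common/n), plus the standard differential-peak filter
  (p < 10⁻⁴ and fold change > 4, both strict).
- **Joint direct-target signature** — genes responding concordantly in
  both knockdown DE tables at FDR < 0.1 *and* carrying at least one
  peak of each factor within TSS ± 5 kb; per-sample signature score
  s = Σ_g w_g · z_g where z_g is the gene's z-scored expression across
  samples (weights ±1 by response direction, or all +1 for plain z-sum
  panels such as the packaged 30-gene AR panel).
- **Germline risk layer** — composite-LD r² (squared dosage
  correlation), proxy expansion at r² ≥ 0.5 within 1 Mb,
  permutation fold-enrichment of risk SNPs in binding-site categories
  with empirical p = (1 + #{null ≥ obs})/(1 + n_perm), eQTL eGene
  joins, PWM log₂-odds allele-affinity deltas (both strands, all
  placements covering the SNP, risk-minus-other sign convention),
  exact binomial allelic-imbalance tests, and qPCR standard-curve
  quantification 10^((Ct − intercept)/slope) normalized to a loading
  control.
- **Survival** — Kaplan–Meier, log-rank, single-covariate Cox HR with
  Breslow ties and Wald CIs; stratification schemes: median split
  (ties low), copy-number split, joint two-gene split,
  genotype-within-expression-stratum (TT vs TC/CC), Gleason ≤6/7/≥8,
  with optional deep-loss exclusion applied before any median.
- **Synthetic cohorts** (`sim_config`, `gen_cohort`, `gen_peaksets`,
  `gen_knockdown_experiment`, `gen_germline`) — every consumed input,
  generated with planted truth and per-generator seed streams.
- **Pipeline** (`run_pipeline`) — stage orchestration with YAML
  config, per-stage filter logging and an MD5 manifest;
  `inst/scripts/regcoop_pipeline.R` is the command-line wrapper.

## Worked example

```r
library(regcoop)
cfg <- sim_config(seed = 1)          # stated-world defaults
co  <- gen_cohort(cfg)
cand <- select_candidates(amplification_frequency(co$cn),
                          cn_expression_correlation(co$cn, co$expr))
ranked <- rank_by_essentiality(cand, co$ess)
head(ranked[, c("gene","amp_frequency","pearson_r","fdr","essentiality","rank")], 3)
#>       gene amp_frequency pearson_r      fdr essentiality rank
#> 1 GENE0001         0.100     0.349 5.39e-05        -5.40    1
#> 2 GENE0018         0.105     0.347 5.96e-05        -1.73    2
#> 3 GENE0014         0.105     0.422 1.09e-07        -1.02    3

ps <- gen_peaksets(cfg)
classify_cooccupancy(ps$peaks_a, ps$peaks_b)
#> Co-occupancy: 4795/10000 A regions common (47.9%); 4795/7321 B regions common (65.5%)

kd  <- gen_knockdown_experiment(cfg)
com <- common_de_genes(select_de_genes(kd$de_a), select_de_genes(kd$de_b))
tg  <- joint_direct_targets(com$common, kd$peaks_a, kd$peaks_b, kd$annotation)
length(com$common); length(tg)
#> [1] 150
#> [1] 50

grp <- stratify_samples("median_split",
                        expression = co$expr[co$truth$top_driver, ])
cox_hr(grp == "high", co$clinical$time, co$clinical$event)$hr
#> [1] 2.34
```

Reading the numbers: the planted top driver (`GENE0001`, the gene
given the strongest essentiality) is recovered at rank 1 with the
planted ~10% amplification frequency and ~0.4 copy-number/expression
correlation; the peak generator's planted 65.5% co-occupancy fraction
is recovered exactly (4795/7321); all 50 planted joint targets survive
the FDR + promoter-co-binding intersection; and the median split on
the driver's expression recovers a hazard ratio near the planted
HR = 2 (2.34 with 95% CI [1.61, 3.39] at n = 200).

## Pipeline CLI

```sh
Rscript inst/scripts/regcoop_pipeline.R --seed 11 --outdir out \
  --stages simulate,drivers,cooccupancy,signatures,germline,survival
```

Outputs land in `out/` as TSV/BED with `run.log` (counts in/out for
every filter) and `manifest.tsv` (MD5 per file); identical
configurations reproduce identical checksums.
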