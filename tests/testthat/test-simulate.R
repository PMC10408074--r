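small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 300L, n_samples = 100L,
             n_driver_genes = 5L, n_peaks_a = 500L, n_peaks_b = 400L,
             n_kd_genes = 600L, n_joint_targets = 10L, n_de_only = 20L,
             n_bound_only = 20L, n_single_bound = 20L,
             n_background_snps = 500L, n_risk_snps = 40L, ...)
}

test_that("config validation rejects bad fields and infeasible setups", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, nonsense = 2), "unknown config")
  expect_error(sim_config(seed = 1, amp_frequency = 0), "infeasible")
  expect_error(sim_config(seed = 1, cooccupancy_fraction = 1.2))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg(42)
  a <- gen_cohort(cfg); b <- gen_cohort(cfg)
  expect_identical(a, b)
  expect_identical(gen_peaksets(cfg), gen_peaksets(cfg))
  expect_identical(gen_knockdown_experiment(cfg),
                   gen_knockdown_experiment(cfg))
  expect_identical(gen_germline(cfg), gen_germline(cfg))
  # different seeds differ
  expect_false(identical(gen_cohort(small_cfg(43))$expr, a$expr))
  # generator streams are independent of one another
  expect_identical(gen_peaksets(cfg)$peaks_a,
                   {gen_cohort(cfg); gen_peaksets(cfg)$peaks_a})
})

test_that("null copy-number effect centers per-gene correlations at zero", {
  cfg <- sim_config(seed = 8, n_genes = 1000L, n_samples = 100L,
                    n_driver_genes = 10L, cn_expr_effect = 0)
  co <- gen_cohort(cfg)
  corr <- cn_expression_correlation(co$cn, co$expr)
  expect_lt(abs(mean(corr$pearson_r, na.rm = TRUE)), 0.02)
})

test_that("planted effect size is recovered in driver genes", {
  cfg <- sim_config(seed = 9, n_genes = 200L, n_samples = 500L,
                    n_driver_genes = 50L)
  co <- gen_cohort(cfg)
  corr <- cn_expression_correlation(co$cn, co$expr)
  r_driver <- corr$pearson_r[corr$gene %in% co$truth$drivers]
  expect_equal(mean(r_driver), 0.4, tolerance = 0.05)
})

test_that("peak generator hits extreme planted fractions exactly", {
  cc1 <- with(gen_peaksets(small_cfg(3, cooccupancy_fraction = 1.0)),
              classify_cooccupancy(peaks_a, peaks_b))
  expect_equal(cc1$fraction_b, 1.0)
  cc0 <- with(gen_peaksets(small_cfg(3, cooccupancy_fraction = 0.0)),
              classify_cooccupancy(peaks_a, peaks_b))
  expect_equal(cc0$fraction_b, 0.0)
  expect_error(gen_peaksets(sim_config(seed = 1, n_peaks_a = 10L,
                                       n_peaks_b = 100L,
                                       cooccupancy_fraction = 1)),
               "infeasible")
  expect_error(gen_peaksets(sim_config(seed = 1, n_peaks_a = 20000L)),
               "too small")
})

test_that("emitted peak sets pass reader validation after BED round trip", {
  ps <- gen_peaksets(small_cfg(4))
  tmp <- withr::local_tempfile(fileext = ".bed")
  expect_no_warning(write_bed(ps$peaks_a, tmp))
  back <- read_bed(tmp)
  expect_equal(back$start, ps$peaks_a$start)
})

test_that("knockdown truth partitions behave as constructed", {
  cfg <- small_cfg(6)
  kd <- gen_knockdown_experiment(cfg)
  tr <- kd$truth
  sel_a <- select_de_genes(kd$de_a)
  sel_b <- select_de_genes(kd$de_b)
  com <- common_de_genes(sel_a, sel_b)
  # planted joint targets are DE in both by construction
  expect_true(all(tr$joint_targets %in% com$common))
  tg <- joint_direct_targets(com$common, kd$peaks_a, kd$peaks_b,
                             kd$annotation)
  # bound-only decoys never appear (not DE)
  expect_length(intersect(tg, tr$bound_only), 0)
  # zero planted targets -> empty output
  kd0 <- gen_knockdown_experiment(small_cfg(6, n_joint_targets = 0L))
  com0 <- common_de_genes(select_de_genes(kd0$de_a),
                          select_de_genes(kd0$de_b))
  tg0 <- joint_direct_targets(com0$common, kd0$peaks_a, kd0$peaks_b,
                              kd0$annotation)
  expect_length(intersect(tg0, kd0$truth$bound_only), 0)
})

test_that("germline generator plants imbalance and eQTL links", {
  cfg <- small_cfg(7, read_depth = 500L)
  g <- gen_germline(cfg)
  ai <- allelic_imbalance(g$allele_counts$count_risk,
                          g$allele_counts$count_other)
  expect_equal(ai$ratio_risk, 0.7, tolerance = 0.05)
  rep_ <- map_eqtl_genes(
    expand_proxies(g$tags, g$block_snps, genotypes = g$genotypes),
    g$eqtl)
  expect_setequal(setdiff(unique(rep_$egene), ""),
                  g$eqtl$egene)
  expect_error(gen_germline(small_cfg(7, enrichment_factor = 1e6)),
               "incompatible")
})
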