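test_that("ld_r2 equals squared Pearson of dosages", {
  g <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ld_r2(g, g), 1.0)
  expect_equal(ld_r2(g, 2 - g), 1.0)  # perfect anti-correlation
  set.seed(12)
  for (rep in 1:20) {
    a <- sample(0:2, 30, TRUE); b <- sample(0:2, 30, TRUE)
    expect_equal(ld_r2(a, b), pearson_formula(a, b)^2, tolerance = 1e-12)
  }
  expect_true(is.na(ld_r2(rep(1, 10), sample(0:2, 10, TRUE))))
  expect_equal(attr(ld_r2(rep(0, 5), 0:4 %% 3), "flag"), "monomorphic")
})

test_that("proxy expansion is inclusive at the r2 cutoff and windowed", {
  tags <- data.frame(rsid = "t1", chrom = "c1", pos = 1000)
  snps <- data.frame(rsid = c("t1", "p1", "p2", "far"),
                     chrom = c("c1", "c1", "c1", "c1"),
                     pos = c(1000, 2000, 3000, 5e6))
  ld <- data.frame(tag = "t1", proxy = c("p1", "p2", "far"),
                   r2 = c(0.5, 0.49, 0.99))
  out <- expand_proxies(tags, snps, ld_pairs = ld, window_bp = 1e6)
  expect_setequal(out$proxy, c("t1", "p1"))  # 0.5 in, 0.49 out, far outside
  expect_equal(out$r2[out$proxy == "t1"], 1)
  # r2_min = 0 returns everything in the window; r2_min = 1 only perfect
  all_in <- expand_proxies(tags, snps, ld_pairs = ld, r2_min = 0)
  expect_setequal(all_in$proxy, c("t1", "p1", "p2"))
  perfect <- expand_proxies(tags, snps, ld_pairs = ld, r2_min = 1)
  expect_setequal(perfect$proxy, "t1")
  expect_warning(
    expand_proxies(data.frame(rsid = "t9", chrom = "c1", pos = 100),
                   snps, ld_pairs = ld), "absent")
})

test_that("genotype-based proxy expansion recovers planted LD blocks", {
  cfg <- sim_config(seed = 5, ld_noise = 0)
  g <- gen_germline(cfg)
  out <- expand_proxies(g$tags, g$block_snps, genotypes = g$genotypes)
  # noiseless blocks: every member is a perfect proxy of its tag
  expect_equal(nrow(out), nrow(g$tags) * cfg$ld_block_size)
  expect_equal(out$r2, rep(1, nrow(out)), tolerance = 1e-12)
  cfg2 <- sim_config(seed = 5)  # default noise targets r2 ~ 0.8
  g2 <- gen_germline(cfg2)
  out2 <- expand_proxies(g2$tags, g2$block_snps, genotypes = g2$genotypes)
  expect_gt(nrow(out2), 0.9 * nrow(g2$tags) * cfg2$ld_block_size)
})

test_that("enrichment arithmetic, bounds and reproducibility hold", {
  regions <- data.frame(chrom = "c1", start = c(0, 5000),
                        end = c(1000, 6000), category = "common")
  snps <- data.frame(rsid = sprintf("r%d", 1:20), chrom = "c1",
                     pos = c(seq(0, 900, length.out = 10),
                             seq(2000, 4000, length.out = 10)))
  set.seed(14)
  bg <- data.frame(chrom = "c1", pos = sample.int(10000, 500) - 1)
  e1 <- snp_peak_enrichment(snps, regions, bg, n_perm = 200, seed = 9)
  e2 <- snp_peak_enrichment(snps, regions, bg, n_perm = 200, seed = 9)
  expect_identical(e1, e2)
  expect_equal(e1$observed, 10)
  expect_gte(e1$p_value, 1 / 201)
  expect_lte(e1$p_value, 1)
  expect_equal(e1$fold, 10 / e1$null_mean)
  expect_error(snp_peak_enrichment(snps, regions, bg[1:5, ],
                                   n_perm = 10, seed = 1),
               "background pool smaller")
})

test_that("eQTL mapping is a relational join with empty-eGene reporting", {
  prox <- data.frame(tag = c("t1", "t1", "t2"),
                     proxy = c("t1", "p1", "t2"),
                     category = c("common", "common", "outside"))
  eq <- data.frame(rsid = c("p1", "p1"), egene = c("EG1", "EG2"),
                   source = "db")
  rep_ <- map_eqtl_genes(prox, eq)
  expect_equal(nrow(rep_), 4)  # t1 empty + p1 x2 + t2 empty
  expect_setequal(rep_$egene[rep_$proxy == "p1"], c("EG1", "EG2"))
  expect_equal(rep_$egene[rep_$proxy == "t2"], "")
  # join-count oracle on random tables
  set.seed(15)
  pr <- data.frame(tag = "t", proxy = sample(letters[1:8], 20, TRUE))
  ee <- data.frame(rsid = sample(letters[1:8], 15, TRUE),
                   egene = sample(LETTERS, 15, TRUE))
  got <- map_eqtl_genes(pr, ee)
  expected_n <- sum(vapply(pr$proxy,
                           function(x) max(1L, sum(ee$rsid == x)), 1L))
  expect_equal(nrow(got), expected_n)
})

test_that("allelic imbalance matches the exact enumeration oracle", {
  r <- allelic_imbalance(5, 5)
  expect_equal(r$ratio_risk, 0.5)
  expect_equal(r$p_value, 1.0)
  expect_equal(allelic_imbalance(9, 1)$p_value, 2 * 11 / 1024,
               tolerance = 1e-12)
  expect_error(allelic_imbalance(0, 0), "zero total")
  for (n in 1:30) for (k in 0:n) {
    expect_equal(allelic_imbalance(k, n - k)$p_value,
                 binom_two_sided_enum(k, n), tolerance = 1e-9)
  }
})

test_that("allelic imbalance p-values are calibrated under a balanced null", {
  set.seed(16)
  ps <- vapply(rbinom(1000, 100, 0.5),
               function(k) allelic_imbalance(k, 100 - k)$p_value, 0)
  # exact test is conservative/discrete: check super-uniformity
  expect_lt(mean(ps < 0.05), 0.06)
  expect_gt(mean(ps), 0.45)
})

test_that("qPCR quantification inverts the standard curve", {
  curve <- list(slope = -3.3, intercept = 20, r2 = 1)
  expect_equal(qpcr_quantify(curve, 20, 20), 1.0)
  expect_equal(qpcr_quantify(curve, c(20, 20), 20), c(1, 1))
  expect_error(qpcr_quantify(curve, NA_real_, 20), "non-finite")
  expect_error(qpcr_quantify(list(slope = 0, intercept = 1), 5, 5))
  # perfect 10-fold dilution series regenerates quantities
  lq <- 0:-5
  ct <- 18 - 3.5 * lq
  fit <- fit_standard_curve(lq, ct)
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
  q <- 10^((ct - fit$intercept) / fit$slope)
  expect_equal(q, 10^lq, tolerance = 1e-9)
  # normalization to control: identical ct -> 1.0
  expect_equal(qpcr_quantify(fit, ct[3], ct[3]), 1.0, tolerance = 1e-12)
})

test_that("SNP tables read from TSV and VCF with coordinate conversion", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\tref\talt",
               "rs1\tc1\t99\tC\tT"), tsv)
  t1 <- read_snp_table(tsv)
  expect_equal(t1$pos, 99)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               "c1\t100\trs1\tC\tT"), vcf)
  v1 <- read_snp_table(vcf)
  expect_equal(v1$pos, 99)  # 1-based VCF -> 0-based
  writeLines(c("rsid\tchrom\tpos\tref\talt",
               "rs2\tc1\t5\tC\tC"), tsv)
  expect_error(read_snp_table(tsv), "invalid alleles")
})
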