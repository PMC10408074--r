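test_that("low-expression filter keeps genes with >= 2 cumulative reads", {
  m <- matrix(c(0, 0, 0, 1, 1, 1, 5, 0), nrow = 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  expect_setequal(filter_low_expression(m), c("c", "d"))
  expect_length(filter_low_expression(matrix(0, 3, 2,
    dimnames = list(letters[1:3], NULL))), 0)
  set.seed(3)
  r <- matrix(rpois(200, 1), 50, 4, dimnames = list(sprintf("g%d", 1:50), NULL))
  expect_equal(filter_low_expression(r),
               rownames(r)[rowSums(r) >= 2])
})

test_that("DE selection is strict at the FDR boundary and keeps direction", {
  de <- data.frame(gene = c("g1", "g2", "g3"),
                   log2fc = c(2, -1, 0.5),
                   p_value = c(0.01, 0.02, 0.05),
                   fdr = c(0.099, 0.10, 0.3))
  out <- select_de_genes(de)
  expect_equal(out$gene, "g1")
  expect_equal(out$direction, 1)
  expect_equal(nrow(select_de_genes(de[0, ])), 0L)
  set.seed(4)
  rde <- data.frame(gene = sprintf("g%d", 1:300), log2fc = rnorm(300),
                    p_value = runif(300), fdr = runif(300))
  expect_equal(nrow(select_de_genes(rde)), sum(rde$fdr < 0.1))
})

test_that("common DE genes honor direction concordance", {
  a <- data.frame(gene = c("g1", "g2"), log2fc = c(2, -1),
                  fdr = 0.01, direction = c(1, -1))
  b <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(1, 1, 1),
                  fdr = 0.01, direction = c(1, 1, 1))
  cm <- common_de_genes(a, b)
  expect_equal(cm$common, "g1")
  expect_equal(cm$discordant, "g2")
  expect_setequal(common_de_genes(a, b, concordant_only = FALSE)$common,
                  intersect(a$gene, b$gene))
  expect_length(common_de_genes(a, b[3, , drop = FALSE])$common, 0)
})

test_that("joint targets require both factors in the promoter window", {
  ann <- data.frame(gene = c("g1", "g2", "g3"), chrom = "c1",
                    tss = c(100000, 300000, 500000), strand = "+")
  pa <- peak_set("c1", c(96000, 296000), c(96500, 296500))  # g1, g2
  pb <- peak_set("c1", c(103000, 496000), c(103400, 496500))  # g1, g3
  tg <- joint_direct_targets(c("g1", "g2", "g3"), pa, pb, ann)
  expect_equal(tg, "g1", ignore_attr = TRUE)
  expect_warning(
    joint_direct_targets(c("g1", "gX"), pa, pb, ann),
    "missing promoter annotation")
  # subset property: targets are always a subset of the common genes
  expect_true(all(tg %in% c("g1", "g2", "g3")))
})

test_that("signature scores equal hand-computed z sums on a toy matrix", {
  expr <- matrix(c(1, 2, 3,
                   10, 10, 16,
                   5, 4, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"),
                                 c("s1", "s2", "s3")))
  sig <- signature_definition("toy", c("gA", "gB", "gC"))
  sc <- score_signature(expr, sig, mode = "z_sum")
  hand <- colSums(rbind(
    (expr["gA", ] - mean(expr["gA", ])) / sd(expr["gA", ]),
    (expr["gB", ] - mean(expr["gB", ])) / sd(expr["gB", ]),
    (expr["gC", ] - mean(expr["gC", ])) / sd(expr["gC", ])))
  expect_equal(as.numeric(sc), unname(hand), tolerance = 1e-12)
  # single-gene panel = that gene's z-score
  s1 <- score_signature(expr, signature_definition("one", "gA"))
  expect_equal(as.numeric(s1),
               unname((expr["gA", ] - 2) / 1), tolerance = 1e-12)
  # weighted mode applies the signs
  sw <- signature_definition("w", c("gA", "gC"), c(1, -1))
  expect_equal(as.numeric(score_signature(expr, sw)),
               unname((expr["gA", ] - 2) / 1 - (expr["gC", ] - 4) / 1),
               tolerance = 1e-12)
})

test_that("z-sum scoring is invariant under per-gene affine rescaling", {
  set.seed(9)
  expr <- matrix(rnorm(60), 6, 10,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
  sig <- signature_definition("s", rownames(expr))
  base <- score_signature(expr, sig, mode = "z_sum")
  rescaled <- expr * runif(6, 0.5, 4) + rnorm(6)
  expect_equal(as.numeric(base),
               as.numeric(score_signature(rescaled, sig, mode = "z_sum")),
               tolerance = 1e-10)
})

test_that("degenerate panels are flagged and absent genes skipped", {
  expr <- matrix(5, 2, 4, dimnames = list(c("gA", "gB"), sprintf("s%d", 1:4)))
  sig <- signature_definition("flat", c("gA", "gB", "gZ"))
  expect_warning(sc <- score_signature(expr, sig), "zero-variance")
  expect_equal(as.numeric(sc), rep(0, 4))
  expect_setequal(attr(sc, "skipped"), c("gA", "gB", "gZ"))
  expect_error(score_signature(expr,
                               signature_definition("none", "gQ")),
               "no signature gene")
})

test_that("score correlation matches the covariance formula and edge rules", {
  x <- 1:10
  expect_equal(correlate_scores(x, 2 * x + 1)$r, 1.0, tolerance = 1e-12)
  expect_equal(correlate_scores(x, -x)$r, -1.0, tolerance = 1e-12)
  expect_equal(correlate_scores(x, rep(3, 10))$flag, "zero variance")
  set.seed(10)
  a <- rnorm(100); b <- 0.4 * a + rnorm(100)
  expect_equal(correlate_scores(a, b)$r, pearson_formula(a, b),
               tolerance = 1e-12)
})

test_that("packaged AR panel loads with 30 unit-weight genes", {
  sig <- ar_signature_panel()
  expect_length(sig$genes, 30)
  expect_true(all(c("MPHOSPH9", "KLK3", "AR", "TMPRSS2", "ZBTB10") %in%
                    sig$genes))
  expect_true(all(sig$weights == 1))
})
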