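test_that("KM estimator matches hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv_at(km, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(km_surv_at(km, 3), 0, tolerance = 1e-12)
  expect_equal(km_surv_at(km, 0.5), 1)
  # no events -> S = 1 throughout
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_surv_at(km0, c(1, 2, 3)) == 1))
  expect_error(km_estimate(-1, 1), "negative")
})

test_that("KM matches exhaustive small-case product-limit oracle", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(1:5, 1)
    times <- sample(1:4, n, replace = TRUE)
    events <- rbinom(n, 1, 0.6)
    km <- km_estimate(times, events)
    # direct product-limit: S(t) = prod over event times <= t
    for (t in 1:4) {
      ets <- sort(unique(times[events == 1]))
      s <- 1
      for (u in ets[ets <= t]) {
        d <- sum(times == u & events == 1)
        r <- sum(times >= u)
        s <- s * (1 - d / r)
      }
      expect_equal(km_surv_at(km, t), s, tolerance = 1e-12)
    }
    # monotonicity property
    expect_true(all(diff(km$surv) <= 1e-12))
  }
})

test_that("log-rank handles identical groups, oracles and label permutation", {
  t0 <- c(1, 2, 3, 4, 5); e0 <- c(1, 0, 1, 1, 0)
  r <- logrank_test(rep(c("a", "b"), each = 5), c(t0, t0), c(e0, e0))
  expect_equal(r$chi2, 0, tolerance = 1e-9)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  expect_error(logrank_test(rep("a", 5), t0, e0), "2 groups")
  # hand computation on a 10-subject dataset
  set.seed(23)
  g <- rep(c("x", "y"), each = 5)
  tt <- c(2, 4, 4, 7, 9, 1, 3, 5, 5, 8)
  ee <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  got <- logrank_test(g, tt, ee)
  expect_equal(got$chi2, logrank_by_hand(g, tt, ee), tolerance = 1e-8)
  # invariance to permuting labels
  perm <- sample(10)
  expect_equal(logrank_test(g[perm], tt[perm], ee[perm])$chi2, got$chi2,
               tolerance = 1e-10)
  expect_equal(got$df, 1L)
})

test_that("Cox HR equals grid-search Breslow partial-likelihood argmax", {
  x <- c(1, 1, 1, 0, 0, 0)
  tt <- c(1, 3, 4, 2, 5, 6)
  ee <- c(1, 1, 0, 1, 1, 1)
  fit <- cox_hr(x, tt, ee)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, 0, x = x, times = tt, events = ee)
  expect_equal(fit$log_hr, grid[which.max(ll)], tolerance = 1e-4)
  # identical groups -> HR 1
  fit1 <- cox_hr(rep(c(1, 0), each = 4), rep(c(1, 2, 3, 4), 2),
                 rep(c(1, 1, 0, 1), 2))
  expect_equal(fit1$hr, 1.0, tolerance = 1e-6)
  expect_error(cox_hr(c(1, 1, 0, 0), c(1, 2, 3, 4), c(1, 1, 0, 0)),
               "at least one event")
})

test_that("Cox flags complete separation as non-convergent", {
  x <- c(1, 1, 1, 0, 0, 0)
  tt <- c(1, 2, 3, 10, 11, 12)  # exposed all fail first
  ee <- rep(1, 6)
  fit <- cox_hr(x, tt, ee)
  expect_false(fit$converged)
})

test_that("median split sends ties low and flags degenerate vectors", {
  e <- setNames(c(1, 2, 3, 3, 5), sprintf("s%d", 1:5))
  lab <- stratify_samples("median_split", expression = e)
  expect_equal(as.character(lab), c("low", "low", "low", "low", "high"))
  flat <- setNames(rep(2, 4), sprintf("s%d", 1:4))
  lab2 <- stratify_samples("median_split", expression = flat)
  expect_true(all(lab2 == "low"))
  expect_match(attr(lab2, "flag"), "degenerate")
  # group sizes differ at most by the median-tied count
  set.seed(25)
  v <- setNames(sample(1:20, 101, TRUE), sprintf("s%d", 1:101))
  l <- stratify_samples("median_split", expression = v)
  ties <- sum(v == median(v))
  expect_lte(abs(sum(l == "high") - sum(l == "low")), ties)
})

test_that("cn split, gleason subgroups and deep-loss exclusion", {
  cn <- setNames(c(-2, -1, 0, 1, 2), sprintf("s%d", 1:5))
  lab <- stratify_samples("cn_split", cn = cn)
  expect_equal(as.character(lab), c(NA, NA, "diploid", "gain_amp", "gain_amp"))
  gl <- setNames(c(6, 7, 8, 9), sprintf("s%d", 1:4))
  expect_equal(as.character(stratify_samples("gleason_subgroup", gleason = gl)),
               c("<=6", "7", ">=8", ">=8"))
  # deep-loss exclusion applies before the median is computed
  e <- setNames(c(10, 1, 2, 3, 4), sprintf("s%d", 1:5))
  dl <- setNames(c(-2, 0, 0, 0, 0), sprintf("s%d", 1:5))
  lab2 <- stratify_samples("median_split", expression = e, deep_loss_cn = dl)
  expect_true(is.na(lab2["s1"]))
  # median over s2..s5 = 2.5, so s4 and s5 high
  expect_equal(unname(lab2[2:5]), c("low", "low", "high", "high"))
})

test_that("genotype-within-stratum compares TT vs TC/CC inside one stratum", {
  e <- setNames(c(1, 2, 3, 4, 5, 6), sprintf("s%d", 1:6))
  gt <- setNames(c("TT", "TC", "CC", "TT", "TC", "CC"), names(e))
  lab <- stratify_samples("genotype_within_stratum", expression = e,
                          genotype = gt, stratum = "high")
  expect_true(all(is.na(lab[1:3])))  # low stratum excluded
  expect_equal(unname(lab[4:6]), c("TT", "TC_CC", "TC_CC"))
  labcc <- stratify_samples("genotype_within_stratum", expression = e,
                            genotype = gt, stratum = "high",
                            genotype_mode = "TT_vs_CC")
  expect_equal(unname(labcc[4:6]), c("TT", NA, "CC"))
  lab_lo <- stratify_samples("genotype_within_stratum", expression = e,
                             genotype = gt, stratum = "low")
  expect_equal(unname(lab_lo[1:3]), c("TT", "TC_CC", "TC_CC"))
})

test_that("missing inputs for a scheme raise errors", {
  expect_error(stratify_samples("median_split"), "missing required input")
  expect_error(stratify_samples("median_split", expression = c(1, 2)),
               "named by sample")
})
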