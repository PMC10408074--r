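# Independent oracles and small fixture builders used across the
# suite.  Oracles are deliberately naive (brute force, enumeration,
# hand formulas) and share no code with the implementation they check.

random_peak_set <- function(n, chroms = c("c1", "c2"), max_pos = 10000,
                            max_width = 200) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), start, start + width)
}

# O(n^2) all-pairs overlap oracle (>= min_overlap bp, half-open
# coords); checks every (i, j) pair directly from the definition
brute_force_pairs <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    j <- which(a$chrom[i] == b$chrom & ov >= min_overlap)
    if (length(j))
      out[[length(out) + 1L]] <- data.frame(idx_a = i, idx_b = j,
                                            overlap_bp = ov[j])
  }
  if (!length(out))
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      overlap_bp = integer()))
  d <- do.call(rbind, out)
  d <- d[order(d$idx_a, d$idx_b), ]
  rownames(d) <- NULL
  d
}

# per-base bitmap union on a toy chromosome
bitmap_covered_bases <- function(p, chrom_len = 10000) {
  total <- 0
  for (ch in unique(p$chrom)) {
    bits <- logical(chrom_len)
    sub <- p[p$chrom == ch, ]
    for (i in seq_len(nrow(sub)))
      bits[(sub$start[i] + 1):sub$end[i]] <- TRUE
    total <- total + sum(bits)
  }
  total
}

# linear-scan point-in-peak oracle
linear_scan_inside <- function(chrom, pos, p) {
  vapply(seq_along(pos), function(i) {
    any(p$chrom == chrom[i] & p$start <= pos[i] & pos[i] < p$end)
  }, TRUE)
}

# textbook Pearson r from sums
pearson_formula <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# exact two-sided binomial p: sum of point probabilities <= observed
binom_two_sided_enum <- function(k, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= dbinom(k, n, p0) * (1 + 1e-7)])
}

# Breslow log partial likelihood for a single binary covariate
breslow_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + beta * sum(x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# two-group log-rank chi-square from observed/expected sums
logrank_by_hand <- function(g, times, events) {
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == levels(factor(g))[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == levels(factor(g))[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
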