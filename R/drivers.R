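# Candidate amplified-driver prioritization: amplification-frequency
# filter, copy-number/expression correlation, essentiality ranking.
#
# Copy-number matrices carry GISTIC-style integer codes
# (-2 deep loss, -1 loss, 0 diploid, +1 gain, +2 amplification).

check_cn_matrix <- function(cn) {
  stopifnot(is.matrix(cn))
  if (ncol(cn) == 0L) stop("copy-number matrix has zero samples", call. = FALSE)
  if (anyDuplicated(colnames(cn))) stop("duplicate sample IDs", call. = FALSE)
  if (any(!cn[is.finite(cn)] %in% -2:2))
    stop("copy-number codes must be integers in -2..2", call. = FALSE)
  invisible(TRUE)
}

#' Per-gene amplification frequency
#'
#' Fraction of samples in which a gene's copy-number code is at least
#' `min_code`.  The default `min_code = 1` pools gain and amplification;
#' `min_code = 2` restricts to amplification proper.
#'
#' @param cn genes x samples integer matrix of GISTIC-style codes.
#' @param min_code 1 (gain or amplification) or 2 (amplification only).
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
amplification_frequency <- function(cn, min_code = 1L) {
  check_cn_matrix(cn)
  stopifnot(min_code %in% c(1L, 2L))
  rowMeans(cn >= min_code, na.rm = TRUE)
}

#' Copy-number/expression correlation per gene
#'
#' Pearson product-moment correlation between the numeric copy-number
#' code and expression, computed over samples restricted to codes in
#' `codes` (default `{0, 1, 2}`: diploid, gain, amplification - losses
#' excluded).  The two-sided p-value comes from the t distribution with
#' n - 2 degrees of freedom.  Genes with fewer than 3 usable samples or
#' zero variance in either vector are flagged undefined (`NA`) and are
#' excluded from candidacy downstream.
#'
#' @param cn genes x samples copy-number code matrix.
#' @param expr genes x samples expression matrix with identical
#'   dimnames (log2-scale normalized values assumed).
#' @param codes copy-number codes admitted to the correlation.
#' @return `data.frame` with columns `gene`, `n`, `pearson_r`,
#'   `p_value`, `defined`.
#' @export
cn_expression_correlation <- function(cn, expr, codes = c(0L, 1L, 2L)) {
  check_cn_matrix(cn)
  stopifnot(is.matrix(expr), identical(rownames(cn), rownames(expr)),
            identical(colnames(cn), colnames(expr)))
  res <- lapply(seq_len(nrow(cn)), function(i) {
    use <- which(cn[i, ] %in% codes & is.finite(expr[i, ]))
    x <- as.numeric(cn[i, use]); y <- as.numeric(expr[i, use])
    n <- length(use)
    if (n < 3L || sd(x) == 0 || sd(y) == 0)
      return(c(n = n, r = NA_real_, p = NA_real_))
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(n = n, r = r, p = 2 * pt(-abs(tt), df = n - 2))
  })
  m <- do.call(rbind, res)
  data.frame(gene = rownames(cn), n = m[, "n"], pearson_r = m[, "r"],
             p_value = m[, "p"], defined = !is.na(m[, "r"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select candidate amplified driver genes
#'
#' Keeps genes with amplification frequency >= `freq_min`, positive
#' copy-number/expression correlation, and Benjamini-Hochberg FDR below
#' `fdr_max`.  The FDR is computed over the full tested gene universe
#' (all genes with a defined correlation), not over the filtered subset.
#'
#' @param freq named amplification-frequency vector
#'   (from [amplification_frequency()]).
#' @param corr correlation table from [cn_expression_correlation()].
#' @param freq_min minimum amplification frequency (default 0.05,
#'   i.e. amplified in at least 5\% of tumors).
#' @param fdr_max BH-FDR cutoff for the correlation (default 0.05).
#' @return `data.frame` of candidates with columns `gene`,
#'   `amp_frequency`, `pearson_r`, `p_value`, `fdr`; attribute
#'   `"excluded"` holds the complementary gene table so no gene is lost.
#' @export
select_candidates <- function(freq, corr, freq_min = 0.05, fdr_max = 0.05) {
  stopifnot(length(freq) > 0, is.data.frame(corr))
  if (!setequal(names(freq), corr$gene))
    stop("frequency and correlation tables must share one gene universe",
         call. = FALSE)
  corr <- corr[match(names(freq), corr$gene), ]
  fdr <- rep(NA_real_, nrow(corr))
  ok <- corr$defined
  fdr[ok] <- p.adjust(corr$p_value[ok], method = "BH")
  tab <- data.frame(gene = corr$gene, amp_frequency = unname(freq),
                    pearson_r = corr$pearson_r, p_value = corr$p_value,
                    fdr = fdr, stringsAsFactors = FALSE)
  keep <- ok & tab$amp_frequency >= freq_min & tab$pearson_r > 0 &
    !is.na(fdr) & fdr < fdr_max
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- tab[!keep, , drop = FALSE]
  out
}

#' Rank candidates by essentiality
#'
#' Ascending sort on the essentiality score (lower = more essential,
#' as in loss-of-function screen summaries): rank 1 is the most
#' essential candidate.  Ties break lexicographically on the gene
#' symbol; genes absent from the essentiality table are placed last and
#' flagged.
#'
#' @param candidates candidate table from [select_candidates()].
#' @param ess named numeric vector of per-gene essentiality scores.
#' @return the candidate table with columns `essentiality`,
#'   `has_essentiality` and `rank` appended, sorted by rank.
#' @export
rank_by_essentiality <- function(candidates, ess) {
  stopifnot(is.data.frame(candidates), nrow(candidates) > 0)
  sc <- unname(ess[candidates$gene])
  has <- !is.na(sc)
  key <- ifelse(has, sc, Inf)
  o <- order(key, candidates$gene, method = "radix")
  out <- candidates[o, , drop = FALSE]
  out$essentiality <- sc[o]
  out$has_essentiality <- has[o]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fisher's exact association between a binary grouping and outcome
#'
#' Two-sided exact hypergeometric p (sum of table probabilities at most
#' the observed table's probability).  The odds ratio is the sample
#' cross-product ratio, with a Haldane 0.5 correction applied to all
#' cells when any cell is zero.  A zero margin makes the association
#' untestable: p = 1 and the OR is undefined.
#'
#' @param group,outcome parallel logical/0-1 vectors over samples.
#' @return list with `odds_ratio`, `p_value`, `table`, `flag`.
#' @export
clinical_association_2x2 <- function(group, outcome) {
  group <- as.logical(group); outcome <- as.logical(outcome)
  stopifnot(length(group) == length(outcome))
  ok <- !is.na(group) & !is.na(outcome)
  tab <- table(factor(group[ok], c(TRUE, FALSE)),
               factor(outcome[ok], c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1.0, table = tab,
                flag = "zero margin"))
  p <- fisher.test(tab)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
        else (a * d) / (b * c_)
  list(odds_ratio = or, p_value = p, table = tab,
       flag = if (any(tab == 0)) "haldane" else "none")
}
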