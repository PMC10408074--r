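# Inherited-risk layer: LD proxy expansion, SNP-in-binding-site
# permutation enrichment, eQTL eGene assignment, allelic-imbalance
# tests and qPCR standard-curve arithmetic.  PWM allele scoring lives
# in pwm.R.

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of alt-allele dosages (codes 0/1/2),
#' pairwise-complete.  This is composite LD: no phasing is required.
#'
#' @param g1,g2 dosage vectors of equal length; `NA` allowed.
#' @return r-squared in `[0, 1]`, or `NA` (flagged via attribute
#'   `"flag"`) when a SNP is monomorphic or fewer than 3 individuals
#'   have both dosages.
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  x <- g1[ok]; y <- g2[ok]
  if (length(x) < 3L)
    return(structure(NA_real_, flag = "fewer than 3 complete pairs"))
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(NA_real_, flag = "monomorphic"))
  unname(cor(x, y)^2)
}

#' Expand GWAS tag SNPs to LD proxies
#'
#' A proxy of a tag is any SNP within `window_bp` of the tag position
#' with r-squared at least `r2_min` (inclusive cutoff, default 0.5) to
#' the tag.  Each tag is its own proxy with r-squared 1.  LD is either
#' computed from a dosage matrix (composite LD, [ld_r2()]) or taken
#' from a precomputed pair table.
#'
#' @param tags `data.frame` of tag SNPs with columns `rsid`, `chrom`,
#'   `pos` (0-based).
#' @param snps `data.frame` of all candidate SNPs (`rsid`, `chrom`,
#'   `pos`); proxies are drawn from this set.
#' @param genotypes optional SNPs x individuals dosage matrix
#'   (rownames = rsid) used to compute r-squared.
#' @param ld_pairs optional precomputed table with columns `tag`,
#'   `proxy`, `r2` (used when `genotypes` is `NULL`).
#' @param r2_min inclusive r-squared threshold (default 0.5).
#' @param window_bp window half-width around each tag (default 1 Mb).
#' @return `data.frame` with columns `tag`, `proxy`, `chrom`, `pos`,
#'   `r2`.  Tags absent from the LD source are reported with a warning
#'   and returned as self-proxies only.
#' @export
expand_proxies <- function(tags, snps, genotypes = NULL, ld_pairs = NULL,
                           r2_min = 0.5, window_bp = 1e6) {
  stopifnot(is.data.frame(tags), is.data.frame(snps),
            r2_min >= 0, r2_min <= 1)
  if (is.null(genotypes) && is.null(ld_pairs))
    stop("provide either a genotype matrix or a precomputed LD table",
         call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(tags))) {
    tg <- tags[i, ]
    rows[[length(rows) + 1L]] <-
      data.frame(tag = tg$rsid, proxy = tg$rsid, chrom = tg$chrom,
                 pos = tg$pos, r2 = 1, stringsAsFactors = FALSE)
    cand <- snps[snps$chrom == tg$chrom &
                   abs(snps$pos - tg$pos) <= window_bp &
                   snps$rsid != tg$rsid, , drop = FALSE]
    if (nrow(cand) == 0L) next
    if (!is.null(genotypes)) {
      if (!tg$rsid %in% rownames(genotypes)) {
        warning("tag ", tg$rsid, " absent from genotype matrix")
        next
      }
      g_tag <- genotypes[tg$rsid, ]
      r2 <- vapply(cand$rsid, function(rs) {
        if (!rs %in% rownames(genotypes)) return(NA_real_)
        as.numeric(ld_r2(g_tag, genotypes[rs, ]))
      }, 0)
    } else {
      idx <- match(paste(tg$rsid, cand$rsid),
                   paste(ld_pairs$tag, ld_pairs$proxy))
      r2 <- ld_pairs$r2[idx]
      if (all(is.na(r2)) && !tg$rsid %in% ld_pairs$tag)
        warning("tag ", tg$rsid, " absent from LD table")
    }
    keep <- which(!is.na(r2) & r2 >= r2_min)
    if (length(keep))
      rows[[length(rows) + 1L]] <-
        data.frame(tag = tg$rsid, proxy = cand$rsid[keep],
                   chrom = cand$chrom[keep], pos = cand$pos[keep],
                   r2 = r2[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation enrichment of risk SNPs in binding-site categories
#'
#' For each region category (factor A only, factor B only, common),
#' the observed statistic is the number of risk SNPs falling inside
#' the category's regions.  The null resamples `|snps|` SNPs without
#' replacement from a background pool `n_perm` times; fold = observed /
#' mean(null), empirical p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param snps risk-SNP `data.frame` (`rsid`, `chrom`, `pos`).
#' @param regions three-way region table from [cooccupancy_regions()],
#'   or any `data.frame` with `chrom`, `start`, `end`, `category`.
#' @param background background-pool `data.frame` (`chrom`, `pos`);
#'   must be at least as large as `snps`.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return `data.frame` with one row per category: `category`,
#'   `observed`, `null_mean`, `fold`, `p_value`.
#' @export
snp_peak_enrichment <- function(snps, regions, background,
                                n_perm = 1000L, seed) {
  stopifnot(is.data.frame(snps), is.data.frame(regions),
            is.data.frame(background), !missing(seed))
  n_snp <- nrow(snps)
  if (nrow(background) < n_snp)
    stop("background pool smaller than the risk-SNP set", call. = FALSE)
  cats <- unique(regions$category)
  # membership flags computed once per category for risk and background
  flag_of <- function(chrom, pos, sub) {
    ps <- peak_set(sub$chrom, sub$start, sub$end)
    assign_points_to_peaks(chrom, pos, ps)
  }
  out <- lapply(cats, function(ct) {
    sub <- regions[regions$category == ct, , drop = FALSE]
    obs <- sum(flag_of(snps$chrom, snps$pos, sub))
    bg_flag <- flag_of(background$chrom, background$pos, sub)
    null <- with_stream_seed(seed, paste0("enrich:", ct), {
      vapply(seq_len(n_perm), function(i)
        sum(bg_flag[sample.int(length(bg_flag), n_snp)]), 0)
    })
    nm <- mean(null)
    data.frame(category = ct, observed = obs, null_mean = nm,
               fold = if (nm > 0) obs / nm else NA_real_,
               p_value = (1 + sum(null >= obs)) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map in-peak proxies to eQTL genes
#'
#' Relational join of proxy SNPs against an eQTL association table on
#' rsid: one report row per (tag, proxy, category, eGene).  Proxies
#' with no eQTL entry are reported with an empty eGene.
#'
#' @param proxies `data.frame` from [expand_proxies()], optionally with
#'   a `category` column recording which binding-site class each proxy
#'   fell into.
#' @param eqtl `data.frame` with columns `rsid`, `egene`, and
#'   optionally `source` and `direction`.
#' @return risk-locus report `data.frame` with columns `tag`, `proxy`,
#'   `category`, `egene`, `source`.
#' @export
map_eqtl_genes <- function(proxies, eqtl) {
  stopifnot(is.data.frame(proxies))
  cat_col <- proxies$category %||% rep(NA_character_, nrow(proxies))
  rows <- lapply(seq_len(nrow(proxies)), function(i) {
    hit <- eqtl[eqtl$rsid == proxies$proxy[i], , drop = FALSE]
    if (nrow(hit) == 0L)
      return(data.frame(tag = proxies$tag[i], proxy = proxies$proxy[i],
                        category = cat_col[i], egene = "",
                        source = "", stringsAsFactors = FALSE))
    data.frame(tag = proxies$tag[i], proxy = proxies$proxy[i],
               category = cat_col[i], egene = hit$egene,
               source = if (is.null(hit$source)) "" else hit$source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact test of allelic imbalance
#'
#' Two-sided exact binomial test of the risk-allele count against a
#' balanced 0.5 ratio (sum of point probabilities at most the observed
#' point probability).
#'
#' @param count_risk,count_other nonnegative integer read (or molecule)
#'   counts for the risk and other allele.
#' @return list with `ratio_risk`, `p_value`, `n`.
#' @export
allelic_imbalance <- function(count_risk, count_other) {
  stopifnot(count_risk >= 0, count_other >= 0)
  n <- count_risk + count_other
  if (n == 0) stop("zero total allele count", call. = FALSE)
  bt <- binom.test(count_risk, n, p = 0.5, alternative = "two.sided")
  list(ratio_risk = count_risk / n, p_value = bt$p.value, n = n)
}

#' Fit a qPCR standard curve (Ct vs log10 quantity)
#'
#' Linear fit `ct = intercept + slope * log10(quantity)` over a
#' dilution series.
#'
#' @param log10_quantity,ct paired vectors from the control-template
#'   dilution series.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
fit_standard_curve <- function(log10_quantity, ct) {
  stopifnot(length(log10_quantity) == length(ct), length(ct) >= 2)
  fit <- stats::lm(ct ~ log10_quantity)
  # a perfect dilution series triggers lm's perfect-fit warning; fine here
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit)$r.squared))
}

#' Quantify qPCR Ct values against a standard curve
#'
#' Quantities are recovered from the curve as
#' `10^((ct - intercept) / slope)` and normalized to the loading
#' control's quantity obtained with the same formula.  For
#' allele-specific input, per-allele quantities yield an allelic ratio.
#'
#' @param curve list with `slope` (nonzero) and `intercept`
#'   (from [fit_standard_curve()]).
#' @param ct numeric vector of sample Ct values.
#' @param control_ct Ct value(s) of the loading control; a vector is
#'   averaged on the quantity scale.
#' @return normalized relative quantities, same length as `ct`.
#' @export
qpcr_quantify <- function(curve, ct, control_ct) {
  stopifnot(is.list(curve), curve$slope != 0)
  if (any(!is.finite(ct)) || any(!is.finite(control_ct)))
    stop("non-finite Ct value", call. = FALSE)
  q <- 10^((ct - curve$intercept) / curve$slope)
  q_ctrl <- mean(10^((control_ct - curve$intercept) / curve$slope))
  q / q_ctrl
}

#' Read SNP records from a TSV or minimal VCF
#'
#' VCF positions (1-based) are converted to the package's 0-based
#' convention; TSV input (columns `rsid`, `chrom`, `pos`, `ref`, `alt`,
#' optionally `risk_allele`, `is_tag`) is taken as already 0-based.
#'
#' @param path input path; format detected from the `##fileformat=VCF`
#'   header or a `.vcf` extension.
#' @return `data.frame` with columns `rsid`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `risk_allele`, `is_tag`.
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)
  if (is_vcf) {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    df <- data.frame(
      rsid = vapply(parts, `[`, "", 3L),
      chrom = vapply(parts, `[`, "", 1L),
      pos = as.numeric(vapply(parts, `[`, "", 2L)) - 1,
      ref = vapply(parts, `[`, "", 4L),
      alt = vapply(parts, `[`, "", 5L),
      stringsAsFactors = FALSE)
    df$risk_allele <- NA_character_
    df$is_tag <- FALSE
  } else {
    # colClasses: a bare "T" allele must not become logical TRUE
    df <- read_tsv_strict(path, colClasses = "character")
    df$pos <- as.numeric(df$pos)
    df$risk_allele <- df$risk_allele %||% NA_character_
    df$is_tag <- as.logical(df$is_tag %||% "FALSE")
  }
  bad <- !df$ref %in% c("A", "C", "G", "T") |
    !df$alt %in% c("A", "C", "G", "T") | df$ref == df$alt
  if (any(bad))
    stop("invalid alleles for SNP ", df$rsid[which(bad)[1L]], call. = FALSE)
  df
}
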