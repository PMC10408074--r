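# Joint direct-target signature construction from paired knockdown
# differential-expression tables plus promoter co-binding, and
# z-score-sum signature scoring / correlation.

#' Filter genes with low cumulative counts
#'
#' A gene is kept iff its summed count across samples is at least
#' `min_total` (default 2: genes with fewer than 2 cumulative reads
#' across samples are dropped before differential analysis).
#'
#' @param counts nonnegative genes x samples count matrix.
#' @param min_total minimum cumulative count.
#' @return character vector of retained gene names.
#' @export
filter_low_expression <- function(counts, min_total = 2) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  rownames(counts)[rowSums(counts, na.rm = TRUE) >= min_total]
}

#' Select differentially expressed genes from a DE table
#'
#' Keeps records with `fdr < fdr_max` (strict) and annotates each with
#' the direction `sign(log2fc)`.
#'
#' @param de `data.frame` with columns `gene`, `log2fc`, `p_value`,
#'   `fdr` (one row per gene).
#' @param fdr_max FDR cutoff, default 0.1.
#' @return subset of `de` with a `direction` column in `{-1, 0, 1}`.
#' @export
select_de_genes <- function(de, fdr_max = 0.1) {
  stopifnot(is.data.frame(de),
            all(c("gene", "log2fc", "fdr") %in% names(de)))
  if (anyDuplicated(de$gene)) stop("duplicate genes in DE table", call. = FALSE)
  out <- de[!is.na(de$fdr) & de$fdr < fdr_max, , drop = FALSE]
  out$direction <- sign(out$log2fc)
  rownames(out) <- NULL
  out
}

#' Common differentially expressed genes across two knockdowns
#'
#' Intersection of two selected DE tables.  By default a gene must also
#' respond in the same direction in both experiments
#' (`sign(log2fc)` equal); direction-discordant genes are reported
#' separately.
#'
#' @param de_a,de_b outputs of [select_de_genes()].
#' @param concordant_only require direction agreement (default `TRUE`).
#' @return list with `common` (gene character vector), `discordant`,
#'   and `table` (merged per-gene log2fc from both experiments).
#' @export
common_de_genes <- function(de_a, de_b, concordant_only = TRUE) {
  shared <- intersect(de_a$gene, de_b$gene)
  ia <- match(shared, de_a$gene); ib <- match(shared, de_b$gene)
  conc <- de_a$direction[ia] == de_b$direction[ib]
  tab <- data.frame(gene = shared,
                    log2fc_a = de_a$log2fc[ia], log2fc_b = de_b$log2fc[ib],
                    concordant = conc, stringsAsFactors = FALSE)
  list(common = if (concordant_only) shared[conc] else shared,
       discordant = shared[!conc],
       table = tab)
}

#' Joint direct targets: common DE genes bound by both factors
#'
#' A gene qualifies iff at least one peak of each factor overlaps its
#' promoter window (TSS +/- flank); the two factors' peaks need not
#' overlap each other.  Genes in the common set missing from the
#' annotation are excluded with a warning and counted.
#'
#' @param common character vector of common DE genes
#'   (from [common_de_genes()]).
#' @param peaks_a,peaks_b [peak_set()] objects for the two factors.
#' @param promoters promoter windows from [promoter_windows()] (gene
#'   symbol in the `name` column), or a gene annotation `data.frame`
#'   from which windows are built with `flank`.
#' @param flank promoter half-width used when `promoters` is an
#'   annotation table (default 5000).
#' @return character vector of joint direct target genes; attribute
#'   `"n_unannotated"` counts common genes without annotation.
#' @export
joint_direct_targets <- function(common, peaks_a, peaks_b, promoters,
                                 flank = 5000L) {
  if (!inherits(promoters, "PeakSet"))
    promoters <- promoter_windows(promoters, flank = flank)
  missing <- setdiff(common, promoters$name)
  if (length(missing))
    warning(length(missing), " common gene(s) missing promoter annotation; excluded")
  prom <- promoters[promoters$name %in% common, , drop = FALSE]
  attr(prom, "merged") <- FALSE
  class(prom) <- c("PeakSet", "data.frame")
  if (nrow(prom) == 0L) {
    out <- character()
    attr(out, "n_unannotated") <- length(missing)
    return(out)
  }
  bound_a <- unique(prom$name[intersect_intervals(prom, peaks_a)$idx_a])
  bound_b <- unique(prom$name[intersect_intervals(prom, peaks_b)$idx_a])
  out <- intersect(common, intersect(bound_a, bound_b))
  attr(out, "n_unannotated") <- length(missing)
  out
}

#' Define a gene signature
#'
#' @param name signature name.
#' @param genes character vector of panel genes (unique).
#' @param weights per-gene weights (default all +1).
#' @return `SignatureDefinition` object.
#' @export
signature_definition <- function(name, genes, weights = rep(1, length(genes))) {
  stopifnot(length(genes) == length(weights), !anyDuplicated(genes))
  structure(list(name = name, genes = as.character(genes),
                 weights = as.numeric(weights)),
            class = "SignatureDefinition")
}

#' Direction-aware weights for a joint-target signature
#'
#' The published description fixes no weight magnitudes, so the default
#' joint-target weight of gene g is the sign of its mean log2
#' fold-change across the two knockdown tables, magnitude 1
#' (direction-aware but magnitude-free).  Knockdown decreasing a gene
#' (negative log2fc) means the factors activate it, so the signature
#' tracks factor activity with weight +1 when `activity = TRUE`.
#'
#' @param targets joint target genes.
#' @param de_a,de_b DE tables containing `gene` and `log2fc`.
#' @param activity orient weights to factor activity (default) rather
#'   than raw knockdown response.
#' @return a [signature_definition()].
#' @export
joint_target_signature <- function(targets, de_a, de_b, activity = TRUE) {
  fc <- (de_a$log2fc[match(targets, de_a$gene)] +
           de_b$log2fc[match(targets, de_b$gene)]) / 2
  w <- sign(fc)
  w[is.na(w) | w == 0] <- 1
  if (activity) w <- -w  # knockdown-down = factor-activated
  signature_definition("joint_direct_targets", targets, w)
}

#' Score a signature across samples
#'
#' Each signature gene is z-normalized across samples (mean 0, sd 1)
#' and the per-sample score is the weighted sum of z-scores;
#' `mode = "z_sum"` forces all weights to +1.  Panel genes absent from
#' the matrix, or with zero variance, are skipped and reported; the
#' score of an empty effective panel is 0 for every sample (flagged).
#'
#' @param expr genes x samples expression matrix.
#' @param sig a [signature_definition()].
#' @param mode `"weighted_z_sum"` (default) or `"z_sum"`.
#' @return named numeric score vector over samples, with attributes
#'   `"skipped"` (genes not used) and `"n_used"`.
#' @export
score_signature <- function(expr, sig, mode = c("weighted_z_sum", "z_sum")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), inherits(sig, "SignatureDefinition"))
  present <- sig$genes %in% rownames(expr)
  if (!any(present))
    stop("no signature gene present in the expression matrix", call. = FALSE)
  genes <- sig$genes[present]
  w <- if (mode == "z_sum") rep(1, length(genes)) else sig$weights[present]
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  usable <- is.finite(sds) & sds > 0
  skipped <- c(sig$genes[!present], genes[!usable])
  if (length(genes[!usable]))
    warning(sum(!usable), " zero-variance signature gene(s) skipped")
  if (!any(usable)) {
    score <- setNames(rep(0, ncol(expr)), colnames(expr))
    attr(score, "skipped") <- skipped; attr(score, "n_used") <- 0L
    attr(score, "flag") <- "empty effective panel"
    return(score)
  }
  z <- (sub[usable, , drop = FALSE] -
          rowMeans(sub[usable, , drop = FALSE])) / sds[usable]
  score <- as.numeric(crossprod(z, w[usable]))
  names(score) <- colnames(expr)
  attr(score, "skipped") <- skipped
  attr(score, "n_used") <- sum(usable)
  score
}

#' Pearson correlation between two score vectors
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `r`, `p_value`, `n`, `flag`.
#' @export
correlate_scores <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n,
                flag = "zero variance"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n, flag = "none")
}

#' Packaged androgen-receptor signaling panel (30 genes)
#'
#' The 30-gene AR-signaling panel shipped with the package, unit
#' weights.
#'
#' @return a [signature_definition()].
#' @export
ar_signature_panel <- function() {
  path <- system.file("extdata", "ar_panel_30.tsv", package = "regcoop")
  tab <- read_tsv_strict(path)
  signature_definition("AR_signaling_30", tab$gene, tab$weight)
}

#' Read a signature panel from a two-column TSV (gene, weight)
#'
#' @param path TSV path; a missing `weight` column defaults to +1.
#' @param name signature name (defaults to the file name).
#' @return a [signature_definition()].
#' @export
read_signature_panel <- function(path, name = basename(path)) {
  tab <- read_tsv_strict(path)
  if (is.null(tab$gene)) stop("panel file needs a 'gene' column", call. = FALSE)
  w <- tab$weight %||% rep(1, nrow(tab))
  signature_definition(name, tab$gene, w)
}
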