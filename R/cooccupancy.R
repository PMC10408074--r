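# Two-factor chromatin co-occupancy classification and the standard
# differential-peak filter applied to scored (p-value, fold-change)
# peak tables.

#' Classify two peak sets into common/unique categories
#'
#' A peak is "common" iff it overlaps at least one peak of the other
#' set by `min_overlap` bases (default 1 bp).  Both sets are merged
#' internally if not already merged, so counts refer to merged regions.
#' Fractions are reported in both directions; e.g. `fraction_b` is the
#' share of B regions co-occupied by A.
#'
#' @param a,b [peak_set()] objects (e.g. two transcription factors'
#'   ChIP-seq peaks from the same cell line).
#' @param min_overlap minimum overlap in bp to call co-occupancy.
#' @return object of class `CooccupancyResult`: list with `n_a`, `n_b`,
#'   `n_common_a`, `n_common_b`, `fraction_a`, `fraction_b`, per-region
#'   label vectors `labels_a`/`labels_b` (`"common"`/`"unique"`), the
#'   merged sets, and `flag` (`"empty set"` when a fraction is
#'   undefined).
#' @export
classify_cooccupancy <- function(a, b, min_overlap = 1L) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  if (!isTRUE(attr(a, "merged"))) a <- merge_intervals(a)
  if (!isTRUE(attr(b, "merged"))) b <- merge_intervals(b)
  n_a <- nrow(a); n_b <- nrow(b)
  flag <- if (n_a == 0L || n_b == 0L) "empty set" else "none"
  hits <- intersect_intervals(a, b, min_overlap = min_overlap)
  common_a <- seq_len(n_a) %in% hits$idx_a
  common_b <- seq_len(n_b) %in% hits$idx_b
  structure(list(
    n_a = n_a, n_b = n_b,
    n_common_a = sum(common_a), n_common_b = sum(common_b),
    fraction_a = if (n_a) sum(common_a) / n_a else NA_real_,
    fraction_b = if (n_b) sum(common_b) / n_b else NA_real_,
    labels_a = ifelse(common_a, "common", "unique"),
    labels_b = ifelse(common_b, "common", "unique"),
    peaks_a = a, peaks_b = b, pairs = hits, flag = flag),
    class = "CooccupancyResult")
}

#' @export
print.CooccupancyResult <- function(x, ...) {
  cat(sprintf(
    "Co-occupancy: %d/%d A regions common (%.1f%%); %d/%d B regions common (%.1f%%)\n",
    x$n_common_a, x$n_a, 100 * x$fraction_a,
    x$n_common_b, x$n_b, 100 * x$fraction_b))
  invisible(x)
}

#' Three-way region classification from a co-occupancy result
#'
#' @param x a `CooccupancyResult`.
#' @return `data.frame` of regions labeled `"A_only"`, `"B_only"` or
#'   `"common"`; common regions are the merged union of the overlapping
#'   A and B regions.
#' @export
cooccupancy_regions <- function(x) {
  stopifnot(inherits(x, "CooccupancyResult"))
  a <- x$peaks_a; b <- x$peaks_b
  parts <- list()
  if (any(x$labels_a == "unique")) {
    u <- a[x$labels_a == "unique", , drop = FALSE]
    parts$A_only <- data.frame(chrom = u$chrom, start = u$start,
                               end = u$end, category = "A_only")
  }
  if (any(x$labels_b == "unique")) {
    u <- b[x$labels_b == "unique", , drop = FALSE]
    parts$B_only <- data.frame(chrom = u$chrom, start = u$start,
                               end = u$end, category = "B_only")
  }
  ca <- a[x$labels_a == "common", , drop = FALSE]
  cb <- b[x$labels_b == "common", , drop = FALSE]
  if (nrow(ca) + nrow(cb) > 0) {
    m <- merge_intervals(peak_set(c(ca$chrom, cb$chrom),
                                  c(ca$start, cb$start),
                                  c(ca$end, cb$end)))
    parts$common <- data.frame(chrom = m$chrom, start = m$start,
                               end = m$end, category = "common")
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Filter differential peaks on significance and fold change
#'
#' Keeps peaks with `p_value < p_max` and `fold_change > fc_min`, both
#' strict inequalities (a peak exactly at either threshold is dropped).
#'
#' @param peaks `data.frame` with at least `p_value` and `fold_change`
#'   columns (BED6+2 convention: interval columns plus the two scores).
#' @param p_max p-value cutoff (default `1e-4`).
#' @param fc_min fold-change cutoff (default 4).
#' @return the passing subset, rows in input order.
#' @export
filter_differential_peaks <- function(peaks, p_max = 1e-4, fc_min = 4) {
  stopifnot(is.data.frame(peaks))
  for (col in c("p_value", "fold_change")) {
    if (is.null(peaks[[col]]))
      stop("scored peaks lack a '", col, "' column", call. = FALSE)
    bad <- which(!is.finite(peaks[[col]]))
    if (length(bad))
      stop(sprintf("peak %s is missing %s",
                   peaks$name[bad[1L]] %||% as.character(bad[1L]), col),
           call. = FALSE)
  }
  peaks[peaks$p_value < p_max & peaks$fold_change > fc_min, , drop = FALSE]
}
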