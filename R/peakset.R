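# Genomic-interval engine.  All coordinates are 0-based half-open
# ([start, end), BED convention); every other module inherits this.
# Overlap machinery is delegated to IRanges behind the half-open facade
# (0-based [s, e) maps to the 1-based closed range [s + 1, e]).

#' Construct a PeakSet
#'
#' A `PeakSet` is a sorted table of genomic intervals in 0-based
#' half-open coordinates, the container used for transcription-factor
#' binding peaks and promoter windows throughout the package.
#'
#' @param chrom character vector of chromosome names (nonempty strings).
#' @param start,end integer vectors; `0 <= start < end`, end exclusive.
#' @param name optional interval labels.
#' @param score optional numeric scores.
#' @param strand strand codes in `+`, `-`, `.`.
#' @param label set-level identifier (e.g. `"GATA2:1F5"`).
#' @param merged logical; `TRUE` asserts no two intervals on one
#'   chromosome overlap (as produced by [merge_intervals()]).
#' @return a `data.frame` of class `PeakSet`, sorted by
#'   (chrom, start, end), with attributes `label` and `merged`.
#' @seealso [read_bed()], [merge_intervals()], [intersect_intervals()]
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NA_character_, score = NA_real_, strand = ".",
                     label = "", merged = FALSE) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  o <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"),
            label = label, merged = isTRUE(merged))
}

validate_intervals <- function(df, lines = NULL) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end |
                 is.na(df$chrom) | !nzchar(df$chrom) |
                 df$start != floor(df$start) | df$end != floor(df$end))
  if (length(bad)) {
    where <- if (is.null(lines)) sprintf("row %d", bad[1L])
             else sprintf("line %d", lines[bad[1L]])
    stop(sprintf("invalid interval at %s: chrom='%s' start=%s end=%s",
                 where, df$chrom[bad[1L]],
                 format(df$start[bad[1L]]), format(df$end[bad[1L]])),
         call. = FALSE)
  }
  if (any(df$strand %in% c("+", "-", ".") == FALSE))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d intervals on %d chromosome(s)%s\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom)),
              if (isTRUE(attr(x, "merged"))) " [merged]" else ""))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a BED3/BED6 file into a PeakSet
#'
#' Track, browser and `#` comment lines are skipped.  Columns 4-6 map to
#' name/score/strand when present.  Malformed lines (non-integer
#' coordinates, start >= end) raise an error naming the line number.
#'
#' @param path path to a BED file.
#' @param label label for the resulting set (defaults to the file name).
#' @param chr_normalize if `TRUE`, strip/keep a leading `"chr"` prefix so
#'   dialects agree; `"add"` forces the prefix, `"strip"` removes it.
#' @return a [peak_set()].
#' @export
read_bed <- function(path, label = basename(path), chr_normalize = "none") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
  lines <- which(keep)
  raw <- raw[keep]
  if (!length(raw))
    return(peak_set(label = label))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("line %d: fewer than 3 tab-separated fields",
                 lines[which(nf < 3L)[1L]]), call. = FALSE)
  getcol <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(getcol(2L, NA)))
  end <- suppressWarnings(as.numeric(getcol(3L, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("line %d: non-numeric coordinate", lines[bad[1L]]),
         call. = FALSE)
  chrom <- normalize_chrom(getcol(1L, ""), chr_normalize)
  name <- getcol(4L, NA_character_)
  score <- suppressWarnings(as.numeric(getcol(5L, NA_character_)))
  strand <- getcol(6L, ".")
  strand[!strand %in% c("+", "-")] <- "."
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  validate_intervals(df, lines = lines)
  peak_set(chrom, start, end, name, score, strand, label = label)
}

#' Write a PeakSet as BED
#'
#' Emits BED6 when any of name/score/strand is informative, else BED3.
#' Missing names become `"."` and missing scores `0`, per BED practice.
#'
#' @param p a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(p, path) {
  stopifnot(inherits(p, "PeakSet"))
  if (nrow(p) == 0L) { writeLines(character(), path); return(invisible(path)) }
  bed6 <- any(!is.na(p$name)) || any(!is.na(p$score)) || any(p$strand != ".")
  df <- if (bed6) {
    data.frame(p$chrom, format(p$start, scientific = FALSE, trim = TRUE),
               format(p$end, scientific = FALSE, trim = TRUE),
               ifelse(is.na(p$name), ".", p$name),
               ifelse(is.na(p$score), 0, p$score), p$strand)
  } else {
    data.frame(p$chrom, format(p$start, scientific = FALSE, trim = TRUE),
               format(p$end, scientific = FALSE, trim = TRUE))
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize chromosome-name dialects
#'
#' @param chrom character vector of chromosome names.
#' @param mode `"none"` (exact-string matching elsewhere), `"add"`
#'   (ensure a `"chr"` prefix) or `"strip"` (remove it).
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom, mode = c("none", "add", "strip")) {
  mode <- match.arg(mode)
  if (mode == "strip") sub("^chr", "", chrom)
  else if (mode == "add") ifelse(grepl("^chr", chrom), chrom,
                                 paste0("chr", chrom))
  else chrom
}

# one IRanges per chromosome; 0-based half-open -> 1-based closed
.iranges_by_chrom <- function(p) {
  split(IRanges::IRanges(start = p$start + 1L, end = p$end),
        factor(p$chrom, levels = unique(p$chrom)))
}

#' Merge overlapping and book-ended intervals
#'
#' Overlapping or book-ended (end == start) intervals on the same
#' chromosome are unioned.  Total covered bases are preserved; name,
#' score and strand are dropped (set to `.`/`NA`) since merged regions
#' no longer correspond to single input records.
#'
#' @param p a [peak_set()].
#' @return a merged [peak_set()] with `merged = TRUE`.
#' @export
merge_intervals <- function(p) {
  stopifnot(inherits(p, "PeakSet"))
  if (nrow(p) == 0L)
    return(peak_set(label = attr(p, "label"), merged = TRUE))
  out <- lapply(split(p[, c("start", "end")], p$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                          min.gapwidth = 1L)
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  chrom <- rep(names(out), vapply(out, nrow, 0L))
  d <- do.call(rbind, out)
  peak_set(chrom, d$start, d$end, label = attr(p, "label"), merged = TRUE)
}

#' All overlapping interval pairs between two PeakSets
#'
#' Every pair `(i, j)` with `a[i]` and `b[j]` overlapping by at least
#' `min_overlap` bases is returned exactly once.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap minimum overlap in bases (default 1).
#' @return `data.frame` with columns `idx_a`, `idx_b` (row indices into
#'   the sorted sets) and `overlap_bp`.
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"),
            min_overlap >= 1L)
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      overlap_bp = integer())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  res <- empty
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = min_overlap)
    if (length(hits)) {
      qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
      ov <- pmin(a$end[ia][qa], b$end[ib][qb]) -
        pmax(a$start[ia][qa], b$start[ib][qb])
      res <- rbind(res, data.frame(idx_a = ia[qa], idx_b = ib[qb],
                                   overlap_bp = ov))
    }
  }
  res <- res[order(res$idx_a, res$idx_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Promoter windows around transcription start sites
#'
#' One symmetric window `[max(0, tss - flank), tss + flank)` per gene.
#' Strand does not change the window (a TSS +/- flank rule is symmetric
#' by construction); windows are clipped at position 0.
#'
#' @param genes `data.frame` with columns `gene`, `chrom`, `tss`
#'   (0-based), `strand` (`+`/`-`).
#' @param flank half-width in bp (default 5000, i.e. TSS +/- 5 kb).
#' @return a [peak_set()] whose `name` column carries the gene symbol.
#' @export
promoter_windows <- function(genes, flank = 5000L) {
  stopifnot(is.data.frame(genes), flank > 0,
            all(c("gene", "chrom", "tss") %in% names(genes)))
  if (anyDuplicated(genes$gene))
    stop("gene symbols must be unique in the annotation", call. = FALSE)
  if (!is.null(genes$strand) && any(!genes$strand %in% c("+", "-")))
    stop("unknown strand code in gene annotation", call. = FALSE)
  if (any(genes$tss < 0)) stop("tss must be >= 0", call. = FALSE)
  peak_set(genes$chrom, pmax(0, genes$tss - flank), genes$tss + flank,
           name = genes$gene,
           strand = if (is.null(genes$strand)) "." else genes$strand,
           label = sprintf("promoters:%dbp", flank))
}

#' Flag genomic points falling inside a PeakSet
#'
#' A point is inside iff `start <= pos < end` for some interval
#' (half-open at both boundaries).
#'
#' @param chrom,pos parallel vectors of 0-based point positions.
#' @param p a [peak_set()].
#' @return logical vector, one flag per point.
#' @export
assign_points_to_peaks <- function(chrom, pos, p) {
  stopifnot(length(chrom) == length(pos), inherits(p, "PeakSet"))
  inside <- logical(length(pos))
  if (!length(pos) || nrow(p) == 0L) return(inside)
  for (ch in intersect(unique(chrom), unique(p$chrom))) {
    ip <- which(chrom == ch); jp <- which(p$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(pos[ip] + 1L, pos[ip] + 1L),
      IRanges::IRanges(p$start[jp] + 1L, p$end[jp]))
    inside[ip[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  inside
}

#' Read a gene annotation table (gene, chrom, tss, strand)
#'
#' @param path TSV path with header columns `gene`, `chrom`, `tss`,
#'   `strand`.
#' @return validated `data.frame`.
#' @export
read_gene_annotation <- function(path) {
  g <- read_tsv_strict(path)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(g)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(g$gene)) stop("duplicate gene symbols", call. = FALSE)
  g$tss <- as.numeric(g$tss)
  g
}
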