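# Position-weight-matrix scoring: log2-odds scan against a background
# model, and the allele-affinity delta used to ask whether a risk
# allele completes or breaks a binding motif.

#' Construct a position probability matrix model
#'
#' @param mat L x 4 matrix of per-position base probabilities, columns
#'   in A, C, G, T order; rows must sum to 1 within 1e-9 after the
#'   pseudocount is applied.
#' @param id motif identifier.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount probability mass added to every cell before
#'   renormalization so all entries are positive (default 1e-4).
#' @return object of class `PWM`.
#' @export
pwm_model <- function(mat, id = "motif", background = rep(0.25, 4),
                      pseudocount = 1e-4) {
  stopifnot(is.matrix(mat), ncol(mat) == 4, all(mat >= 0),
            length(background) == 4, all(background > 0))
  colnames(mat) <- c("A", "C", "G", "T")
  mat <- mat + pseudocount
  mat <- mat / rowSums(mat)
  background <- background / sum(background)
  if (any(abs(rowSums(mat) - 1) > 1e-9))
    stop("PWM rows do not sum to 1", call. = FALSE)
  structure(list(id = id, mat = mat, background = background,
                 pseudocount = pseudocount, L = nrow(mat)),
            class = "PWM")
}

#' Read a PWM probability file
#'
#' Four-column probability matrix (A, C, G, T order) with a header row.
#'
#' @param path TSV path.
#' @param id motif id (defaults to file name).
#' @param ... passed to [pwm_model()].
#' @return a [pwm_model()].
#' @export
read_pwm <- function(path, id = basename(path), ...) {
  tab <- read_tsv_strict(path)
  stopifnot(all(c("A", "C", "G", "T") %in% names(tab)))
  pwm_model(as.matrix(tab[, c("A", "C", "G", "T")]), id = id, ...)
}

#' Write a PWM probability file
#' @param pwm a [pwm_model()].
#' @param path output TSV path.
#' @export
write_pwm <- function(pwm, path) {
  write_tsv(as.data.frame(pwm$mat), path)
}

.base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# log2-odds score of one exact-length window
.pwm_score_window <- function(pwm, window) {
  idx <- .base_idx[strsplit(window, "")[[1]]]
  if (anyNA(idx)) stop("non-ACGT character in sequence", call. = FALSE)
  sum(log2(pwm$mat[cbind(seq_len(pwm$L), idx)] / pwm$background[idx]))
}

#' Best log2-odds PWM score over placements covering one position
#'
#' Scans every placement of the motif window that covers `pos`, on both
#' strands, and returns the maximum score.
#'
#' @param pwm a [pwm_model()].
#' @param seq DNA string (A/C/G/T).
#' @param pos 1-based position within `seq` that every placement must
#'   cover; `NULL` scans the whole sequence.
#' @return maximum log2-odds score.
#' @export
pwm_best_score <- function(pwm, seq, pos = NULL) {
  L <- pwm$L
  n <- nchar(seq)
  if (n < L) stop("sequence shorter than the motif", call. = FALSE)
  starts <- if (is.null(pos)) seq_len(n - L + 1L)
            else max(1L, pos - L + 1L):min(pos, n - L + 1L)
  best <- -Inf
  for (s in starts) {
    win <- substr(seq, s, s + L - 1L)
    best <- max(best, .pwm_score_window(pwm, win),
                .pwm_score_window(pwm, revcomp(win)))
  }
  best
}

#' Allele-affinity delta at a SNP
#'
#' Scores the sequence with the reference and the alternate allele
#' substituted at the SNP position, maximizing the log2-odds PWM score
#' over all placements covering the SNP and both strands.  The delta is
#' signed risk-minus-other, so a positive delta means the risk allele
#' is the preferred (higher-affinity) allele.
#'
#' @param pwm a [pwm_model()].
#' @param seq DNA string covering at least `L - 1` bases on each side
#'   of the SNP; must carry the reference allele at `snp_pos`.
#' @param snp_pos 1-based SNP position within `seq`.
#' @param ref,alt reference and alternate alleles (single bases).
#' @param risk_allele which of `ref`/`alt` is the risk allele
#'   (default `alt`).
#' @return list with `score_ref`, `score_alt`, `delta`,
#'   `preferred_allele`.
#' @export
pwm_allele_delta <- function(pwm, seq, snp_pos, ref, alt,
                             risk_allele = alt) {
  seq <- toupper(seq)
  stopifnot(ref %in% names(.base_idx), alt %in% names(.base_idx),
            ref != alt, risk_allele %in% c(ref, alt))
  if (substr(seq, snp_pos, snp_pos) != ref)
    stop(sprintf("sequence has '%s' at the SNP position, expected ref '%s'",
                 substr(seq, snp_pos, snp_pos), ref), call. = FALSE)
  sub_at <- function(s, base) {
    substr(s, snp_pos, snp_pos) <- base
    s
  }
  score_ref <- pwm_best_score(pwm, sub_at(seq, ref), snp_pos)
  score_alt <- pwm_best_score(pwm, sub_at(seq, alt), snp_pos)
  delta <- if (identical(risk_allele, alt)) score_alt - score_ref
           else score_ref - score_alt
  preferred <- if (score_ref > score_alt) ref
               else if (score_alt > score_ref) alt
               else "tie"
  list(score_ref = score_ref, score_alt = score_alt,
       delta = delta, preferred_allele = preferred)
}
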