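#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test pt p.adjust fisher.test binom.test rnorm
#'   runif rbinom rexp rlnorm median sd pchisq qnorm quantile setNames
#'   complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

# Derive a reproducible 31-bit sub-seed from a master seed and a stream
# name, so that adding one generator never perturbs the draws of another.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(seed) * 2654435 + h) %% 2147483647)
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}

read_tsv_strict <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
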