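#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# scenario seed fully determines every output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_that <- function(ok, msg, class = "tnseqsi_error") {
  if (!isTRUE(ok)) abort(msg, class = c(class, "tnseqsi_error"))
  invisible(TRUE)
}

# Vectorised reverse complement on plain character vectors.
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between each string in `x` and the single string `y`,
# comparing only the first nchar(y) characters. Strings shorter than y
# get distance Inf.
prefix_mismatches <- function(x, y) {
  k <- nchar(y)
  yraw <- charToRaw(y)
  vapply(x, function(s) {
    if (nchar(s) < k) return(Inf)
    sum(charToRaw(substr(s, 1L, k)) != yraw)
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
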