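#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors, which is how sequences travel inside this
#' package.
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic 32-bit sub-seed for a named random substream. Every stage and
# library draws from its own stream derived from the single study seed, so
# stages are individually reproducible.
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

# Uniform integer draw from [lo, hi], safe for degenerate ranges (avoids
# base sample()'s scalar expansion).
sample_range <- function(lo, hi, n = 1) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# Random DNA string(s) of the given lengths, uniform over A/C/G/T.
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# 0-based half-open substring of a sequence string.
subseq0 <- function(seq, start, end) {
  stringr::str_sub(seq, start + 1, end)
}

fmt_lib <- function(tissue, age, replicate) {
  paste(tissue, age, replicate, sep = "_")
}
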