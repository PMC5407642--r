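# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic entry points funnel
# through this so no stage consumes ambient randomness.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

str_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  str_rev(chartr("ACGTN", "TGCAN", x))
}

# DNA <-> RNA display conversion (storage alphabet is DNA).
dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)

# 0-based half-open interval overlap (vectorised over data.frame rows).
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
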