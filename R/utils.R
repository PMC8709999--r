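#' Nearest-integer rounding, halves away from zero
#'
#' Rounding convention used when converting the contaminant fraction of
#' ambiguous reads into a removal count. R's `round()` rounds halves to even;
#' decontamination instead rounds halves away from zero so that e.g. 0.5 of
#' one ambiguous read removes one read.
#'
#' @param x numeric vector.
#' @return integer vector, `sign(x) * floor(|x| + 0.5)`.
#' @examples
#' nint(c(0.5, 1.5, 2.4, -0.5))
#' @export
nint <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

## reverse a character string (no complement): used to orient clipped
## overhangs away from the exon on the left/5' side
str_rev <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## run an expression with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
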