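# shared internal helpers

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded generator code
#' never perturbs the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based half-open interval overlap
#' @noRd
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' @noRd
check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  x
}

# sequence input: accept character or XString(Set element)
#' @noRd
as_seq_chr <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet"))
    x <- as.character(x)
  if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
  toupper(unname(x))
}
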