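# Tetrapolar compatibility rule and the pairwise compatibility matrix.

#' Are two mating genotypes sexually compatible?
#'
#' Under the tetrapolar rule two monokaryons are compatible iff their
#' alleles differ at BOTH mating-type loci; under the bipolar mode only
#' the A locus is compared. Unknown (`NA`) alleles propagate as `NA`
#' (indeterminate), never as silently compatible. Self-crosses are
#' incompatible.
#'
#' @param g1,g2 Lists (or one-row data frames) with `a_allele` and
#'   `b_allele`.
#' @param mode `"tetrapolar"` (default) or `"bipolar"`.
#' @return `TRUE`, `FALSE`, or `NA`.
#' @examples
#' compatible(list(a_allele = "A1", b_allele = "B1"),
#'            list(a_allele = "A2", b_allele = "B2"))
#' @export
compatible <- function(g1, g2, mode = c("tetrapolar", "bipolar")) {
  mode <- match.arg(mode)
  a1 <- g1$a_allele; a2 <- g2$a_allele
  b1 <- g1$b_allele; b2 <- g2$b_allele
  if (is.null(a1) || is.null(a2) ||
      (mode == "tetrapolar" && (is.null(b1) || is.null(b2))))
    stop("genotype with missing allele field", call. = FALSE)
  a_diff <- if (is.na(a1) || is.na(a2)) NA else a1 != a2
  if (mode == "bipolar") return(a_diff)
  b_diff <- if (is.na(b1) || is.na(b2)) NA else b1 != b2
  a_diff & b_diff
}

#' Pairwise compatibility matrix over a set of strains
#'
#' Evaluates [compatible()] on every unordered strain pair. The matrix is
#' symmetric with a `FALSE` diagonal.
#'
#' @param genotypes A `mating_genotypes` data frame (columns `strain`,
#'   `a_allele`, `b_allele`) with unique strain names, >= 2 strains.
#' @param mode Passed to [compatible()].
#' @return Object of class `compatibility_matrix`: `strains`, `matrix`
#'   (logical), `compatible_pairs` (data frame `strain1`, `strain2`),
#'   `n_compatible`, `n_indeterminate`.
#' @export
compatibility_matrix <- function(genotypes,
                                 mode = c("tetrapolar", "bipolar")) {
  mode <- match.arg(mode)
  strains <- genotypes$strain
  if (length(strains) < 2L) stop("need at least 2 strains", call. = FALSE)
  if (anyDuplicated(strains))
    stop("duplicate strain names", call. = FALSE)
  n <- length(strains)
  m <- matrix(FALSE, n, n, dimnames = list(strains, strains))
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- compatible(as.list(genotypes[i, ]), as.list(genotypes[j, ]), mode)
    m[i, j] <- v; m[j, i] <- v
    if (isTRUE(v))
      pairs[[length(pairs) + 1L]] <- data.frame(
        strain1 = strains[i], strain2 = strains[j],
        stringsAsFactors = FALSE)
  }
  cp <- if (length(pairs)) do.call(rbind, pairs)
        else data.frame(strain1 = character(), strain2 = character(),
                        stringsAsFactors = FALSE)
  structure(list(strains = strains, matrix = m, compatible_pairs = cp,
                 n_compatible = nrow(cp),
                 n_indeterminate = sum(is.na(m[upper.tri(m)]))),
            class = "compatibility_matrix")
}

#' @export
print.compatibility_matrix <- function(x, ...) {
  cat(sprintf("compatibility_matrix: %d strain(s), %d compatible pair(s)",
              length(x$strains), x$n_compatible))
  if (x$n_indeterminate)
    cat(sprintf(" [%d indeterminate]", x$n_indeterminate))
  cat("\n")
  if (x$n_compatible)
    for (i in seq_len(nrow(x$compatible_pairs)))
      cat(sprintf("  %s x %s\n", x$compatible_pairs$strain1[i],
                  x$compatible_pairs$strain2[i]))
  invisible(x)
}
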