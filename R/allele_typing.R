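# Pairwise global protein identity, allele classing, mating genotypes.

#' Global pairwise protein identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 1
#' by default); identity is matches over alignment columns, with gap
#' columns counted in the denominator (switch `denominator = "aligned"`
#' to exclude them). The result is symmetric under argument swap: the two
#' sequences are ordered canonically before alignment so co-optimal
#' traceback ties cannot break symmetry.
#'
#' @param p1,p2 Protein sequences (character or `AAString`). Trailing `*`
#'   is stripped.
#' @param ids Optional length-2 character vector of sequence ids.
#' @param substitution_matrix Scoring matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend Gap penalties (positive costs; defaults 10
#'   and 1).
#' @param denominator `"columns"` (all alignment columns, default) or
#'   `"aligned"` (gapless columns only).
#' @return Object of class `identity_result`: `query_id`, `subject_id`,
#'   `identity_percent` (2-decimal), `aligned_columns`, `matches`.
#' @examples
#' global_identity("ACDEFG", "ACDEYG")
#' @export
global_identity <- function(p1, p2, ids = c("query", "subject"),
                            substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 1,
                            denominator = c("columns", "aligned")) {
  denominator <- match.arg(denominator)
  p1 <- sub("\\*+$", "", as_seq_chr(p1))
  p2 <- sub("\\*+$", "", as_seq_chr(p2))
  if (!nzchar(p1) || !nzchar(p2))
    stop("empty protein sequence", call. = FALSE)
  # canonical order for symmetry under argument swap
  swapped <- p1 > p2
  a <- if (swapped) p2 else p1
  b <- if (swapped) p1 else p2
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pat)
  matches <- Biostrings::nmatch(aln)
  denom <- if (denominator == "columns") cols
           else sum(strsplit(pat, "")[[1]] != "-" &
                    strsplit(sub, "")[[1]] != "-")
  structure(list(query_id = ids[1], subject_id = ids[2],
                 identity_percent = round(100 * matches / denom, 2),
                 aligned_columns = cols, matches = matches),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %.2f%% identity (%d/%d columns)\n",
              x$query_id, x$subject_id, x$identity_percent,
              x$matches, x$aligned_columns))
  invisible(x)
}

#' All-vs-all global identity matrix
#'
#' @param proteins Named character vector of protein sequences.
#' @param ... Passed to [global_identity()].
#' @return Symmetric numeric matrix of identity percentages (100 on the
#'   diagonal).
#' @export
identity_matrix <- function(proteins, ...) {
  n <- length(proteins)
  ids <- names(proteins)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- global_identity(proteins[[i]], proteins[[j]],
                           ids = ids[c(i, j)], ...)$identity_percent
      m[i, j] <- v; m[j, i] <- v
    }
  m
}

#' Group strains into allele classes by exact marker-protein identity
#'
#' Strains whose marker proteins are byte-identical (across all markers)
#' share an allele label; labels are numbered in first-seen strain order
#' (`A1`, `A2`, ... or `B1`, `B2`, ...). The full pairwise identity
#' matrix of every marker is attached as evidence.
#'
#' @param marker_proteins Either a named character vector (strain ->
#'   protein) or a named list of such vectors (marker -> strain vector,
#'   all over the same strain set).
#' @param locus `"A"` or `"B"`.
#' @return Object of class `allele_assignment`: `locus`, `assignment`
#'   (data frame `strain`, `allele`), `evidence` (named list of identity
#'   matrices, one per marker).
#' @export
assign_alleles <- function(marker_proteins, locus = c("A", "B")) {
  locus <- match.arg(locus)
  if (!is.list(marker_proteins))
    marker_proteins <- list(marker = marker_proteins)
  strains <- names(marker_proteins[[1]])
  if (is.null(strains) || length(strains) < 1L)
    stop("marker proteins must be named by strain", call. = FALSE)
  for (m in marker_proteins)
    if (!identical(names(m), strains))
      stop("markers disagree on the strain set", call. = FALSE)
  key <- vapply(strains, function(s)
    paste(vapply(marker_proteins, function(m) as_seq_chr(m[[s]]),
                 character(1)), collapse = "|"), character(1))
  labels <- paste0(locus, match(key, unique(key)))
  evidence <- lapply(marker_proteins, function(m)
    identity_matrix(stats::setNames(vapply(m, as_seq_chr, character(1)),
                                    strains)))
  structure(list(locus = locus,
                 assignment = data.frame(strain = strains, allele = labels,
                                         stringsAsFactors = FALSE,
                                         row.names = NULL),
                 evidence = evidence),
            class = "allele_assignment")
}

#' @export
print.allele_assignment <- function(x, ...) {
  cat(sprintf("%s-locus alleles (%d class(es)):\n", x$locus,
              length(unique(x$assignment$allele))))
  for (i in seq_len(nrow(x$assignment)))
    cat(sprintf("  %s: %s\n", x$assignment$strain[i],
                x$assignment$allele[i]))
  invisible(x)
}

#' Combine A- and B-locus allele assignments into mating genotypes
#'
#' @param a,b `allele_assignment` objects for the A and B loci over the
#'   same strain set.
#' @return Object of class `mating_genotypes`: a data frame with columns
#'   `strain`, `a_allele`, `b_allele`, `composite` (e.g. `"A1B1"`).
#' @export
genotype_strains <- function(a, b) {
  stopifnot(inherits(a, "allele_assignment"),
            inherits(b, "allele_assignment"))
  sa <- a$assignment$strain; sb <- b$assignment$strain
  if (!setequal(sa, sb))
    stop("strain sets differ: ",
         paste(c(setdiff(sa, sb), setdiff(sb, sa)), collapse = ", "),
         call. = FALSE)
  bb <- b$assignment$allele[match(sa, sb)]
  out <- data.frame(strain = sa, a_allele = a$assignment$allele,
                    b_allele = bb,
                    composite = paste0(a$assignment$allele, bb),
                    stringsAsFactors = FALSE)
  class(out) <- c("mating_genotypes", "data.frame")
  out
}
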