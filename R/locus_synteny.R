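# Locus-scale microsynteny: reciprocal-best gene pairing, inversion and
# insertion calls, and strain-specific gene detection.

#' Pair the genes of two locus regions by reciprocal best identity
#'
#' Computes all-vs-all global identities between the member-gene proteins
#' of the two loci; pairs that are reciprocal best (row and column maxima,
#' first index on ties) with identity at or above `match_threshold`
#' become `matched`; remaining genes become `inserted_in_a` /
#' `inserted_in_b`. Every gene of both loci appears in exactly one pairing.
#'
#' @param locus_a,locus_b `locus_region` objects.
#' @param proteins_a,proteins_b Named character vectors of proteins
#'   covering every member gene of the respective locus.
#' @param match_threshold Minimum identity percent for a match (default
#'   30; cross-allele mating-type genes can sit in the 35% range and must
#'   still pair).
#' @param ... Passed to [global_identity()].
#' @return Data frame of class `gene_pairing`: `gene_a`, `gene_b` (either
#'   may be `NA`), `identity_percent`, `relation`.
#' @export
match_locus_genes <- function(locus_a, locus_b, proteins_a, proteins_b,
                              match_threshold = 30, ...) {
  ga <- locus_a$members$gene_id
  gb <- locus_b$members$gene_id
  miss <- c(setdiff(ga, names(proteins_a)), setdiff(gb, names(proteins_b)))
  if (length(miss))
    stop("missing protein for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  na <- length(ga); nb <- length(gb)
  m <- matrix(0, na, nb, dimnames = list(ga, gb))
  for (i in seq_len(na)) for (j in seq_len(nb))
    m[i, j] <- global_identity(proteins_a[[ga[i]]], proteins_b[[gb[j]]],
                               ids = c(ga[i], gb[j]), ...)$identity_percent
  rows <- list()
  matched_a <- character(); matched_b <- character()
  if (na && nb)
    for (i in seq_len(na)) {
      j <- which.max(m[i, ])
      if (which.max(m[, j]) == i && m[i, j] >= match_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ga[i], gene_b = gb[j], identity_percent = m[i, j],
          relation = "matched", stringsAsFactors = FALSE)
        matched_a <- c(matched_a, ga[i]); matched_b <- c(matched_b, gb[j])
      }
    }
  for (g in setdiff(ga, matched_a))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = g, gene_b = NA_character_, identity_percent = NA_real_,
      relation = "inserted_in_a", stringsAsFactors = FALSE)
  for (g in setdiff(gb, matched_b))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = NA_character_, gene_b = g, identity_percent = NA_real_,
      relation = "inserted_in_b", stringsAsFactors = FALSE)
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene_a = character(), gene_b = character(),
                         identity_percent = numeric(),
                         relation = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_pairing", "data.frame")
  out
}

#' Call the locus architecture from gene pairings
#'
#' Matched pairs are ordered by locus-A coordinates; maximal runs (length
#' >= 2) in which the locus-B order is strictly decreasing are reported
#' as inversions. Unmatched genes are grouped into per-locus insertion
#' sets.
#'
#' @param pairings A `gene_pairing` data frame from [match_locus_genes()].
#' @param locus_a,locus_b The `locus_region` objects the pairing was
#'   computed from (for gene coordinates).
#' @return Object of class `architecture_call`: `pairings` (matched pairs
#'   in locus-A order), `inversions` (list of character vectors of
#'   locus-A gene ids), `insertions_a`, `insertions_b`.
#' @export
call_architecture <- function(pairings, locus_a, locus_b) {
  matched <- pairings[pairings$relation == "matched", , drop = FALSE]
  ord_a <- locus_a$members$gene_id[order(locus_a$members$start)]
  ord_b <- locus_b$members$gene_id[order(locus_b$members$start)]
  matched <- matched[order(match(matched$gene_a, ord_a)), , drop = FALSE]
  rownames(matched) <- NULL
  inversions <- list()
  if (nrow(matched) >= 2L) {
    br <- match(matched$gene_b, ord_b)
    run_start <- 1L
    for (k in 2:(nrow(matched) + 1L)) {
      desc <- k <= nrow(matched) && br[k] < br[k - 1L]
      if (!desc) {
        if (k - run_start >= 2L)
          inversions[[length(inversions) + 1L]] <-
            matched$gene_a[run_start:(k - 1L)]
        run_start <- k
      }
    }
  }
  structure(list(
    pairings = matched,
    inversions = inversions,
    insertions_a = pairings$gene_a[pairings$relation == "inserted_in_a"],
    insertions_b = pairings$gene_b[pairings$relation == "inserted_in_b"]),
    class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(sprintf(
    "architecture_call: %d matched pair(s), %d inversion(s), %d + %d inserted\n",
    nrow(x$pairings), length(x$inversions),
    length(x$insertions_a), length(x$insertions_b)))
  invisible(x)
}

#' Find strain-specific genes between two proteomes
#'
#' A cross-proteome hit is a pair whose local (Smith-Waterman) alignment
#' has identity at or above `min_identity` percent over at least
#' `min_coverage` of the query length; genes with zero hits in either
#' direction are strain-specific. This replaces a BLASTP e-value screen
#' with an explicit identity-plus-coverage rule (the 40% minimal
#' alignment-length fraction is kept).
#'
#' @param proteome_a,proteome_b Named character vectors of proteins
#'   (non-empty).
#' @param min_identity Minimum local identity percent (default 30).
#' @param min_coverage Minimum aligned fraction of the query length
#'   (default 0.4).
#' @param substitution_matrix,gap_open,gap_extend Local-alignment scoring
#'   (defaults BLOSUM62, 10, 1).
#' @return List with character vectors `a_specific` and `b_specific`.
#' @export
find_strain_specific_genes <- function(proteome_a, proteome_b,
                                       min_identity = 30,
                                       min_coverage = 0.4,
                                       substitution_matrix = "BLOSUM62",
                                       gap_open = 10, gap_extend = 1) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("empty proteome", call. = FALSE)
  ids_a <- names(proteome_a); ids_b <- names(proteome_b)
  pa <- Biostrings::AAStringSet(vapply(proteome_a, function(p)
    sub("\\*+$", "", as_seq_chr(p)), character(1)))
  pb <- vapply(proteome_b, function(p) sub("\\*+$", "", as_seq_chr(p)),
               character(1))
  len_a <- Biostrings::width(pa)
  hit_a <- rep(FALSE, length(pa)); hit_b <- rep(FALSE, length(pb))
  for (j in seq_along(pb)) {
    aln <- Biostrings::pairwiseAlignment(
      pa, Biostrings::AAString(pb[[j]]), type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend)
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub_ <- as.character(Biostrings::alignedSubject(aln))
    matches <- Biostrings::nmatch(aln)
    cols <- nchar(pat)
    ident <- ifelse(cols > 0, 100 * matches / cols, 0)
    cov_a <- nchar(gsub("-", "", pat)) / len_a
    cov_b <- nchar(gsub("-", "", sub_)) / nchar(pb[[j]])
    hit_any <- ident >= min_identity & (cov_a >= min_coverage |
                                        cov_b >= min_coverage)
    hit_a <- hit_a | hit_any
    hit_b[j] <- any(hit_any)
  }
  list(a_specific = ids_a[!hit_a], b_specific = ids_b[!hit_b])
}
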