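# A (HD) mating-type locus discovery: divergently transcribed HD1/HD2 pair.

#' Test whether two genes form a head-to-head (divergent) pair
#'
#' Two genes on the same chromosome are head-to-head when the leftmost is
#' on the minus strand, the rightmost on the plus strand, their intervals
#' do not overlap, and the intergenic gap is at most `max_gap` — i.e. they
#' are transcribed away from each other with facing 5' ends. Overlapping
#' divergent genes are rejected. The test is symmetric in its arguments.
#'
#' @param g1,g2 Gene models (lists with `chrom`, `start`, `end`, `strand`,
#'   e.g. from [get_gene()]).
#' @param max_gap Maximum intergenic gap in bp (default 10000).
#' @return Logical scalar.
#' @export
is_head_to_head <- function(g1, g2, max_gap = 10000L) {
  if (!identical(g1$chrom, g2$chrom))
    stop("genes lie on different chromosomes", call. = FALSE)
  if (g1$start > g2$start) { tmp <- g1; g1 <- g2; g2 <- tmp }
  if (g1$end > g2$start) return(FALSE)            # overlap (or touching ok)
  g1$strand == "-" && g2$strand == "+" && (g2$start - g1$end) <= max_gap
}

#' Find candidate HD1/HD2 divergent gene pairs
#'
#' Candidate homeodomain genes are those whose functional label matches any
#' keyword (case-insensitive substring). Every unordered candidate pair
#' passing [is_head_to_head()] is returned, sorted by intergenic gap
#' ascending.
#'
#' @param annots An `annotation_set`.
#' @param keywords Label keywords (defaults: homeobox, homeodomain, HD1,
#'   HD2).
#' @param max_gap Maximum intergenic gap in bp.
#' @return A list of `hd_pair` objects: `hd1` (left, minus-strand gene),
#'   `hd2` (right, plus-strand gene), `intergenic_gap`, `orientation`.
#' @export
find_hd_pairs <- function(annots,
                          keywords = c("homeobox", "homeodomain",
                                       "HD1", "HD2"),
                          max_gap = 10000L) {
  stopifnot(inherits(annots, "annotation_set"))
  cand <- annots$genes[label_matches(annots$genes$label, keywords), ,
                       drop = FALSE]
  pairs <- list()
  if (nrow(cand) >= 2L) {
    idx <- utils::combn(nrow(cand), 2L)
    for (k in seq_len(ncol(idx))) {
      a <- as.list(cand[idx[1, k], ]); b <- as.list(cand[idx[2, k], ])
      if (!identical(a$chrom, b$chrom)) next
      if (!is_head_to_head(a, b, max_gap)) next
      if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
      pairs[[length(pairs) + 1L]] <- structure(
        list(hd1 = get_gene(annots, a$gene_id),
             hd2 = get_gene(annots, b$gene_id),
             intergenic_gap = b$start - a$end,
             orientation = "head_to_head"),
        class = "hd_pair")
    }
  }
  pairs[order(vapply(pairs, `[[`, 0, "intergenic_gap"))]
}

# case-insensitive fixed-substring label matching against a keyword list
#' @noRd
label_matches <- function(labels, keywords) {
  hit <- rep(FALSE, length(labels))
  for (k in keywords)
    hit <- hit | grepl(k, labels, ignore.case = TRUE, fixed = FALSE)
  hit
}

#' Delimit a locus region around anchor genes
#'
#' The span is the union of the anchor gene intervals extended by `flank`
#' on both sides, clipped to the chromosome; member genes are all genes
#' overlapping the span, in coordinate order.
#'
#' @param anchor_ids Character vector of anchor gene ids (all on one
#'   chromosome).
#' @param annots An `annotation_set`.
#' @param flank Flank extension in bp.
#' @param locus_type `"A"` or `"B"`.
#' @param chrom_len Chromosome length for clipping (optional; if `NULL`,
#'   the right edge is not clipped).
#' @return An object of class `locus_region`: `locus_type`, `chrom`,
#'   `start`, `end` (0-based half-open), `members` (gene data frame in
#'   coordinate order), `anchor_ids`.
#' @export
define_locus <- function(anchor_ids, annots, flank = 30000L,
                         locus_type = c("A", "B"), chrom_len = NULL) {
  locus_type <- match.arg(locus_type)
  stopifnot(inherits(annots, "annotation_set"))
  g <- annots$genes
  i <- match(anchor_ids, g$gene_id)
  if (anyNA(i))
    stop("anchor gene(s) not in annotation: ",
         paste(anchor_ids[is.na(i)], collapse = ", "), call. = FALSE)
  chrom <- unique(g$chrom[i])
  if (length(chrom) != 1L)
    stop("anchors span multiple chromosomes", call. = FALSE)
  span_start <- max(0L, min(g$start[i]) - as.integer(flank))
  span_end <- max(g$end[i]) + as.integer(flank)
  if (!is.null(chrom_len)) span_end <- min(span_end, as.integer(chrom_len))
  memb <- g[g$chrom == chrom & overlaps(g$start, g$end, span_start, span_end),
            , drop = FALSE]
  memb <- memb[order(memb$start, memb$gene_id), , drop = FALSE]
  memb <- memb[!duplicated(memb$gene_id), , drop = FALSE]
  rownames(memb) <- NULL
  structure(list(locus_type = locus_type, chrom = chrom,
                 start = span_start, end = span_end,
                 members = memb, anchor_ids = anchor_ids),
            class = "locus_region")
}

#' @export
print.locus_region <- function(x, ...) {
  cat(sprintf("%s locus on %s: [%d, %d) (%.1f kb), %d gene(s); anchors: %s\n",
              x$locus_type, x$chrom, x$start, x$end,
              (x$end - x$start) / 1000, nrow(x$members),
              paste(x$anchor_ids, collapse = ", ")))
  invisible(x)
}

#' @export
print.hd_pair <- function(x, ...) {
  cat(sprintf(
    "hd_pair on %s: %s [-] <- %d bp -> %s [+] (head-to-head)\n",
    x$hd1$chrom, x$hd1$gene_id, x$intergenic_gap, x$hd2$gene_id))
  invisible(x)
}
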