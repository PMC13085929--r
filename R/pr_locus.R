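# B (pheromone/receptor) mating-type locus discovery: STE3 receptors,
# flank ORF enumeration, and the CaaX + N-terminal AF/ER precursor filter.

#' Find annotated pheromone-receptor genes by label
#'
#' @param annots An `annotation_set`.
#' @param keywords Label keywords (defaults: "pheromone receptor", "STE3").
#' @return Gene data frame (possibly empty).
#' @export
find_receptors <- function(annots,
                           keywords = c("pheromone receptor", "STE3")) {
  stopifnot(inherits(annots, "annotation_set"))
  g <- annots$genes[label_matches(annots$genes$label, keywords), ,
                    drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Extract the upstream and downstream flanks of a gene
#'
#' Flanks are strand-agnostic genomic windows: upstream is
#' `[max(0, start - flank), start)` and downstream `[end, min(L, end +
#' flank))`, each reported with its genomic offset.
#'
#' @param gene Gene model (needs `chrom`, `start`, `end`).
#' @param genome Nucleotide `DNAStringSet` or named character vector.
#' @param flank Flank size in bp (default 10000, i.e. the 10-kb windows
#'   within which fungal pheromone precursors typically lie).
#' @return List with `upstream` and `downstream`, each a list of `seq`
#'   (character, possibly empty) and `offset` (genomic start, 0-based).
#' @export
extract_flanks <- function(gene, genome, flank = 10000L) {
  chrom_seq <- if (is.character(genome)) genome[[gene$chrom]]
               else as.character(genome[[gene$chrom]])
  if (is.null(chrom_seq) || is.na(chrom_seq))
    stop("chromosome not in genome: ", gene$chrom, call. = FALSE)
  L <- nchar(chrom_seq)
  up_start <- max(0L, gene$start - as.integer(flank))
  dn_end <- min(L, gene$end + as.integer(flank))
  list(
    upstream = list(
      seq = if (gene$start > up_start)
              substring(chrom_seq, up_start + 1L, gene$start) else "",
      offset = up_start),
    downstream = list(
      seq = if (dn_end > gene$end)
              substring(chrom_seq, gene$end + 1L, dn_end) else "",
      offset = gene$end))
}

#' Enumerate open reading frames in a sequence
#'
#' Reports maximal ATG-to-stop ORFs: for every in-frame stop codon, the
#' ORF starting at the leftmost ATG since the previous stop (the
#' longest-per-stop rule; disable it to also report nested ATG starts).
#' ORFs must terminate with a stop codon inside the sequence. Lengths are
#' counted in nucleotides including the stop codon. Coordinates are
#' 0-based half-open on the forward strand of `seq` for both strands.
#'
#' @param seq Nucleotide sequence (character or `DNAString`).
#' @param min_nt Minimum ORF length in nt, stop included (default 75,
#'   divisible by 3, >= 30).
#' @param strands `"both"` or `"forward"`.
#' @param longest_per_stop Keep only the longest ORF per stop codon
#'   (default `TRUE`).
#' @return Data frame with columns `strand`, `start`, `end`, `nt`
#'   (reading-strand ORF sequence including stop), `peptide` (stop
#'   excluded), ordered by `start`.
#' @examples
#' find_orfs("ATGAAATAG", min_nt = 9)
#' @export
find_orfs <- function(seq, min_nt = 75L, strands = c("both", "forward"),
                      longest_per_stop = TRUE) {
  strands <- match.arg(strands)
  seq <- as_seq_chr(seq)
  if (min_nt < 6L || min_nt %% 3L != 0L)
    stop("min_nt must be >= 6 and divisible by 3", call. = FALSE)
  fwd <- orfs_one_strand(seq, min_nt, longest_per_stop)
  if (nrow(fwd)) fwd$strand <- "+"
  out <- fwd
  if (strands == "both") {
    rc <- revcomp(seq)
    rev <- orfs_one_strand(rc, min_nt, longest_per_stop)
    if (nrow(rev)) {
      n <- nchar(seq)
      rev$strand <- "-"
      new_start <- n - rev$end
      rev$end <- n - rev$start
      rev$start <- new_start
      out <- rbind(out, rev)
    }
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("strand", "start", "end", "nt", "peptide"), drop = FALSE]
}

# ORFs on the forward strand only; 0-based half-open coordinates
#' @noRd
orfs_one_strand <- function(seq, min_nt, longest_per_stop) {
  empty <- data.frame(strand = character(), start = integer(),
                      end = integer(), nt = character(),
                      peptide = character(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < min_nt) return(empty)
  rows <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    cod_start <- f + 3L * (seq_len(ncod) - 1L)       # 0-based codon starts
    codons <- substring(seq, cod_start + 1L, cod_start + 3L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    prev_stop <- 0L
    for (si in which(is_stop)) {
      region <- if (si > prev_stop + 1L) (prev_stop + 1L):(si - 1L)
                else integer()
      starts <- region[is_atg[region]]
      prev_stop <- si
      if (!length(starts)) next
      if (longest_per_stop) starts <- starts[1L]
      for (ai in starts) {
        s0 <- cod_start[ai]; e0 <- cod_start[si] + 3L
        if (e0 - s0 < min_nt) next
        nt <- substring(seq, s0 + 1L, e0)
        pep <- as.character(Biostrings::translate(
          Biostrings::DNAString(substring(nt, 1L, nchar(nt) - 3L)),
          if.fuzzy.codon = "X", no.init.codon = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          strand = "+", start = s0, end = e0, nt = nt, peptide = pep,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Classify a peptide as a candidate lipopeptide pheromone precursor
#'
#' Applies the two-part filter for basidiomycete mating pheromone
#' precursors: (i) the peptide terminates with a CaaX prenylation motif —
#' cysteine at position -4, two aliphatic residues (A, V, L, I, G) at -3
#' and -2, and A, S, M, Q or C at -1; and (ii) the conserved N-terminal
#' signature dipeptides `AF` and `ER` both occur (in either order) within
#' the first `sig_window` residues. The verdict is the conjunction of the
#' two rules. Candidates whose length falls outside 20-120 aa are flagged
#' but not rejected.
#'
#' @param peptide Protein string (20 amino acids plus `X`).
#' @param sig_window Number of N-terminal residues searched for the AF and
#'   ER signatures (default 40).
#' @return An object of class `pheromone_call`: `peptide`, `caax_ok`,
#'   `caax_residues`, `nterm_ok`, `signature_positions` (1-based start of
#'   the first AF and ER match, `NA` if absent), `length_flag`, `verdict`.
#' @examples
#' classify_pheromone_precursor("MAFSERLLQGGSNDCVIA")
#' @export
classify_pheromone_precursor <- function(peptide, sig_window = 40L) {
  peptide <- toupper(check_string(peptide, "peptide"))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", peptide))
    stop("peptide contains non-amino-acid characters", call. = FALSE)
  n <- nchar(peptide)
  aliphatic <- c("A", "V", "L", "I", "G")
  x_set <- c("A", "S", "M", "Q", "C")
  if (n >= 4L) {
    tail4 <- substring(peptide, n - 3L, n)
    r <- strsplit(tail4, "")[[1]]
    caax_ok <- r[1] == "C" && r[2] %in% aliphatic &&
      r[3] %in% aliphatic && r[4] %in% x_set
  } else {
    tail4 <- peptide
    caax_ok <- FALSE
  }
  head_win <- substring(peptide, 1L, min(n, sig_window))
  p_af <- regexpr("AF", head_win, fixed = TRUE)
  p_er <- regexpr("ER", head_win, fixed = TRUE)
  nterm_ok <- p_af > 0L && p_er > 0L
  structure(list(
    peptide = peptide,
    caax_ok = caax_ok,
    caax_residues = tail4,
    nterm_ok = nterm_ok,
    signature_positions = c(AF = if (p_af > 0L) as.integer(p_af) else NA_integer_,
                            ER = if (p_er > 0L) as.integer(p_er) else NA_integer_),
    length_flag = n < 20L || n > 120L,
    verdict = caax_ok && nterm_ok),
    class = "pheromone_call")
}

#' @export
print.pheromone_call <- function(x, ...) {
  cat(sprintf(
    "pheromone_call: %d aa, CaaX %s (%s), AF/ER %s -> %s%s\n",
    nchar(x$peptide), if (x$caax_ok) "ok" else "fail", x$caax_residues,
    if (x$nterm_ok) "ok" else "fail",
    if (x$verdict) "PRECURSOR" else "rejected",
    if (x$length_flag) " [length outside 20-120 aa]" else ""))
  invisible(x)
}

#' Scan the flanks of a receptor gene for pheromone-precursor ORFs
#'
#' Extracts the upstream/downstream flanks of the receptor, enumerates
#' ORFs on both strands, and classifies every translated peptide with
#' [classify_pheromone_precursor()].
#'
#' @param receptor Receptor gene model (from [get_gene()] or a row of
#'   [find_receptors()] output coerced with `as.list`).
#' @param genome Nucleotide `DNAStringSet` or named character vector.
#' @param flank Flank size in bp (default 10000).
#' @param min_nt,sig_window See [find_orfs()] and
#'   [classify_pheromone_precursor()].
#' @return Data frame of calls: `source`, `strand`, `start`, `end`
#'   (genomic, 0-based half-open), `peptide`, `caax_ok`, `nterm_ok`,
#'   `length_flag`, `verdict`, `dist_to_receptor`.
#' @export
scan_pheromones <- function(receptor, genome, flank = 10000L,
                            min_nt = 75L, sig_window = 40L) {
  fl <- extract_flanks(receptor, genome, flank)
  rows <- list()
  for (side in c("upstream", "downstream")) {
    s <- fl[[side]]$seq
    if (!nzchar(s)) next
    orfs <- find_orfs(s, min_nt = min_nt)
    off <- fl[[side]]$offset
    for (i in seq_len(nrow(orfs))) {
      call <- classify_pheromone_precursor(orfs$peptide[i], sig_window)
      gs <- off + orfs$start[i]; ge <- off + orfs$end[i]
      dist <- if (ge <= receptor$start) receptor$start - ge
              else if (gs >= receptor$end) gs - receptor$end else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        source = paste0(side, "_flank"), strand = orfs$strand[i],
        start = gs, end = ge, peptide = orfs$peptide[i],
        caax_ok = call$caax_ok, nterm_ok = call$nterm_ok,
        length_flag = call$length_flag, verdict = call$verdict,
        dist_to_receptor = dist, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$start), , drop = FALSE]
  } else {
    data.frame(source = character(), strand = character(),
               start = integer(), end = integer(), peptide = character(),
               caax_ok = logical(), nterm_ok = logical(),
               length_flag = logical(), verdict = logical(),
               dist_to_receptor = integer(), stringsAsFactors = FALSE)
  }
}

#' Delimit the B (pheromone/receptor) locus around a receptor
#'
#' Anchors are the receptor plus the verdict-true precursor call nearest
#' to it (or, failing that, an annotated pheromone-precursor gene). The
#' locus span is the anchor union extended by `flank`; additionally all
#' annotated genes lying strictly between the two anchors are reported as
#' the insertion set (the matB2-style inserted genes).
#'
#' @param receptor Receptor gene model.
#' @param calls Data frame from [scan_pheromones()] (may be empty or
#'   `NULL`).
#' @param annots An `annotation_set`.
#' @param flank Locus flank in bp (default 20000; sized so a precursor +
#'   receptor pair spans a region on the ~60 kb scale typical of
#'   tremellalean B loci).
#' @param chrom_len Optional chromosome length for clipping.
#' @param phb_keywords Fallback label keywords for an annotated precursor.
#' @return A `locus_region` (locus_type `"B"`) with extra fields
#'   `precursor` (list: `start`, `end`, `peptide` or `gene_id`),
#'   `insertion_set` (character vector of gene ids strictly between the
#'   anchors), and `warning` (`NA` or a message when no precursor found).
#' @export
define_b_locus <- function(receptor, calls, annots, flank = 20000L,
                           chrom_len = NULL,
                           phb_keywords = c("pheromone precursor", "PhB")) {
  stopifnot(inherits(annots, "annotation_set"))
  prec <- NULL
  if (!is.null(calls) && nrow(calls)) {
    ok <- calls[calls$verdict, , drop = FALSE]
    if (nrow(ok)) {
      ok <- ok[order(ok$dist_to_receptor), , drop = FALSE]
      prec <- list(start = ok$start[1], end = ok$end[1],
                   peptide = ok$peptide[1], gene_id = NA_character_)
    }
  }
  if (is.null(prec)) {
    phb <- find_receptors(annots, phb_keywords)
    phb <- phb[phb$chrom == receptor$chrom &
                 phb$gene_id != receptor$gene_id, , drop = FALSE]
    if (nrow(phb)) {
      d <- pmax(phb$start - receptor$end, receptor$start - phb$end, 0L)
      i <- which.min(d)
      prec <- list(start = phb$start[i], end = phb$end[i],
                   peptide = NA_character_, gene_id = phb$gene_id[i])
    }
  }
  warn <- NA_character_
  if (is.null(prec)) {
    warn <- "no pheromone-precursor candidate; single-anchor locus"
    span_lo <- receptor$start; span_hi <- receptor$end
    ins <- character()
  } else {
    span_lo <- min(receptor$start, prec$start)
    span_hi <- max(receptor$end, prec$end)
    # genes fully inside the open interval between the two anchors
    inner_lo <- min(receptor$end, prec$end)
    inner_hi <- max(receptor$start, prec$start)
    g <- annots$genes
    ins <- g$gene_id[g$chrom == receptor$chrom &
                       g$start >= inner_lo & g$end <= inner_hi &
                       !(g$gene_id %in% c(receptor$gene_id, prec$gene_id))]
  }
  start <- max(0L, span_lo - as.integer(flank))
  end <- span_hi + as.integer(flank)
  if (!is.null(chrom_len)) end <- min(end, as.integer(chrom_len))
  g <- annots$genes
  memb <- g[g$chrom == receptor$chrom &
              overlaps(g$start, g$end, start, end), , drop = FALSE]
  memb <- memb[order(memb$start, memb$gene_id), , drop = FALSE]
  rownames(memb) <- NULL
  anchors <- c(receptor$gene_id,
               if (!is.null(prec) && !is.na(prec$gene_id)) prec$gene_id)
  out <- structure(list(locus_type = "B", chrom = receptor$chrom,
                        start = start, end = end, members = memb,
                        anchor_ids = anchors, precursor = prec,
                        insertion_set = ins, warning = warn),
                   class = "locus_region")
  if (!is.na(warn)) warning(warn, call. = FALSE)
  out
}
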