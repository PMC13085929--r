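#' Scan one chromosome end for a telomeric repeat array
#'
#' Finds the maximal exact tandem run of `monomer` whose start (5' end) or
#' end (3' end) lies within `max_offset` bp of the respective terminus and
#' whose copy number is at least `min_copies`. Matching is exact: no
#' degenerate variants and no monomer rotations. When several disjoint runs
#' qualify, the one nearest the terminus is reported.
#'
#' @param seq Chromosome sequence (character or `DNAString`).
#' @param monomer Repeat monomer over `A/C/G/T`, length >= 4.
#' @param min_copies Minimum tandem copy number (>= 2; default 3).
#' @param max_offset Maximum distance (bp) of the array from the terminus
#'   (default 1000).
#' @param which_end `"five_prime"` or `"three_prime"`.
#' @return A list of class `telomere_array` with fields `monomer`, `copies`,
#'   `start`, `end` (0-based half-open), `offset_from_terminus`; or `NULL`
#'   if no qualifying run exists.
#' @examples
#' scan_end(paste0(strrep("CCCCCTAA", 5), strrep("G", 50)), "CCCCCTAA",
#'          which_end = "five_prime")
#' @export
scan_end <- function(seq, monomer, min_copies = 3L, max_offset = 1000L,
                     which_end = c("five_prime", "three_prime")) {
  which_end <- match.arg(which_end)
  seq <- as_seq_chr(seq)
  monomer <- toupper(check_string(monomer, "monomer"))
  if (!grepl("^[ACGT]+$", monomer))
    stop("monomer must contain only A/C/G/T", call. = FALSE)
  if (nchar(monomer) < 4L) stop("monomer length must be >= 4", call. = FALSE)
  if (min_copies < 2L) stop("min_copies must be >= 2", call. = FALSE)
  L <- nchar(monomer)
  if (nchar(seq) < L * min_copies) return(NULL)
  hits <- Biostrings::matchPattern(monomer, Biostrings::DNAString(seq))
  starts0 <- BiocGenerics::start(hits) - 1L      # 0-based match starts
  if (length(starts0) == 0L) return(NULL)
  sset <- starts0
  heads <- sset[!((sset - L) %in% sset)]
  runs <- lapply(heads, function(p) {
    k <- 1L
    while ((p + k * L) %in% sset) k <- k + 1L
    list(start = p, end = p + k * L, copies = k)
  })
  runs <- Filter(function(r) r$copies >= min_copies, runs)
  if (!length(runs)) return(NULL)
  n <- nchar(seq)
  if (which_end == "five_prime") {
    runs <- Filter(function(r) r$start <= max_offset, runs)
    if (!length(runs)) return(NULL)
    r <- runs[[which.min(vapply(runs, `[[`, 0, "start"))]]
    off <- r$start
  } else {
    runs <- Filter(function(r) (n - r$end) <= max_offset, runs)
    if (!length(runs)) return(NULL)
    r <- runs[[which.max(vapply(runs, `[[`, 0, "end"))]]
    off <- n - r$end
  }
  structure(list(end_scanned = which_end, monomer = monomer,
                 copies = r$copies, start = r$start, end = r$end,
                 offset_from_terminus = off),
            class = "telomere_array")
}

#' Scan a genome for telomeric arrays at both chromosome ends
#'
#' Applies [scan_end()] at the 5' and 3' terminus of every sequence with
#' the configured monomers. Defaults are the basidiomycete-style monomers
#' `(CCCCCTAA)n` at 5' and its reverse complement `(TTAGGGGG)n` at 3'.
#'
#' @param seqs Nucleotide `DNAStringSet` (or named character vector).
#' @param monomer5,monomer3 Repeat monomers for the two termini.
#' @param min_copies,max_offset Passed to [scan_end()].
#' @return An object of class `telomere_report`: list with `arrays` (data
#'   frame: `chrom`, `end`, `start`, `end_coord`, `copies`, `offset`),
#'   `n_telomeres`, `n_t2t` (telomere-to-telomere chromosomes), `n_chroms`.
#' @export
scan_genome <- function(seqs, monomer5 = "CCCCCTAA", monomer3 = "TTAGGGGG",
                        min_copies = 3L, max_offset = 1000L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  ids <- names(seqs)
  if (length(seqs) && is.null(ids))
    stop("sequences must be named", call. = FALSE)
  rows <- list(); t2t <- 0L
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    a5 <- scan_end(s, monomer5, min_copies, max_offset, "five_prime")
    a3 <- scan_end(s, monomer3, min_copies, max_offset, "three_prime")
    if (!is.null(a5) && !is.null(a3)) t2t <- t2t + 1L
    for (a in list(a5, a3)) {
      if (is.null(a)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ids[i], end = a$end_scanned, start = a$start,
        end_coord = a$end, copies = a$copies,
        offset = a$offset_from_terminus, stringsAsFactors = FALSE)
    }
  }
  arrays <- if (length(rows)) do.call(rbind, rows)
            else data.frame(chrom = character(), end = character(),
                            start = integer(), end_coord = integer(),
                            copies = integer(), offset = integer(),
                            stringsAsFactors = FALSE)
  structure(list(arrays = arrays, n_telomeres = nrow(arrays),
                 n_t2t = t2t, n_chroms = length(seqs)),
            class = "telomere_report")
}

#' @export
print.telomere_report <- function(x, ...) {
  cat(sprintf(
    "telomere_report: %d telomere(s) on %d chromosome(s); %d telomere-to-telomere\n",
    x$n_telomeres, x$n_chroms, x$n_t2t))
  invisible(x)
}
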