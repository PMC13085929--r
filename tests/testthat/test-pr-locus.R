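test_that("flank extraction clips at chromosome ends", {
  genome <- Biostrings::DNAStringSet(
    c(chrA = random_dna(10000, seed = 5)))
  g <- list(gene_id = "g", chrom = "chrA", start = 50L, end = 150L)
  fl <- extract_flanks(g, genome, flank = 10000)
  expect_identical(nchar(fl$upstream$seq), 50L)
  expect_identical(fl$upstream$offset, 0L)
  expect_identical(nchar(fl$downstream$seq), 9850L)
  expect_identical(fl$downstream$offset, 150L)

  fl0 <- extract_flanks(g, genome, flank = 0)
  expect_identical(fl0$upstream$seq, "")
  expect_identical(fl0$downstream$seq, "")
})

test_that("find_orfs handles trivial and empty cases", {
  o <- find_orfs("ATGAAATAG", min_nt = 9)
  expect_identical(nrow(o), 1L)
  expect_identical(o$peptide, "MK")
  expect_identical(o$start, 0L)
  expect_identical(o$end, 9L)

  expect_identical(nrow(find_orfs("CCTTTTTAGCCTTTAA", min_nt = 9)), 0L)
})

# independent six-frame brute-force ORF scanner (nested-ATG aware)
brute_orfs <- function(seq, min_nt, longest_per_stop = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  scan1 <- function(s) {
    out <- list()
    n <- nchar(s)
    for (i in seq_len(max(0, n - 2))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (j > i && cod %in% stops) {
          if (j + 3 - i >= min_nt)
            out[[length(out) + 1L]] <- c(start = i - 1L, end = j + 2L,
                                         stop_at = j - 1L)
          break
        }
        j <- j + 3L
      }
    }
    do.call(rbind, out)
  }
  collect <- function(m, strand, n) {
    if (is.null(m)) return(NULL)
    df <- as.data.frame(m)
    if (longest_per_stop) {
      df <- df[order(df$stop_at, df$start), ]
      df <- df[!duplicated(df$stop_at), ]   # smallest start per stop
    }
    if (strand == "-") {
      s2 <- n - df$end
      df$end <- n - df$start
      df$start <- s2
    }
    df$strand <- strand
    df[, c("strand", "start", "end")]
  }
  n <- nchar(seq)
  out <- rbind(collect(scan1(seq), "+", n),
               collect(scan1(revcomp_chr(seq)), "-", n))
  if (is.null(out)) return(data.frame(strand = character(),
                                      start = integer(), end = integer()))
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

test_that("both-strand enumeration equals the brute-force six-frame scanner", {
  for (r in 1:15) {
    s <- random_dna(600, seed = 500 + r)
    got <- find_orfs(s, min_nt = 30)
    want <- brute_orfs(s, min_nt = 30)
    expect_identical(got[, c("strand", "start", "end")], want)
    # nt/peptide structural invariants
    if (nrow(got)) {
      expect_true(all(nchar(got$nt) %% 3 == 0))
      expect_true(all(substr(got$nt, 1, 3) == "ATG"))
      expect_true(all(substr(got$nt, nchar(got$nt) - 2, nchar(got$nt)) %in%
                        c("TAA", "TAG", "TGA")))
      expect_false(any(grepl("\\*", got$peptide)))
    }
  }
})

test_that("reverse-strand ORFs equal forward ORFs of the reverse complement", {
  s <- random_dna(800, seed = 77)
  rc <- revcomp_chr(s)
  fwd_of_rc <- find_orfs(rc, min_nt = 30, strands = "forward")
  rev_of_s <- find_orfs(s, min_nt = 30)
  rev_of_s <- rev_of_s[rev_of_s$strand == "-", ]
  n <- nchar(s)
  mapped <- data.frame(start = n - fwd_of_rc$end, end = n - fwd_of_rc$start,
                       nt = fwd_of_rc$nt)
  mapped <- mapped[order(mapped$start), ]
  expect_identical(rev_of_s$start, mapped$start)
  expect_identical(rev_of_s$end, mapped$end)
  expect_identical(rev_of_s$nt, mapped$nt)
})

test_that("pheromone filter applies the printed CaaX and AF/ER rules", {
  call <- classify_pheromone_precursor("MAFSERLLQGGSNDCVIA",
                                       sig_window = 40)
  expect_true(call$caax_ok)
  expect_identical(call$caax_residues, "CVIA")
  expect_true(call$nterm_ok)
  expect_identical(call$signature_positions[["AF"]], 2L)
  expect_identical(call$signature_positions[["ER"]], 5L)
  expect_true(call$verdict)

  expect_false(classify_pheromone_precursor(
    "MAFSERLLQGGSNDCVIR")$caax_ok)                # X = R not allowed
  expect_false(classify_pheromone_precursor(
    "MSSQRLLQGGSNDCVIA")$nterm_ok)                # no AF
  expect_false(classify_pheromone_precursor("MKC")$verdict)  # too short
  expect_error(classify_pheromone_precursor("MK*"), "non-amino-acid")
})

test_that("filter agrees with a set-membership oracle, exhaustively on a 6-letter alphabet", {
  alpha <- c("C", "A", "F", "E", "R", "S")
  oracle <- function(p, win = 40) {
    n <- nchar(p)
    res <- strsplit(p, "")[[1]]
    caax <- n >= 4 &&
      res[n - 3] == "C" &&
      res[n - 2] %in% c("A", "V", "L", "I", "G") &&
      res[n - 1] %in% c("A", "V", "L", "I", "G") &&
      res[n] %in% c("A", "S", "M", "Q", "C")
    w <- res[seq_len(min(n, win))]
    dip <- paste0(w[-length(w)], w[-1])
    caax && ("AF" %in% dip) && ("ER" %in% dip)
  }
  for (len in 4:6) {
    grid <- do.call(expand.grid, c(rep(list(alpha), len),
                                   stringsAsFactors = FALSE))
    peps <- do.call(paste0, grid)
    got <- vapply(peps, function(p)
      classify_pheromone_precursor(p)$verdict, logical(1),
      USE.NAMES = FALSE)
    want <- vapply(peps, oracle, logical(1), USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("B locus: planted architectures give the right insertion sets", {
  ss <- shared_strain_set()
  for (s in names(ss$strains)) {
    st <- ss$strains[[s]]
    rec <- find_receptors(st$annots)
    expect_identical(nrow(rec), 1L)
    expect_identical(rec$gene_id, st$truth$b_locus$ste3_id)
    receptor <- get_gene(st$annots, rec$gene_id)
    calls <- scan_pheromones(receptor, st$genome)
    ok <- calls[calls$verdict, ]
    expect_true(nrow(ok) >= 1)
    expect_true(all(ok$dist_to_receptor <= 10000))   # flank bound
    # the planted precursor peptide is among the verdict-true calls
    expect_true(st$truth$b_locus$phb_peptide %in% ok$peptide)
    loc <- define_b_locus(receptor, calls, st$annots)
    expect_setequal(loc$insertion_set, st$truth$b_locus$insertion_ids)
    arch <- st$truth$b_architecture
    expect_identical(length(loc$insertion_set),
                     if (arch == "inserted") 3L else 0L)
  }
})

test_that("B locus without any precursor falls back to a single-anchor call", {
  a <- make_annots("rec", "chr1", 5000, 6000, "+",
                   label = "pheromone receptor")
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(12000, seed = 9)))
  receptor <- get_gene(a, "rec")
  calls <- scan_pheromones(receptor, genome)
  calls <- calls[calls$verdict, ]      # near-certainly empty on random DNA
  expect_warning(loc <- define_b_locus(receptor, calls, a),
                 "single-anchor")
  expect_identical(loc$anchor_ids, "rec")
  expect_length(loc$insertion_set, 0L)
})
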