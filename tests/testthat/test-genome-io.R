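test_that("read_fasta uppercases, preserves order, handles degenerate input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), f)
  s <- read_fasta(f)
  expect_s4_class(s, "DNAStringSet")
  expect_identical(names(s), "chr1")
  expect_identical(as.character(s[[1]]), "ACGT")

  writeLines(character(), f)
  expect_length(read_fasta(f), 0L)

  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">a", "ACGT", ">b", "AC!T"), f)
  expect_error(read_fasta(f, moltype = "nucleotide"), "line 4")
})

test_that("FASTA round-trips 50 random records byte-identically", {
  set.seed(11)
  n <- 50
  recs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(10:200, 1),
                 replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
          collapse = ""), character(1))
  names(recs) <- paste0("seq", seq_len(n))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(Biostrings::DNAStringSet(recs), f)
  back <- read_fasta(f, moltype = "nucleotide")
  expect_identical(names(back), names(recs))
  expect_identical(as.character(back), recs)
})

test_that("read_gff3 converts 1-based inclusive to 0-based half-open and groups CDS", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t11\t40\t.\t+\t.\tID=g1;product=homeobox KN domain",
    "chr1\tx\tmRNA\t11\t40\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tx\tCDS\t11\t22\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tx\tCDS\t30\t40\t.\t+\t0\tID=c2;Parent=m1"), f)
  a <- read_gff3(f)
  expect_identical(a$genes$start, 10L)
  expect_identical(a$genes$end, 40L)
  seg <- a$cds[a$cds$gene_id == "g1", ]
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$start, c(10L, 29L))
  expect_identical(seg$end, c(22L, 40L))
  expect_match(a$genes$label, "homeobox")

  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tCDS\t11\t22\t.\t+\t0\tID=c1;Parent=nosuch"), f)
  expect_error(read_gff3(f), "nosuch")
})

test_that("GFF3 write -> read is the identity on coordinates and labels", {
  # two CDS segments for gA, one for gB
  a <- make_annots(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
    start = c(100, 5), end = c(400, 305), strand = c("+", "-"),
    label = c("pheromone receptor", "hypothetical protein"),
    cds = data.frame(gene_id = c("gA", "gA", "gB"),
                     start = c(100L, 250L, 5L),
                     end = c(180L, 400L, 305L), stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(a, f)
  b <- read_gff3(f)
  expect_identical(b$genes[, c("gene_id", "chrom", "start", "end",
                               "strand", "label")],
                   a$genes[, c("gene_id", "chrom", "start", "end",
                               "strand", "label")])
  expect_identical(b$cds, a$cds)
})

test_that("extract_protein translates single- and minus-strand CDS", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAG"))
  a <- make_annots("g1", "chr1", 0, 9, "+")
  expect_identical(unname(extract_protein(genome, get_gene(a, "g1"))), "MK")

  genome2 <- Biostrings::DNAStringSet(
    c(chr1 = revcomp_chr("ATGAAATAG")))
  a2 <- make_annots("g1", "chr1", 0, 9, "-")
  expect_identical(unname(extract_protein(genome2, get_gene(a2, "g1"))),
                   "MK")
})

test_that("spliced CDS translation equals splice-then-translate oracle", {
  set.seed(21)
  for (rep in 1:10) {
    pep <- random_aa(40, seed = 100 + rep)
    cds <- reverse_translate(pep, seed = 200 + rep)
    sp <- sample(2:(nchar(cds) - 2), 1)          # split inside codons too
    intron <- random_dna(30, seed = 300 + rep)
    chrom <- paste0(substr(cds, 1, sp), intron,
                    substr(cds, sp + 1, nchar(cds)))
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    a <- make_annots("g1", "chr1", 0, nchar(chrom), "+",
                     cds = data.frame(gene_id = "g1",
                                      start = c(0L, sp + 30L),
                                      end = c(sp, nchar(chrom)),
                                      stringsAsFactors = FALSE))
    # oracle: splice manually, translate the concatenation
    spliced <- paste0(substr(chrom, 1, sp),
                      substr(chrom, sp + 31, nchar(chrom)))
    oracle <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(spliced))))
    expect_identical(unname(extract_protein(genome, get_gene(a, "g1"))),
                     oracle)
  }
})

test_that("extract_protein flags internal stops and rejects frame errors", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGTAAAAATAG"))
  a <- make_annots("g1", "chr1", 0, 12, "+")
  expect_warning(p <- extract_protein(genome, get_gene(a, "g1")),
                 "internal stop")
  expect_true(attr(p, "internal_stop"))

  a2 <- make_annots("g1", "chr1", 0, 10, "+")
  expect_error(suppressWarnings(
    extract_protein(genome, get_gene(a2, "g1"))), "divisible by 3")
})

test_that("assembly statistics match hand-computed N50 and GC", {
  one <- assembly_stats(Biostrings::DNAStringSet(c(a = strrep("A", 100))))
  expect_identical(one$n50, 100L)
  expect_identical(one$max_length, 100L)

  lens <- c(5, 4, 3, 2, 1)
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(vapply(lens, function(n) strrep("A", n), ""),
                    paste0("c", lens)))
  st <- assembly_stats(seqs)
  expect_identical(st$n50, 4L)          # cumulative 5, 9 >= 7.5
  expect_identical(st$total_length, 15L)

  expect_equal(assembly_stats(
    Biostrings::DNAStringSet(c(x = "GGCC")))$gc_percent, 100)
  # N excluded from the denominator: G+C over the 3 unambiguous bases
  expect_equal(assembly_stats(
    Biostrings::DNAStringSet(c(x = "GNCA")))$gc_percent, 200 / 3)

  # permutation invariance
  set.seed(4)
  perm <- sample(length(seqs))
  st2 <- assembly_stats(seqs[perm])
  expect_identical(st2[c("n50", "total_length", "max_length",
                         "gc_percent")],
                   st[c("n50", "total_length", "max_length", "gc_percent")])

  expect_error(assembly_stats(Biostrings::AAStringSet(c(p = "MK"))),
               "nucleotide")
})
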