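# small constructed loci for pairing tests
toy_locus <- function(ids, starts, strands = NULL, type = "A") {
  if (is.null(strands)) strands <- rep("+", length(ids))
  members <- data.frame(gene_id = ids, chrom = "chr1",
                        start = as.integer(starts),
                        end = as.integer(starts + 500L),
                        strand = strands, label = "",
                        stringsAsFactors = FALSE)
  structure(list(locus_type = type, chrom = "chr1",
                 start = min(members$start), end = max(members$end),
                 members = members, anchor_ids = ids[1]),
            class = "locus_region")
}

test_that("identical loci match gene-for-gene at 100 with no insertions", {
  prots <- stats::setNames(
    vapply(1:4, function(i) random_aa(120, seed = 1000 + i), ""),
    paste0("g", 1:4))
  la <- toy_locus(names(prots), seq(0, 9000, length.out = 4))
  pr <- match_locus_genes(la, la, prots, prots)
  expect_identical(sum(pr$relation == "matched"), 4L)
  expect_true(all(pr$identity_percent[pr$relation == "matched"] == 100))
  arch <- call_architecture(pr, la, la)
  expect_length(arch$inversions, 0L)
  expect_length(arch$insertions_a, 0L)
  expect_length(arch$insertions_b, 0L)
})

test_that("pairing equals brute-force reciprocal-best assignment", {
  set.seed(55)
  for (rep in 1:5) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pa <- stats::setNames(
      vapply(seq_len(na), function(i)
        random_aa(100, seed = 2000 + 10 * rep + i), ""),
      paste0("a", seq_len(na)))
    # b genes: some are mutated copies of a genes, some unrelated
    pb <- stats::setNames(vapply(seq_len(nb), function(j) {
      if (j <= na && j %% 2 == 1)
        mutate_protein(pa[[j]], 70, seed = 3000 + 10 * rep + j)
      else random_aa(100, seed = 4000 + 10 * rep + j)
    }, ""), paste0("b", seq_len(nb)))
    la <- toy_locus(names(pa), seq(0, by = 1000, length.out = na))
    lb <- toy_locus(names(pb), seq(0, by = 1000, length.out = nb), type = "B")
    got <- match_locus_genes(la, lb, pa, pb, match_threshold = 30)

    m <- matrix(0, na, nb, dimnames = list(names(pa), names(pb)))
    for (i in seq_len(na)) for (j in seq_len(nb))
      m[i, j] <- global_identity(pa[[i]], pb[[j]])$identity_percent
    want <- list()
    for (i in seq_len(na)) for (j in seq_len(nb))
      if (m[i, j] >= 30 && which.max(m[i, ]) == j &&
          which.max(m[, j]) == i)
        want[[length(want) + 1L]] <- c(names(pa)[i], names(pb)[j])
    gotm <- got[got$relation == "matched", ]
    expect_identical(nrow(gotm), length(want))
    for (w in want)
      expect_true(any(gotm$gene_a == w[1] & gotm$gene_b == w[2]))
    # partition property: every gene appears exactly once
    expect_setequal(got$gene_a[!is.na(got$gene_a)], names(pa))
    expect_setequal(got$gene_b[!is.na(got$gene_b)], names(pb))
    expect_identical(anyDuplicated(stats::na.omit(got$gene_a)), 0L)
    expect_identical(anyDuplicated(stats::na.omit(got$gene_b)), 0L)

    # symmetry: swapping loci transposes the pairing
    swp <- match_locus_genes(lb, la, pb, pa, match_threshold = 30)
    swpm <- swp[swp$relation == "matched", ]
    expect_setequal(paste(swpm$gene_b, swpm$gene_a),
                    paste(gotm$gene_a, gotm$gene_b))
    expect_setequal(swp$gene_b[swp$relation == "inserted_in_b"],
                    got$gene_a[got$relation == "inserted_in_a"])
  }
})

test_that("a planted two-gene inverted block is called as one inversion", {
  prots <- stats::setNames(
    vapply(1:5, function(i) random_aa(110, seed = 5000 + i), ""),
    paste0("g", 1:5))
  la <- toy_locus(paste0("g", 1:5), seq(0, by = 1000, length.out = 5))
  # same genes but g3/g4 swapped in coordinate order on locus b
  lb <- toy_locus(paste0("g", c(1, 2, 4, 3, 5)),
                  seq(0, by = 1000, length.out = 5), type = "A")
  pr <- match_locus_genes(la, lb, prots, prots)
  arch <- call_architecture(pr, la, lb)
  expect_length(arch$inversions, 1L)
  expect_identical(sort(arch$inversions[[1]]), c("g3", "g4"))
})

test_that("matB2 vs matB1 comparison reports the inter-anchor insertion set", {
  rep <- shared_pipeline()
  ss <- shared_strain_set()
  arch <- rep$synteny[["NS-27:NS-29:B"]]
  expect_false(is.null(arch))
  expect_setequal(arch$insertions_b,
                  ss$strains[["NS-29"]]$truth$b_locus$insertion_ids)
  expect_length(arch$insertions_a, 0L)
  # the STE12 homolog is among the genes absent from the matB1 locus
  expect_true(any(grepl("STE12", arch$insertions_b)))
})

test_that("strain-specific genes follow the zero-reciprocal-match rule", {
  prot <- stats::setNames(
    vapply(1:6, function(i) random_aa(150, seed = 6000 + i), ""),
    paste0("p", 1:6))
  # identical proteomes: nothing specific
  both <- find_strain_specific_genes(prot, prot)
  expect_length(both$a_specific, 0L)
  expect_length(both$b_specific, 0L)

  # one unrelated 300-aa protein added to b: it alone is specific
  pb <- c(prot, novel = random_aa(300, seed = 6100))
  res <- find_strain_specific_genes(prot, pb)
  expect_identical(res$b_specific, "novel")
  expect_length(res$a_specific, 0L)

  # diverged homologs (70% identity) are still hits, not specific
  pa2 <- prot
  pb2 <- stats::setNames(vapply(seq_along(prot), function(i)
    mutate_protein(prot[[i]], 70, seed = 6200 + i), ""), names(prot))
  res2 <- find_strain_specific_genes(pa2, pb2)
  expect_length(res2$a_specific, 0L)
  expect_length(res2$b_specific, 0L)

  expect_error(find_strain_specific_genes(character(), prot), "empty")
})
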