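# Synthetic multi-strain genome generator with planted telomeres, MAT loci,
# controlled allele divergence, and a machine-readable truth manifest.

#' Mutate a protein down to a target global identity
#'
#' Substitutes uniformly chosen positions with uniformly chosen distinct
#' residues, one at a time, until the realized global identity (measured
#' by [global_identity()] under default scoring) first reaches at most
#' `target_identity`. Deterministic for a fixed seed; the caller's RNG
#' state is untouched.
#'
#' @param seq Protein sequence, length >= 50.
#' @param target_identity Target identity percent in \[20, 100\].
#' @param seed Integer seed.
#' @return The mutated protein (character scalar); `seq` unchanged when
#'   `target_identity` is 100.
#' @export
mutate_protein <- function(seq, target_identity, seed) {
  seq <- as_seq_chr(seq)
  if (nchar(seq) < 50L) stop("sequence shorter than 50 aa", call. = FALSE)
  if (target_identity < 20 || target_identity > 100)
    stop("target_identity must lie in [20, 100]", call. = FALSE)
  if (target_identity == 100) return(seq)
  with_local_seed(seed, mutate_core(seq, target_identity, check = TRUE))
}

# substitution loop; check = FALSE skips alignment checks and plants the
# count-implied number of substitutions (used for short constrained spans)
#' @noRd
mutate_core <- function(seq, target, check = TRUE) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  order_pos <- sample.int(L)
  k_expect <- max(1L, floor(L * (1 - target / 100)))
  mutated <- res
  sub_one <- function(v, p) {
    v[p] <- sample(setdiff(AA20, v[p]), 1L)
    v
  }
  if (!check) {
    kc <- min(L, max(1L, as.integer(ceiling(L * (1 - target / 100)))))
    for (p in order_pos[seq_len(kc)])
      mutated <- sub_one(mutated, p)
    return(paste(mutated, collapse = ""))
  }
  k0 <- max(0L, k_expect - 3L)
  applied <- 0L
  for (p in order_pos[seq_len(k0)]) {
    mutated <- sub_one(mutated, p)
    applied <- applied + 1L
  }
  repeat {
    id <- global_identity(seq, paste(mutated, collapse = ""))$identity_percent
    if (id <= target || applied >= L) break
    applied <- applied + 1L
    mutated <- sub_one(mutated, order_pos[applied])
  }
  paste(mutated, collapse = "")
}

#' Reverse-translate a protein into a CDS
#'
#' Each residue gets a codon chosen uniformly among its synonymous codons
#' of the standard genetic code; a uniformly chosen stop codon is
#' appended. `translate(reverse_translate(p))` recovers `p`.
#'
#' @param pep Protein sequence over the 20 standard amino acids.
#' @param seed Integer seed.
#' @return CDS nucleotide string (length `3 * (nchar(pep) + 1)`).
#' @export
reverse_translate <- function(pep, seed) {
  pep <- as_seq_chr(pep)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep))
    stop("pep must contain only the 20 standard amino acids",
         call. = FALSE)
  with_local_seed(seed, rev_translate_core(pep))
}

#' @noRd
rev_translate_core <- function(pep) {
  syn <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  res <- strsplit(pep, "")[[1]]
  codons <- vapply(res, function(a) {
    opts <- syn[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  stop_opts <- syn[["*"]]
  paste0(paste(codons, collapse = ""),
         stop_opts[sample.int(length(stop_opts), 1L)])
}

#' Describe one synthetic strain
#'
#' @param strain_name Strain label.
#' @param a_allele,b_allele Allele labels (`"A1"`/`"A2"`, `"B1"`/`"B2"`).
#' @param b_architecture `"adjacent"` (precursor directly beside the
#'   receptor) or `"inserted"` (three extra genes planted between them).
#' @return A `strain_design` list.
#' @export
strain_design <- function(strain_name, a_allele, b_allele,
                          b_architecture = c("adjacent", "inserted")) {
  structure(list(strain_name = check_string(strain_name, "strain_name"),
                 a_allele = a_allele, b_allele = b_allele,
                 b_architecture = match.arg(b_architecture)),
            class = "strain_design")
}

#' The default four-strain study design
#'
#' Encodes the published four-monokaryon configuration: genotypes
#' A1B1 / A1B2 / A2B2 / A2B1 for NS-27 / NS-29 / NS-45 / NS-58, with the
#' B1 strains carrying the adjacent precursor-receptor architecture and
#' the B2 strains the three-gene-insertion architecture.
#'
#' @return List of four `strain_design` objects.
#' @export
default_strain_designs <- function() {
  list(strain_design("NS-27", "A1", "B1", "adjacent"),
       strain_design("NS-29", "A1", "B2", "inserted"),
       strain_design("NS-45", "A2", "B2", "inserted"),
       strain_design("NS-58", "A2", "B1", "adjacent"))
}

# ---- internal builders ------------------------------------------------

#' @noRd
random_nt <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
random_protein <- function(n) {
  paste0("M", paste(sample(AA20, n - 1L, replace = TRUE), collapse = ""))
}

# pheromone precursor: M + AF + spacer + ER + interior + CaaX (CVIA)
#' @noRd
random_precursor <- function(total_len = 55L) {
  interior <- paste(sample(AA20, total_len - 12L, replace = TRUE),
                    collapse = "")
  paste0("MAF", paste(sample(AA20, 3L, replace = TRUE), collapse = ""),
         "ER", interior, "CVIA")
}

# gene cassette in genomic space; coordinates relative to cassette start.
# An in-frame stop guard flanks the CDS on its 5' side so a chance
# upstream in-frame ATG in intergenic sequence can never extend the
# planted ORF (which would displace planted N-terminal signatures).
#' @noRd
gene_cassette <- function(gene_id, protein, strand, label, n_exons = 1L,
                          intron_len = 60L, gc = 0.5) {
  cds_nt <- rev_translate_core(protein)
  genomic <- if (strand == "+") cds_nt else revcomp(cds_nt)
  if (n_exons == 2L) {
    sp <- sample(3:(nchar(genomic) - 3L), 1L)
    intron <- random_nt(intron_len, gc)
    body <- paste0(substr(genomic, 1L, sp), intron,
                   substr(genomic, sp + 1L, nchar(genomic)))
    segs <- data.frame(start = c(0L, sp + intron_len),
                       end = c(sp, nchar(body)))
  } else {
    body <- genomic
    segs <- data.frame(start = 0L, end = nchar(body))
  }
  g5 <- if (strand == "+") "TAA" else ""
  g3 <- if (strand == "+") "" else "TTA"
  off <- nchar(g5)
  segs$start <- segs$start + off
  segs$end <- segs$end + off
  list(nt = paste0(g5, body, g3), cds_offset = off,
       gene = list(gene_id = gene_id, strand = strand, label = label,
                   protein = protein, cds = segs))
}

# raw (unannotated) ORF cassette for decoy planting, forward strand, with
# the same 5' in-frame stop guard
#' @noRd
decoy_cassette <- function(peptide, fails) {
  list(nt = paste0("TAA", rev_translate_core(peptide)), orf_offset = 3L,
       decoy = list(peptide = peptide, fails = fails))
}

#' Generate a synthetic multi-strain genome set with ground truth
#'
#' Emits, per strain, a haploid genome of `n_chrom` chromosomes flanked by
#' exact telomere-monomer arrays at both termini, a gene annotation with
#' planted mating-type loci, and the per-gene proteins; plus a truth
#' manifest recording everything planted. The A locus is a divergently
#' transcribed HD1/HD2 pair (labels "homeobox KN domain" / "homeobox
#' domain") on the chromosome-5 equivalent; the B locus is a pheromone
#' precursor (PhB) upstream of a pheromone receptor (STE3) on the
#' chromosome-11 equivalent, with three genes (ZNF622/DBP10/STE12
#' homolog labels) planted between them in the "inserted" architecture.
#' Allele divergence is controlled per marker: default targets 78.3%
#' (HD1), 77.22% (HD2), 76.72% (PhB) and 35.1% (STE3), the published
#' inter-allele identities, so recovery exercises both high- and
#' low-identity matching. Planted precursor peptides satisfy the CaaX +
#' AF/ER rules by construction; two decoy ORFs each failing exactly one
#' rule are planted in the receptor flanks. Background sequence is
#' i.i.d. A/C/G/T at the configured GC; background gene proteins are
#' shared across strains. All output is a deterministic function of
#' `(designs, scale, seed)`.
#'
#' @param designs List of [strain_design()] objects (default: the
#'   published four-strain design).
#' @param scale `"test"` (30-60 kb chromosomes; the suite's scale) or
#'   `"paper"` (1-2.5 Mb).
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (default 12).
#' @param gc_percent Background GC percent (default 53.65, the four-strain
#'   assembly average).
#' @param telomere_copies Exact monomer copies planted per terminus
#'   (default 5).
#' @param divergence Named numeric vector of inter-allele identity
#'   targets for markers `HD1`, `HD2`, `PhB`, `STE3`.
#' @param outdir Optional directory: writes `<strain>.fa`,
#'   `<strain>.gff3`, `<strain>.faa` and `truth.json`.
#' @return Object of class `strain_set`: `strains` (named list with
#'   `genome` (`DNAStringSet`), `annots` (`annotation_set`), `proteins`
#'   (named character), `truth`), plus `truth` (cross-strain manifest:
#'   `genotypes`, `compatible_pairs`), `monomer5`, `monomer3`, `seed`.
#' @export
generate_strain_set <- function(designs = default_strain_designs(),
                                scale = c("test", "paper"),
                                seed = 1L, n_chrom = 12L,
                                gc_percent = 53.65, telomere_copies = 5L,
                                divergence = c(HD1 = 78.3, HD2 = 77.22,
                                               PhB = 76.72, STE3 = 35.1),
                                outdir = NULL) {
  scale <- match.arg(scale)
  nm <- vapply(designs, `[[`, character(1), "strain_name")
  if (anyDuplicated(nm)) stop("duplicate strain names", call. = FALSE)
  with_local_seed(seed, {
    gen_strain_set_core(designs, scale, n_chrom, gc_percent / 100,
                        telomere_copies, divergence, outdir, seed)
  })
}

#' @noRd
gen_strain_set_core <- function(designs, scale, n_chrom, gc,
                                tel_copies, divergence, outdir, seed) {
  mono5 <- "CCCCCTAA"; mono3 <- "TTAGGGGG"
  len_range <- if (scale == "test") c(30000, 60000) else c(1e6, 2.5e6)
  a_chrom <- min(5L, n_chrom); b_chrom <- min(11L, n_chrom)

  # ---- shared material (identical across strains) ----
  markers <- list(
    HD1 = list(A1 = random_protein(450L)),
    HD2 = list(A1 = random_protein(420L)),
    STE3 = list(B1 = random_protein(450L)),
    PhB = list(B1 = random_precursor(55L)))
  markers$HD1$A2 <- mutate_core(markers$HD1$A1, divergence[["HD1"]])
  markers$HD2$A2 <- mutate_core(markers$HD2$A1, divergence[["HD2"]])
  markers$STE3$B2 <- mutate_core(markers$STE3$B1, divergence[["STE3"]])
  markers$PhB$B2 <- mutate_precursor(markers$PhB$B1, divergence[["PhB"]])

  ins_proteins <- list(
    ZNF622 = random_protein(180L),
    DBP10 = random_protein(220L),
    STE12 = random_protein(200L))
  ins_labels <- c(ZNF622 = "cytoplasm protein ZNF622",
                  DBP10 = "ATP-dependent RNA helicase DBP10",
                  STE12 = "transcription factor STE12")

  a_flank_names <- c("ODDT", "RGTB1", "RPL22", "INO80")
  a_flank_labels <- c(ODDT = "oxidoreductase",
                      RGTB1 = "geranylgeranyl transferase",
                      RPL22 = "ribosomal L22e protein",
                      INO80 = "ATP-dependent helicase")
  b_flank_names <- c("STEA", "USP14", "CLA4", "NDC80")
  b_flank_labels <- c(STEA = "STE like transcription factor",
                      USP14 = "ubiquitin carboxyl-terminal hydrolase",
                      CLA4 = "serine/threonine-protein kinase",
                      NDC80 = "probable kinetochore protein")
  flank_proteins <- stats::setNames(
    lapply(seq_along(c(a_flank_names, b_flank_names)),
           function(i) random_protein(sample(120:250, 1L))),
    c(a_flank_names, b_flank_names))

  n_bg <- pmax(2L, sample(2:4, n_chrom, replace = TRUE))
  bg_proteins <- lapply(seq_len(n_chrom), function(ci)
    lapply(seq_len(n_bg[ci]), function(k)
      random_protein(sample(100:220, 1L))))
  bg_meta <- lapply(seq_len(n_chrom), function(ci)
    data.frame(strand = sample(c("+", "-"), n_bg[ci], replace = TRUE),
               n_exons = sample(1:2, n_bg[ci], replace = TRUE),
               stringsAsFactors = FALSE))

  # decoys: one fails only CaaX, one fails only the N-terminal signature
  decoy_caax <- paste0("MAF", "GT", "ER",
                       paste(sample(AA20, 30L, replace = TRUE),
                             collapse = ""), "CVIR")
  safe <- c("S", "T", "G", "L", "V", "K", "D")     # no F, no E/R pairs
  decoy_nterm <- paste0("M", paste(sample(safe, 36L, replace = TRUE),
                                   collapse = ""), "CVIA")

  chrom_targets <- round(stats::runif(n_chrom, len_range[1], len_range[2]))

  strains <- list()
  for (d in designs) {
    sid <- gsub("-", "", d$strain_name)
    prefix <- function(x) paste0(sid, "_", x)
    genome <- character(); annots_genes <- list(); annots_cds <- list()
    proteins <- character(); truth_tel <- list()
    truth <- list(strain = d$strain_name, a_allele = d$a_allele,
                  b_allele = d$b_allele, b_architecture = d$b_architecture)

    for (ci in seq_len(n_chrom)) {
      chrom <- paste0("chr", ci)
      cassettes <- list(); gaps <- integer()
      add <- function(cas, gap) {
        cassettes[[length(cassettes) + 1L]] <<- cas
        gaps[length(gaps) + 1L] <<- gap
      }
      for (k in seq_len(n_bg[ci]))
        add(gene_cassette(prefix(sprintf("bg%d_%d", ci, k)),
                          bg_proteins[[ci]][[k]], bg_meta[[ci]]$strand[k],
                          "hypothetical protein", bg_meta[[ci]]$n_exons[k],
                          gc = gc),
            sample(1500:4000, 1L))
      if (ci == a_chrom) {
        add(gene_cassette(prefix("ODDT"), flank_proteins$ODDT, "+",
                          a_flank_labels[["ODDT"]], gc = gc),
            sample(4000:7000, 1L))
        add(gene_cassette(prefix("RGTB1"), flank_proteins$RGTB1, "-",
                          a_flank_labels[["RGTB1"]], gc = gc),
            sample(3000:5000, 1L))
        add(gene_cassette(prefix("HD1"), markers$HD1[[d$a_allele]], "-",
                          "homeobox KN domain", gc = gc),
            sample(1500:2500, 1L))
        add(gene_cassette(prefix("HD2"), markers$HD2[[d$a_allele]], "+",
                          "homeobox domain", gc = gc),
            sample(3000:5000, 1L))
        add(gene_cassette(prefix("RPL22"), flank_proteins$RPL22, "+",
                          a_flank_labels[["RPL22"]], gc = gc),
            sample(4000:7000, 1L))
        add(gene_cassette(prefix("INO80"), flank_proteins$INO80, "+",
                          a_flank_labels[["INO80"]], gc = gc),
            sample(2000:4000, 1L))
      }
      if (ci == b_chrom) {
        add(gene_cassette(prefix("STEA"), flank_proteins$STEA, "-",
                          b_flank_labels[["STEA"]], gc = gc),
            sample(3000:5000, 1L))
        add(gene_cassette(prefix("USP14"), flank_proteins$USP14, "+",
                          b_flank_labels[["USP14"]], gc = gc),
            sample(2000:3000, 1L))
        add(decoy_cassette(decoy_caax, "caax"), sample(800:1200, 1L))
        add(gene_cassette(prefix("PhB"), markers$PhB[[d$b_allele]], "+",
                          "pheromone precursor", gc = gc),
            sample(1200:1800, 1L))
        if (d$b_architecture == "inserted")
          for (g in names(ins_proteins))
            add(gene_cassette(prefix(g), ins_proteins[[g]], "+",
                              ins_labels[[g]], gc = gc),
                sample(300:600, 1L))
        add(gene_cassette(prefix("STE3"), markers$STE3[[d$b_allele]], "+",
                          "pheromone receptor", gc = gc),
            sample(800:1200, 1L))
        add(decoy_cassette(decoy_nterm, "nterm"), sample(2000:3000, 1L))
        add(gene_cassette(prefix("CLA4"), flank_proteins$CLA4, "-",
                          b_flank_labels[["CLA4"]], gc = gc),
            sample(2000:4000, 1L))
        add(gene_cassette(prefix("NDC80"), flank_proteins$NDC80, "+",
                          b_flank_labels[["NDC80"]], gc = gc),
            sample(2000:4000, 1L))
      }
      tel5 <- strrep(mono5, tel_copies)
      parts <- tel5
      pos <- nchar(tel5) + 0L
      lead <- random_nt(sample(1200:2000, 1L), gc)
      parts <- c(parts, lead); pos <- pos + nchar(lead)
      for (k in seq_along(cassettes)) {
        cas <- cassettes[[k]]
        if (!is.null(cas$gene)) {
          g <- cas$gene
          annots_genes[[length(annots_genes) + 1L]] <- data.frame(
            gene_id = g$gene_id, chrom = chrom, start = pos,
            end = pos + nchar(cas$nt), strand = g$strand,
            label = g$label, stringsAsFactors = FALSE)
          annots_cds[[length(annots_cds) + 1L]] <- data.frame(
            gene_id = g$gene_id, start = pos + g$cds$start,
            end = pos + g$cds$end, stringsAsFactors = FALSE)
          proteins[g$gene_id] <- g$protein
        } else if (!is.null(cas$decoy)) {
          truth[[paste0("decoy_", cas$decoy$fails)]] <-
            list(chrom = chrom, start = pos + cas$orf_offset,
                 end = pos + nchar(cas$nt),
                 peptide = cas$decoy$peptide, fails = cas$decoy$fails)
        }
        parts <- c(parts, cas$nt); pos <- pos + nchar(cas$nt)
        gp <- random_nt(gaps[k], gc)
        parts <- c(parts, gp); pos <- pos + nchar(gp)
      }
      fill <- max(500L, chrom_targets[ci] - pos - nchar(mono3) * tel_copies)
      tailp <- random_nt(fill, gc)
      parts <- c(parts, tailp, strrep(mono3, tel_copies))
      seqc <- paste(parts, collapse = "")
      genome[chrom] <- seqc
      L <- nchar(seqc)
      truth_tel[[length(truth_tel) + 1L]] <- data.frame(
        chrom = chrom,
        end = c("five_prime", "three_prime"),
        start = c(0L, L - nchar(mono3) * tel_copies),
        end_coord = c(nchar(mono5) * tel_copies, L),
        copies = tel_copies, stringsAsFactors = FALSE)
    }

    genes_df <- do.call(rbind, annots_genes)
    cds_df <- do.call(rbind, annots_cds)
    annots <- annotation_set(genes_df, cds_df)
    hd1 <- get_gene(annots, paste0(sid, "_HD1"))
    hd2 <- get_gene(annots, paste0(sid, "_HD2"))
    phb <- get_gene(annots, paste0(sid, "_PhB"))
    ste3 <- get_gene(annots, paste0(sid, "_STE3"))
    truth$chrom_lengths <- vapply(genome, nchar, integer(1))
    truth$telomeres <- do.call(rbind, truth_tel)
    truth$a_locus <- list(chrom = hd1$chrom, hd1_id = hd1$gene_id,
                          hd2_id = hd2$gene_id, start = hd1$start,
                          end = hd2$end,
                          intergenic_gap = hd2$start - hd1$end)
    truth$b_locus <- list(
      chrom = ste3$chrom, phb_id = phb$gene_id, ste3_id = ste3$gene_id,
      start = phb$start, end = ste3$end,
      phb_peptide = markers$PhB[[d$b_allele]],
      insertion_ids = if (d$b_architecture == "inserted")
        paste0(sid, "_", names(ins_proteins)) else character())
    strains[[d$strain_name]] <- list(
      genome = Biostrings::DNAStringSet(genome),
      annots = annots,
      proteins = proteins,
      truth = truth)
  }

  genotypes <- data.frame(
    strain = vapply(designs, `[[`, character(1), "strain_name"),
    a_allele = vapply(designs, `[[`, character(1), "a_allele"),
    b_allele = vapply(designs, `[[`, character(1), "b_allele"),
    stringsAsFactors = FALSE)
  genotypes$composite <- paste0(genotypes$a_allele, genotypes$b_allele)
  pairs <- list()
  n <- nrow(genotypes)
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (genotypes$a_allele[i] != genotypes$a_allele[j] &&
          genotypes$b_allele[i] != genotypes$b_allele[j])
        pairs[[length(pairs) + 1L]] <- data.frame(
          strain1 = genotypes$strain[i], strain2 = genotypes$strain[j],
          stringsAsFactors = FALSE)
  compatible_pairs <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(strain1 = character(), strain2 = character(),
                    stringsAsFactors = FALSE)

  ss <- structure(list(strains = strains,
                       truth = list(genotypes = genotypes,
                                    compatible_pairs = compatible_pairs),
                       monomer5 = mono5, monomer3 = mono3, seed = seed),
                  class = "strain_set")
  if (!is.null(outdir)) write_strain_set(ss, outdir)
  ss
}

# PhB allele-2: mutate only the unconstrained interior so the AF/ER
# signatures and the CaaX terminus survive; interior target solved so the
# whole-peptide identity lands near the requested value
#' @noRd
mutate_precursor <- function(pep, target) {
  n <- nchar(pep)
  fixed_head <- 8L; fixed_tail <- 4L
  interior <- substring(pep, fixed_head + 1L, n - fixed_tail)
  li <- nchar(interior)
  ti <- max(0, min(100, 100 * (target / 100 * n - (n - li)) / li))
  paste0(substring(pep, 1L, fixed_head),
         mutate_core(interior, ti, check = FALSE),
         substring(pep, n - fixed_tail + 1L, n))
}

#' @export
print.strain_set <- function(x, ...) {
  cat(sprintf("strain_set: %d strain(s) (seed %d)\n",
              length(x$strains), x$seed))
  for (s in names(x$strains)) {
    tr <- x$strains[[s]]$truth
    cat(sprintf("  %s: %d chromosomes, %s kb, genotype %s%s (%s B locus)\n",
                s, length(tr$chrom_lengths),
                format(round(sum(tr$chrom_lengths) / 1000)),
                tr$a_allele, tr$b_allele, tr$b_architecture))
  }
  invisible(x)
}

#' Write a strain set to disk
#'
#' Emits per strain `<strain>.fa`, `<strain>.gff3` and `<strain>.faa`,
#' plus a single `truth.json` manifest.
#'
#' @param ss A `strain_set`.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_strain_set <- function(ss, outdir) {
  stopifnot(inherits(ss, "strain_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- list(genotypes = ss$truth$genotypes,
                compatible_pairs = ss$truth$compatible_pairs,
                strains = list())
  for (s in names(ss$strains)) {
    st <- ss$strains[[s]]
    write_fasta(st$genome, file.path(outdir, paste0(s, ".fa")))
    write_gff3(st$annots, file.path(outdir, paste0(s, ".gff3")))
    write_fasta(Biostrings::AAStringSet(st$proteins),
                file.path(outdir, paste0(s, ".faa")))
    truth$strains[[s]] <- st$truth
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Check a strain set against its own truth manifest
#'
#' Verifies that the emitted sequences and annotations are mutually
#' consistent with the manifest: every CDS translates to the recorded
#' protein without internal stops, every recorded telomere span is an
#' exact monomer array, the planted locus genes carry their keyword
#' labels, and the planted decoy ORFs fail exactly their intended
#' pheromone-filter rule.
#'
#' @param ss A `strain_set`.
#' @return Character vector of problems (empty when fully consistent).
#' @export
validate_strain_set <- function(ss) {
  stopifnot(inherits(ss, "strain_set"))
  problems <- character()
  bad <- function(...) problems <<- c(problems, sprintf(...))
  for (s in names(ss$strains)) {
    st <- ss$strains[[s]]
    for (gid in st$annots$genes$gene_id) {
      p <- tryCatch(extract_protein(st$genome, get_gene(st$annots, gid)),
                    warning = function(w) w, error = function(e) e)
      if (inherits(p, "condition"))
        bad("%s/%s: %s", s, gid, conditionMessage(p))
      else if (!identical(unname(p), unname(st$proteins[[gid]])))
        bad("%s/%s: protein mismatch", s, gid)
    }
    tel <- st$truth$telomeres
    for (i in seq_len(nrow(tel))) {
      mono <- if (tel$end[i] == "five_prime") ss$monomer5 else ss$monomer3
      span <- substring(as.character(st$genome[[tel$chrom[i]]]),
                        tel$start[i] + 1L, tel$end_coord[i])
      if (!identical(span, strrep(mono, tel$copies[i])))
        bad("%s/%s %s: telomere span mismatch", s, tel$chrom[i], tel$end[i])
    }
    lab <- st$annots$genes$label[match(
      c(st$truth$a_locus$hd1_id, st$truth$a_locus$hd2_id,
        st$truth$b_locus$ste3_id, st$truth$b_locus$phb_id),
      st$annots$genes$gene_id)]
    want <- c("homeobox", "homeobox", "pheromone receptor",
              "pheromone precursor")
    for (k in seq_along(lab))
      if (is.na(lab[k]) || !grepl(want[k], lab[k], ignore.case = TRUE))
        bad("%s: locus gene label missing ('%s')", s, want[k])
    for (dk in c("decoy_caax", "decoy_nterm")) {
      dc <- st$truth[[dk]]
      if (is.null(dc)) next
      call <- classify_pheromone_precursor(dc$peptide)
      ok <- if (dc$fails == "caax") !call$caax_ok && call$nterm_ok
            else call$caax_ok && !call$nterm_ok
      if (!ok || call$verdict) bad("%s/%s: wrong decoy behaviour", s, dk)
    }
  }
  problems
}
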