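# Pipeline orchestration: io -> telomeres -> loci -> alleles -> genotypes
# -> compatibility -> locus synteny, with per-strain fault isolation.

#' Default pipeline configuration
#'
#' Every stage parameter with its documented default: telomere monomers
#' and scan settings, locus keyword lists and flank sizes, ORF and
#' signature parameters, alignment scoring, and synteny thresholds.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    monomer5 = "CCCCCTAA", monomer3 = "TTAGGGGG",
    min_copies = 3L, max_offset = 1000L,
    hd_keywords = c("homeobox", "homeodomain", "HD1", "HD2"),
    hd_max_gap = 10000L, a_flank = 30000L,
    receptor_keywords = c("pheromone receptor", "STE3"),
    phb_keywords = c("pheromone precursor", "PhB"),
    pr_flank = 10000L, min_orf_nt = 75L, sig_window = 40L,
    b_flank = 20000L,
    match_threshold = 30, mode = "tetrapolar")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Run the full mating-type characterization pipeline
#'
#' Executes, per strain: assembly statistics, telomere scan, A-locus
#' discovery (HD pair + locus region), B-locus discovery (receptor,
#' flank ORF scan, pheromone filter, locus region + insertion set) and
#' marker-protein extraction; then cross-strain: allele assignment at
#' both loci, mating genotypes, the pairwise compatibility matrix
#' (skipped with a warning for a single strain), and locus-scale gene
#' pairing/architecture between every strain pair at both loci. A strain
#' whose stages fail is isolated (its error recorded) and the others
#' continue.
#'
#' @param strains Either a `strain_set` from [generate_strain_set()] or a
#'   named list where each element is a list with paths `fasta` and
#'   `gff3` (and optionally `proteins`).
#' @param config A list from [pipeline_config()].
#' @return Object of class `mat_report`: `strain_reports` (per strain:
#'   `stats`, `telomeres`, `a_locus`, `hd_pair`, `b_locus`,
#'   `pheromone_calls`, `markers`, `error`), `alleles` (A and B
#'   `allele_assignment`s), `genotypes`, `compatibility`, `synteny`
#'   (per locus and strain pair), `config`.
#' @export
run_pipeline <- function(strains, config = pipeline_config()) {
  inputs <- load_pipeline_inputs(strains)
  reports <- list()
  for (s in names(inputs)) {
    reports[[s]] <- tryCatch(
      run_strain_stages(inputs[[s]], config),
      error = function(e) list(error = conditionMessage(e)))
  }
  ok <- names(reports)[vapply(reports, function(r) is.null(r$error),
                              logical(1))]
  if (!length(ok))
    stop("all strains failed: ",
         paste(vapply(reports, `[[`, character(1), "error"),
               collapse = " | "), call. = FALSE)

  alleles <- genotypes <- compat <- NULL
  hd1 <- vapply(ok, function(s) reports[[s]]$markers[["HD1"]], character(1))
  hd2 <- vapply(ok, function(s) reports[[s]]$markers[["HD2"]], character(1))
  phb <- vapply(ok, function(s) reports[[s]]$markers[["PhB"]], character(1))
  ste3 <- vapply(ok, function(s) reports[[s]]$markers[["STE3"]],
                 character(1))
  alleles <- list(
    A = assign_alleles(list(HD1 = hd1, HD2 = hd2), "A"),
    B = assign_alleles(list(PhB = phb, STE3 = ste3), "B"))
  genotypes <- genotype_strains(alleles$A, alleles$B)
  if (length(ok) >= 2L) {
    compat <- compatibility_matrix(genotypes, mode = config$mode)
  } else {
    warning("single strain: compatibility stage skipped", call. = FALSE)
  }

  synteny <- list()
  if (length(ok) >= 2L) {
    for (i in seq_len(length(ok) - 1L)) for (j in (i + 1L):length(ok)) {
      s1 <- ok[i]; s2 <- ok[j]
      for (lt in c("a_locus", "b_locus")) {
        la <- reports[[s1]][[lt]]; lb <- reports[[s2]][[lt]]
        if (is.null(la) || is.null(lb)) next
        pr <- match_locus_genes(la, lb,
                                reports[[s1]]$proteins,
                                reports[[s2]]$proteins,
                                match_threshold = config$match_threshold)
        synteny[[paste(s1, s2, toupper(substr(lt, 1, 1)), sep = ":")]] <-
          call_architecture(pr, la, lb)
      }
    }
  }
  structure(list(strain_reports = reports, alleles = alleles,
                 genotypes = genotypes, compatibility = compat,
                 synteny = synteny, config = config),
            class = "mat_report")
}

#' @noRd
load_pipeline_inputs <- function(strains) {
  if (inherits(strains, "strain_set")) {
    return(lapply(strains$strains, function(st)
      list(genome = st$genome, annots = st$annots)))
  }
  if (!is.list(strains) || is.null(names(strains)))
    stop("strains must be a strain_set or a named list of input paths",
         call. = FALSE)
  lapply(strains, function(st) {
    list(genome = read_fasta(st$fasta, moltype = "nucleotide"),
         annots = read_gff3(st$gff3))
  })
}

#' @noRd
run_strain_stages <- function(input, cfg) {
  genome <- input$genome
  annots <- input$annots
  out <- list(error = NULL)
  out$stats <- assembly_stats(genome)
  out$telomeres <- scan_genome(genome, cfg$monomer5, cfg$monomer3,
                               cfg$min_copies, cfg$max_offset)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  pairs <- find_hd_pairs(annots, cfg$hd_keywords, cfg$hd_max_gap)
  markers <- character()
  if (length(pairs)) {
    hp <- pairs[[1]]
    out$hd_pair <- hp
    out$a_locus <- define_locus(c(hp$hd1$gene_id, hp$hd2$gene_id), annots,
                                flank = cfg$a_flank, locus_type = "A",
                                chrom_len = chrom_len[[hp$hd1$chrom]])
    markers["HD1"] <- extract_protein(genome, hp$hd1)
    markers["HD2"] <- extract_protein(genome, hp$hd2)
  } else stop("no head-to-head HD pair found")

  rec <- find_receptors(annots, cfg$receptor_keywords)
  if (!nrow(rec)) stop("no pheromone-receptor gene found")
  receptor <- get_gene(annots, rec$gene_id[1])
  calls <- scan_pheromones(receptor, genome, cfg$pr_flank,
                           cfg$min_orf_nt, cfg$sig_window)
  out$pheromone_calls <- calls
  out$b_locus <- define_b_locus(receptor, calls, annots,
                                flank = cfg$b_flank,
                                chrom_len = chrom_len[[receptor$chrom]],
                                phb_keywords = cfg$phb_keywords)
  markers["STE3"] <- extract_protein(genome, receptor)
  prec <- out$b_locus$precursor
  markers["PhB"] <- if (!is.null(prec) && !is.na(prec$peptide))
    prec$peptide
  else if (!is.null(prec) && !is.na(prec$gene_id))
    extract_protein(genome, get_gene(annots, prec$gene_id))
  else stop("no pheromone-precursor candidate found")

  out$markers <- markers
  # proteins for every member gene of both loci (for synteny pairing)
  memb <- unique(c(out$a_locus$members$gene_id,
                   out$b_locus$members$gene_id))
  out$proteins <- vapply(memb, function(g)
    unname(suppressWarnings(extract_protein(genome, get_gene(annots, g)))),
    character(1))
  out
}

#' @export
print.mat_report <- function(x, ...) {
  ok <- names(x$strain_reports)[vapply(x$strain_reports,
                                       function(r) is.null(r$error),
                                       logical(1))]
  cat(sprintf("mat_report: %d/%d strain(s) analysed\n",
              length(ok), length(x$strain_reports)))
  for (s in names(x$strain_reports)) {
    r <- x$strain_reports[[s]]
    if (!is.null(r$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", s, r$error)); next
    }
    g <- x$genotypes[x$genotypes$strain == s, ]
    cat(sprintf(
      "  %s: %d telomeres, A locus %s [%d genes], B locus %s [%d genes%s], genotype %s\n",
      s, r$telomeres$n_telomeres, r$a_locus$chrom, nrow(r$a_locus$members),
      r$b_locus$chrom, nrow(r$b_locus$members),
      if (length(r$b_locus$insertion_set))
        paste0(", ", length(r$b_locus$insertion_set), " inserted")
      else "",
      if (nrow(g)) g$composite else "?"))
  }
  if (!is.null(x$compatibility)) print(x$compatibility)
  invisible(x)
}
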