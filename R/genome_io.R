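#' Read a FASTA file into a sequence set
#'
#' Sequences are uppercased and validated against the molecule alphabet:
#' `A/C/G/T/N` for nucleotide records, the 20 amino acids plus `X` and `*`
#' for protein records. Record order is preserved and ids must be unique.
#'
#' @param path Path to a FASTA file. An empty file yields an empty set.
#' @param moltype `"nucleotide"`, `"protein"`, or `"auto"` (guess from
#'   residue composition).
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, moltype = c("auto", "nucleotide", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    return(if (moltype == "protein") Biostrings::AAStringSet()
           else Biostrings::DNAStringSet())
  }
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1]
    stop("empty sequence for record '", bad, "'", call. = FALSE)
  }
  if (moltype == "auto") {
    nt_frac <- mean(strsplit(paste(seqs, collapse = ""), "")[[1]] %in%
                      c("A", "C", "G", "T", "N", "U"))
    moltype <- if (nt_frac >= 0.95) "nucleotide" else "protein"
  }
  alphabet <- if (moltype == "nucleotide") c("A", "C", "G", "T", "N")
              else c(AA20, "X", "*")
  bad <- !grepl(sprintf("^[%s]*$", paste(gsub("\\*", "\\\\*", alphabet),
                                         collapse = "")), seqs)
  if (any(bad)) {
    # report the first offending file line for the error contract
    pat <- sprintf("[^%s%s]", paste(alphabet, collapse = ""),
                   tolower(paste(setdiff(alphabet, "*"), collapse = "")))
    hit <- which(!startsWith(lines, ">") & grepl(pat, trimws(lines)))[1]
    stop("illegal ", moltype, " character in record '", ids[bad][1],
         "' (file line ", ifelse(is.na(hit), "?", hit), ")", call. = FALSE)
  }
  out <- if (moltype == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a sequence set to FASTA
#'
#' Lines are wrapped at 60 columns.
#'
#' @param seqs A named `XStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Parses gene/mRNA/CDS features into an annotation set. GFF3 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention. CDS features are grouped per gene (`Parent` chains through
#' mRNA are resolved); free-text functional labels are taken from the
#' `product` and `Note` attributes of the gene or its mRNAs.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `annotation_set`: a list with elements
#'   `genes` (data frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `label`) and `cds` (data frame: `gene_id`, `start`, `end`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  getattr <- function(col) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is(v, "CharacterList") || is.list(v))
        vapply(v, function(x) paste(x, collapse = ";"), character(1))
      else ifelse(is.na(v), "", as.character(v))
    } else rep("", nrow(df))
  }
  id <- getattr("ID")
  parent <- getattr("Parent")
  product <- getattr("product")
  note <- getattr("Note")
  type <- as.character(df$type)

  is_gene <- type == "gene"
  is_mrna <- type == "mRNA"
  is_cds  <- type == "CDS"

  # map mRNA id -> gene id
  mrna2gene <- stats::setNames(parent[is_mrna], id[is_mrna])
  gene_ids <- id[is_gene]

  # label: product/Note on the gene, plus those of its mRNAs
  lab <- stats::setNames(trimws(paste(product[is_gene], note[is_gene])),
                         gene_ids)
  for (i in which(is_mrna)) {
    g <- parent[i]
    extra <- trimws(paste(product[i], note[i]))
    if (nzchar(extra) && g %in% names(lab))
      lab[g] <- trimws(paste(lab[g], extra))
  }

  genes <- data.frame(
    gene_id = gene_ids,
    chrom = df$seqnames[is_gene],
    start = df$start[is_gene] - 1L,
    end = df$end[is_gene],
    strand = df$strand[is_gene],
    label = unname(lab[gene_ids]),
    stringsAsFactors = FALSE
  )
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene feature without +/- strand", call. = FALSE)

  cds_parent <- parent[is_cds]
  cds_gene <- ifelse(cds_parent %in% names(mrna2gene),
                     unname(mrna2gene[cds_parent]), cds_parent)
  orphan <- !(cds_gene %in% gene_ids)
  if (any(orphan))
    stop("CDS feature(s) with unresolvable parent gene: ",
         paste(unique(cds_parent[orphan]), collapse = ", "), call. = FALSE)
  cds <- data.frame(
    gene_id = cds_gene,
    start = df$start[is_cds] - 1L,
    end = df$end[is_cds],
    stringsAsFactors = FALSE
  )
  cds <- cds[order(match(cds$gene_id, gene_ids), cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  annotation_set(genes, cds)
}

#' Construct an annotation set
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `label`.
#' @param cds Data frame with columns `gene_id`, `start`, `end`.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(genes, cds = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "label")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids", call. = FALSE)
  if (any(genes$start >= genes$end))
    stop("gene with start >= end", call. = FALSE)
  if (is.null(cds))
    cds <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  structure(list(genes = genes, cds = cds), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,",
      nrow(x$cds), "CDS segments on",
      length(unique(x$genes$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Write an annotation set to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based inclusive; labels are emitted as `product` attributes. The
#' round trip `read_gff3(write_gff3(x))` preserves coordinates and labels.
#'
#' @param annots An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annots, path) {
  stopifnot(inherits(annots, "annotation_set"))
  g <- annots$genes
  cds <- annots$cds
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    mid <- paste0(gid, ".t1")
    seg <- cds[cds$gene_id == gid, , drop = FALSE]
    lab <- g$label[i]
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = g$chrom[i], start = g$start[i] + 1L, end = g$end[i],
      strand = g$strand[i], type = c("gene", "mRNA"),
      ID = c(gid, mid), Parent = c(NA, gid),
      product = c(if (nzchar(lab)) lab else NA, NA),
      phase = NA_integer_, stringsAsFactors = FALSE)
    if (nrow(seg)) {
      seg <- seg[order(seg$start), , drop = FALSE]
      widths <- seg$end - seg$start
      # phase: unread bases carried into each segment, transcription order
      tx <- if (g$strand[i] == "-") rev(seq_len(nrow(seg)))
            else seq_len(nrow(seg))
      carried <- c(0L, cumsum(widths[tx]))[seq_len(nrow(seg))]
      phase <- integer(nrow(seg))
      phase[tx] <- (3L - carried %% 3L) %% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = g$chrom[i], start = seg$start + 1L, end = seg$end,
        strand = g$strand[i], type = "CDS",
        ID = paste0(gid, ".cds", seq_len(nrow(seg))), Parent = mid,
        product = NA, phase = phase, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "matlocus"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$product <- df$product
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Retrieve one gene model from an annotation set
#'
#' @param annots An `annotation_set`.
#' @param gene_id Gene identifier.
#' @return A list with the gene's fields plus a `cds` data frame of its
#'   segments (genomic coordinate order).
#' @export
get_gene <- function(annots, gene_id) {
  stopifnot(inherits(annots, "annotation_set"))
  i <- match(gene_id, annots$genes$gene_id)
  if (is.na(i)) stop("no such gene: ", gene_id, call. = FALSE)
  g <- as.list(annots$genes[i, , drop = FALSE])
  seg <- annots$cds[annots$cds$gene_id == gene_id, , drop = FALSE]
  g$cds <- seg[order(seg$start), , drop = FALSE]
  g
}

#' Extract and translate the protein of a gene
#'
#' CDS segments are concatenated in genomic order, reverse-complemented for
#' minus-strand genes (yielding transcription order), and translated with
#' the standard genetic code by default. The trailing stop is stripped;
#' codons containing `N` translate to `X`. An internal stop codon sets a
#' warning attribute `internal_stop` on the result.
#'
#' @param genome A nucleotide `DNAStringSet` (or named character vector).
#' @param gene A gene model from [get_gene()] (needs `chrom`, `strand`,
#'   `cds`; if `cds` is empty, the gene interval itself is used).
#' @param codon_table NCBI translation table id (default 1, standard code).
#' @return A named character scalar (the protein), possibly with attribute
#'   `internal_stop = TRUE`.
#' @export
extract_protein <- function(genome, gene, codon_table = 1L) {
  chrom_seq <- if (is.character(genome)) genome[[gene$chrom]]
               else as.character(genome[[gene$chrom]])
  if (is.null(chrom_seq) || is.na(chrom_seq))
    stop("chromosome not in genome: ", gene$chrom, call. = FALSE)
  seg <- gene$cds
  if (is.null(seg) || nrow(seg) == 0L)
    seg <- data.frame(start = gene$start, end = gene$end)
  if (any(seg$start < 0L) || any(seg$end > nchar(chrom_seq)))
    stop("CDS segment outside chromosome bounds for gene ", gene$gene_id,
         call. = FALSE)
  nt <- paste(substring(chrom_seq, seg$start + 1L, seg$end), collapse = "")
  if (nchar(nt) %% 3L != 0L)
    stop("CDS length not divisible by 3 for gene ", gene$gene_id,
         call. = FALSE)
  if (identical(gene$strand, "-")) nt <- revcomp(nt)
  code <- Biostrings::getGeneticCode(as.character(codon_table))
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt), genetic.code = code,
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  if (endsWith(pep, "*")) pep <- substr(pep, 1L, nchar(pep) - 1L)
  out <- stats::setNames(pep, gene$gene_id)
  if (grepl("*", pep, fixed = TRUE)) {
    warning("internal stop codon in gene ", gene$gene_id, call. = FALSE)
    attr(out, "internal_stop") <- TRUE
  }
  out
}

#' Basic assembly statistics
#'
#' N50 is the smallest contig length `L` such that contigs of length `>= L`
#' (sorted descending) sum to at least half the assembly. The GC denominator
#' excludes `N`.
#'
#' @param seqs A nucleotide `DNAStringSet` (or named character vector).
#' @return An object of class `assembly_stats` with fields `n_contigs`,
#'   `total_length`, `max_length`, `n50`, `gc_percent`.
#' @examples
#' assembly_stats(Biostrings::DNAStringSet(c(a = "GGCC", b = "ATATAT")))
#' @export
assembly_stats <- function(seqs) {
  if (methods::is(seqs, "AAStringSet"))
    stop("assembly_stats expects nucleotide sequences", call. = FALSE)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  len <- Biostrings::width(seqs)
  total <- sum(len)
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  comp <- colSums(Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"),
                                                      drop = FALSE])
  gc <- 100 * (comp[["C"]] + comp[["G"]]) / sum(comp)
  structure(list(n_contigs = length(seqs), total_length = total,
                 max_length = max(len), n50 = n50, gc_percent = gc),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "assembly: %d contig(s), %s bp total, max %s bp, N50 %s bp, GC %.2f%%\n",
    x$n_contigs, format(x$total_length, big.mark = ","),
    format(x$max_length, big.mark = ","),
    format(x$n50, big.mark = ","), x$gc_percent))
  invisible(x)
}
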