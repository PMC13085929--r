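# Shared fixtures. The four-strain synthetic set and its pipeline run are
# expensive (tens of seconds), so they are built once per session and
# memoized; every file that needs them shares the same objects.

.fixtures <- new.env(parent = emptyenv())

shared_strain_set <- function() {
  if (is.null(.fixtures$ss))
    .fixtures$ss <- generate_strain_set(seed = 7)
  .fixtures$ss
}

shared_pipeline <- function() {
  if (is.null(.fixtures$report))
    .fixtures$report <- run_pipeline(shared_strain_set())
  .fixtures$report
}

# a minimal annotation set from parallel vectors; single-exon CDS spanning
# each gene unless a cds data frame is given
make_annots <- function(gene_id, chrom, start, end, strand,
                        label = "", cds = NULL) {
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = as.integer(start), end = as.integer(end),
                      strand = strand, label = label,
                      stringsAsFactors = FALSE)
  if (is.null(cds))
    cds <- data.frame(gene_id = gene_id, start = as.integer(start),
                      end = as.integer(end), stringsAsFactors = FALSE)
  annotation_set(genes, cds)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, seed) {
  set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste0("M", paste(sample(aa, n - 1, replace = TRUE), collapse = ""))
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
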