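---
title: "Mining tetrapolar mating-type loci from fungal genome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining tetrapolar mating-type loci from fungal genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matlocus)
```

## The biological model

Tetrapolar basidiomycetes carry two unlinked mating-type loci. The A
locus holds a divergently transcribed pair of homeodomain transcription
factors (HD1/HD2); after cell fusion, HD1 and HD2 proteins from
*different* alleles heterodimerize to license dikaryotic development.
The B locus holds lipopeptide pheromone precursors (PhB) and
seven-transmembrane pheromone receptors (STE3); recognition again
requires non-self alleles. Mating therefore succeeds exactly when two
monokaryons differ at both loci — with two alleles per locus, the four
composite genotypes A1B1, A1B2, A2B1, A2B2 always contain exactly two
compatible pairs, a perfect matching.

`matlocus` operationalizes the locus-discovery workflow on assemblies
plus annotations, and ships a synthetic-genome generator so that every
stage is verifiable against planted ground truth.

## Procedures and their assumptions

### Telomere arrays

`scan_end()` looks for *exact* tandem runs of a repeat monomer whose 5′
start (or 3′ end) lies within `max_offset` of the terminus. Defaults:
monomers `CCCCCTAA` (5′) / `TTAGGGGG` (3′) — reverse complements of each
other — `min_copies = 3`, `max_offset = 1000` bp. Exact matching keeps
the detector auditable (a planted run of *k* copies is always reported
with copies = *k*) at the cost of missing degenerate or rotated
variants; rotations are deliberately not matched. When several disjoint
runs qualify, the one nearest the terminus wins, since telomeres are
terminal by definition. The minimum copy number and offset tolerance
are judgment calls, not biological constants; both are arguments.

### The A locus

Candidate homeodomain genes are selected by case-insensitive substring
match of their functional annotation labels (defaults: "homeobox",
"homeodomain", "HD1", "HD2"). We deliberately trust upstream database
annotation rather than running a profile-HMM scan: the package consumes
annotation labels as input. "Head-to-head" is operationalized as
divergent transcription with non-overlapping intervals — leftmost gene
on the minus strand, rightmost on plus, intergenic gap at most
`max_gap` (default 10 kb, generous for compact fungal genomes);
overlapping divergent genes are rejected. Candidate pairs are ranked by
gap, smallest first. `define_locus()` extends the anchor union by a
flank (default 30 kb, which puts a typical HD pair plus flank on the
~70 kb scale reported for tremellalean A loci) and collects all
overlapping genes in coordinate order.

### The B locus and the pheromone filter

Receptors are found by label ("pheromone receptor", "STE3"). Because
fungal pheromone precursor genes are short, often unannotated, and
typically lie within ~10 kb of their receptor, `scan_pheromones()`
extracts the 10-kb genomic flanks on both sides of each receptor
(strand-agnostic windows, clipped at chromosome ends) and enumerates
ORFs on both strands: maximal ATG-to-stop, one ORF per stop codon
(longest-per-stop; nested ATGs available via a switch), minimum 75 nt
including the stop — the documented defaults of the NCBI ORF finder,
since lipopeptide precursors are commonly in the 20–120 aa range.

Each translated peptide is then classified by two rules:

1. **CaaX prenylation motif** at the C-terminus: position −4 is `C`,
   positions −3/−2 are aliphatic (`A V L I G`), position −1 is one of
   `A S M Q C`.
2. **N-terminal signatures**: the dipeptides `AF` and `ER` both occur,
   in either order, within the first `sig_window = 40` residues.

The verdict is the conjunction. "AF and ER" is interpreted as literal
dipeptides within a window — the simplest operationalization consistent
with short precursors; the window is configurable, and peptides outside
20–120 aa are flagged rather than dropped so that edge cases remain
auditable. `define_b_locus()` anchors the locus at the receptor and the
nearest verdict-true precursor (falling back to an annotated precursor
gene, and to a single-anchor locus with a warning when neither exists),
and reports every annotated gene lying strictly between the two anchors
as the insertion set — the signature of the rearranged B-locus
architecture in which ZNF622/DBP10/STE12 homologs separate precursor
and receptor.

### Identity, alleles, genotypes, compatibility

`global_identity()` is a Needleman–Wunsch global alignment (BLOSUM62,
gap open 10, gap extend 1) with identity defined as matches over all
alignment columns, gap columns included in the denominator; a
`denominator = "aligned"` switch excludes them. No consensus exists for
the "percent identity" of a gapped alignment, so both conventions are
explicit and the scoring is configurable. Symmetry under argument swap
is guaranteed by aligning the two sequences in a canonical order, which
removes any dependence on traceback tie-breaking.

Allele classes use exact sequence equality of the marker proteins (all
markers must match), labelled in first-seen strain order; the full
identity matrices are attached as evidence. Exact equality reflects how
allele designations are made in practice — strains with identical
HD1/HD2 sequences share an allele name — and a similarity-threshold
mode was considered and rejected as a default because it can silently
merge near-identical alleles. Genotypes concatenate the two labels, and
`compatibility_matrix()` applies the tetrapolar rule to every unordered
pair; unknown alleles propagate as indeterminate (`NA`), never as
compatible.

### Locus microsynteny and strain-specific genes

`match_locus_genes()` pairs genes of two locus regions by reciprocal
best global identity with a `match_threshold` of 30 % — low enough that
cross-allele receptor homologs at ~35 % identity still pair, high
enough that unrelated proteins do not. Inversions are called from order
reversal of matched anchors (maximal strictly decreasing runs of length
at least 2), i.e. at gene-level granularity rather than by nucleotide
alignment. `find_strain_specific_genes()` replaces the conventional
BLASTP e-value screen with an explicit hit rule — local alignment
identity at least 30 % covering at least 40 % of the query — because
the package performs its own alignments rather than wrapping an
external search engine; the 40 % minimal alignment-length fraction is
retained from standard practice and both thresholds are arguments.
Genes with zero hits in either direction are strain-specific.

## The synthetic generator: what it emulates, and what it does not

`generate_strain_set()` emits per-strain FASTA/GFF3/protein files plus
a truth manifest. It emulates the features the pipeline must recover:

- 12 chromosomes, each flanked by five exact telomere-monomer copies;
- a head-to-head HD1(−)/HD2(+) pair with homeobox labels on the
  chromosome-5 equivalent, with conserved labelled neighbours within
  the locus flank;
- PhB (CaaX + AF/ER-satisfying peptide, by construction) upstream of a
  labelled STE3 on the chromosome-11 equivalent, adjacent or separated
  by three inserted genes depending on the strain design;
- controlled inter-allele protein divergence, default targets 78.3 %
  (HD1), 77.22 % (HD2), 76.72 % (PhB) and 35.1 % (STE3) — the published
  inter-allele identities — so that matching is exercised in both the
  high- and the low-identity regime;
- two decoy ORFs in the receptor flanks, one failing only the CaaX rule
  and one failing only the N-terminal rule, as specificity controls;
- background sequence i.i.d. A/C/G/T at 53.65 % GC (the published
  four-strain assembly average) and background genes with one or two
  exons whose proteins are shared across strains.

`mutate_protein()` substitutes uniformly chosen positions with distinct
residues one at a time until the measured global identity first drops
to the target, so realized divergence tracks the target to within one
substitution (±100/L percent); the calibration test requires ±2 points
at length ≥ 200 aa. The PhB allele keeps its first 8 and last 4
residues fixed (so both alleles remain valid precursors) and the
interior substitution count is solved from the whole-peptide target;
on a 55-aa peptide the realized identity is accordingly looser.

A stop-codon guard is placed in frame immediately 5′ of every planted
forward-strand ORF so that a chance upstream in-frame ATG in random
intergenic sequence cannot extend the ORF and displace the N-terminal
signatures out of the search window.

The generator does **not** model introns with splice signals (CDS
segments are planted directly), repeats, GC heterogeneity, degenerate
telomere variants, or annotation noise (labels are always correct).
Passing recovery tests therefore demonstrates the correctness of the
algorithms under clean annotations, not robustness to mislabelled or
missing gene models — on real data, the label keyword lists and the
filter windows are the knobs to adjust.

Everything is a deterministic function of `(designs, scale, seed)`: a
single seeded stream is threaded through all steps, and the caller's
RNG state is saved and restored.

## Numerical and design choices

- Internal coordinates are 0-based half-open everywhere; GFF3's 1-based
  inclusive convention is converted exactly once, at the file boundary.
- Codons containing `N` translate to `X`; the standard genetic code
  (table 1) is the default, as no alternative code applies to these
  nuclear genes.
- GC content excludes `N` from the denominator, standard assembly-stats
  practice.
- N50 is the smallest length *L* such that contigs ≥ *L* sum to at
  least half the assembly.
- Reciprocal-best ties (equal identities) resolve to the first index in
  coordinate order; allele labels are stable for a fixed input order
  and consistent under permutation up to relabelling.
- Degenerate inputs are contracts, not crashes: empty FASTA reads as an
  empty set, a receptor without any precursor candidate yields a
  single-anchor locus with a warning, a single-strain run skips the
  compatibility stage with a warning, and a strain failing mid-pipeline
  is isolated while the others continue.

## Problem sizes

The test suite and the acceptance script run the generator at the
"test" scale — twelve chromosomes of 30–60 kb, four strains, ~0.5 Mb
per genome — which exercises every code path in seconds while keeping
alignment work (the dominant cost: all-vs-all locus pairing across six
strain pairs) modest. A "paper" scale profile (1–2.5 Mb chromosomes)
exists for soak testing; no algorithm has super-linear behaviour in
chromosome length except the terminal-window telomere scan, which is
effectively linear.

## Known limitations

- Locus discovery is label-driven; assemblies annotated without
  homeodomain/pheromone-receptor labels need a keyword list matched to
  their annotation vocabulary (or an upstream HMM scan, which is out of
  scope here).
- Published inter-allele identity values depend on the (unstated)
  alignment convention used to compute them; with the default scoring
  the generator's targets are recovered to within the documented
  tolerance, but reproducing a specific printed percentage for real
  proteins may require switching the denominator mode or scoring
  matrix.
- The compatibility rule is genetic, not phenotypic: it predicts allele
  complementarity, not mycelial vigour or clamp-connection frequency.
- Telomere detection is exact-match only, by design.
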