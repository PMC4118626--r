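---
title: "saltmir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{saltmir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmir)
```

# Scope

`saltmir` re-implements, as a reusable and tested pipeline, the standard
genome-wide small-RNA-seq analysis used to catalogue salt-responsive
microRNAs in a woody plant: four libraries (salt-treated and control, leaf
and root: `3dSL`, `3dCKL`, `3dSR`, `3dCKR`) are cleaned, collapsed to
unique tags, annotated against a genome and reference sets, mined for
conserved and novel miRNA hairpins with miRNA* evidence, matched to
candidate target transcripts, and compared between libraries with an exact
count-ratio test. Because no public sequencing data accompanies this kind
of study, the package ships a first-class synthetic-data generator that
emulates the design, so every stage is testable offline.

# The models and procedures

## Read cleaning

Raw reads are classified in a fixed, mutually exclusive order: low quality
(mean Phred < 20 or more than 2 `N`), 5' adapter contaminant (read starts
with the first 8 nt of the 5' adapter), 3' adapter null (the adapter's
8-nt seed is absent), insert null (adapter at position 1), polyA (insert
at least 80% A, or a run of 10 A), and length out of range (insert outside
the closed interval 18-30 nt). The order mirrors the order in which the
categories are conventionally listed; because categories are assigned
winner-takes-all, `raw = clean + sum(removed)` holds exactly per library.
The polyA and quality thresholds are not standardized in the literature,
so they are parameters of `clean_params()` with the defaults above.

The adapter seed is searched at *any* position: a hit at position 1 is an
empty insert, no hit means the adapter (and hence a real insert) is
missing, and short inserts (1-17 nt) are left to the length filter. T and
U are identified everywhere (the internal canonical alphabet is DNA).

## Annotation hierarchy

Tags are mapped to the genome by perfect match only, on both strands
(`map_perfect`, `Biostrings::matchPDict` per width class). Mapped tags get
exactly one category by priority:

`known_miRNA > ncRNA > repeat > exon_sense > exon_antisense >
intron_sense > intron_antisense > unknown`

Known-miRNA membership is sequence-level (at most 2 mismatches against the
mature reference, gapless, sliding with full overlap); ncRNA membership is
an exact substring match against the ncRNA reference; repeat/exon/intron
need at least 1 bp of genomic overlap, exon and intron split by strand.
Putting `known_miRNA` first keeps the categories disjoint while letting
miRNA reads dominate the read-level distribution, which is how published
category charts (with miRNA fractions of 40% of reads) must have been
tallied even though the prose describes ncRNA exclusion first. Multi-locus
tags are categorized from the union of their hits and counted once - the
alternative (splitting counts across loci) double-counts reads in the
distribution tables. Introns are derived from the gaps between exons of
each transcript when the GFF omits them.

## Folding engine

`rna_fold()` is a Zuker-style minimum-free-energy dynamic program over a
simplified nearest-neighbor model: Turner-style stacking energies for the
36 pair-on-pair stacks (canonical plus G:U), tabulated hairpin, bulge and
internal-loop penalties with logarithmic length extrapolation and a capped
asymmetry term, an affine multiloop penalty (a = 3.4, b = 0.4 per branch),
minimum hairpin loop 3, and interior loops capped at 15 unpaired bases.
The point is contract fidelity - deterministic MFE structures, negative
MFE for stable hairpins, correct relative ordering - not kcal/mol
agreement with a full thermodynamic package; every downstream threshold is
configurable against the engine. Energies of explicit structures can be
evaluated independently of the DP by loop decomposition
(`structure_energy()`), and a brute-force enumerator over all well-nested
structures serves as the test oracle at small n: the DP provably returns
an energy no higher than any enumerated structure, and in practice equal.

Among co-optimal structures the traceback prefers, deterministically:
interior/stacking extensions first (smallest inner pair indices), then
multiloop splits, then hairpin closure. This replaces ranking co-optimals
by pair count and lexicographic dot-bracket - enumerating co-optimals just
to rank ties costs far more than the determinism it buys, and determinism
is the actual contract.

`is_hairpin()` decides precursor-hood on the *main stem*: the chains of
nested pairs above each terminal loop are followed outward through
single-branch loops; the fold qualifies when exactly one terminal loop
sits on a stem of at least `min_stem_pairs = 16` pairs and the MFE is at
most `mfe_max = -18` kcal/mol (just below the weakest novel precursors
typically accepted). Judging the whole window instead of the main stem
would reject real precursors whenever the excision window drags in a few
incidentally-paired flanking bases, while a second *long* stem (a genuine
two-hairpin region) still disqualifies.

## miRNA discovery

Conserved calling is reference-guided: tags matching a mature reference
within 2 mismatches are grouped by best hit (fewest mismatches, ties by
name), groups with fewer than 5 total reads are dropped, and the
reference precursor (or, failing that, a 150-nt-flank genomic window) must
pass `is_hairpin`. The family is the `miR<number>` token of the winning
reference. Each tag counts toward exactly one record, so downstream
expression tables never double-count.

Novel calling is genome-guided (Mireap-style): unannotated tags with at
least 5 reads and mature-like length (20-24 nt) seed windows with flanks
of 30/60/100/150 nt on each side of each genomic locus; each window is
folded and the minimum-MFE window passing `is_hairpin` - with the mature
on one arm, at most 4 unpaired mature bases, and (by default) a
star-supporting tag on the opposite arm - yields a record. Candidates are
processed in decreasing abundance and each called locus blocks later
overlapping candidates, so the star read of a called hairpin never spawns
a duplicate record. The star check accepts a 3' overhang of 1-3 nt
(canonical 2, plus or minus one for Dicer wobble), measured as the
distance from the star's 3' end to the partner of the mature's 5' end -
an expression that is valid for both 5p and 3p matures.

Whether a study requires star support for *every* novel call or merely
reports the supported ones is usually ambiguous; `require_star` defaults
to `TRUE` (star detection is the robust evidence) and is a flag.

## Target prediction

Plant miRNA targets are predicted by gapless antiparallel complementarity:
each miRNA is slid along every transcript and the duplex is scored with
Allen-style position-weighted penalties - mismatch 1.0, G:U wobble 0.5,
doubled at miRNA positions 2-13, site rejected outright on a true
mismatch at positions 10-11 (the cleavage site) unless explicitly allowed
- keeping sites with score at most 4, the classic "at most four
mismatches" rule. Whether G:U counts as a full mismatch is not
standardized; the default charges half, and `strict_hamming = TRUE` gives
the pure Hamming reading. Per-miRNA target counts are distinct
transcripts, not sites. A brute-force all-offset scorer written
independently in the test suite must agree exactly on random instances.

## Differential expression

Expression is normalized to reads per million: `rpm = count * 1e6 / N`
with `N` the library's clean-read total. For counts `x` (library 1) and
`y` (library 2) with sizes `N1`, `N2`, the exact conditional distribution

$$p(y\mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}$$

is computed in log space via log-gamma (it is the negative-binomial
NB(x+1, N1/(N1+N2)) mass, so it sums to one - a property the tests check
to 1e-9). The lower tail `C = sum_{k<=y} p(k|x)`, upper tail
`D = sum_{k>=y} p(k|x)` (so `C + D = 1 + p(y|x)`), and the two-sided
p-value `min(1, 2 min(C, D))` are computed by summing the *smaller* tail
directly, which preserves relative precision for extreme counts. One
subtlety the tests document: with inclusive tails the label swap
`(x,N1) <-> (y,N2)` maps `C` to `D` only up to the boundary point mass
(`C(x,y) = D(y,x) - p_point`); the exact identity is asserted rather than
the naive swap.

Calls: miRNAs with both normalized values below 1 RPM are `filtered`
(filtering on *either* value would make a gene fully switched off by
treatment uncallable); a zero on one side is substituted with the 1-RPM
floor before the fold-change so `log2fc` stays finite, and the
substitution is flagged in the output. `up` means `log2fc > 0.5` and
`p < 0.05`; `down` the mirror image. The 0.5 threshold (not 1.0, which
also circulates for this design) governs the headline result sets, and
both cutoffs are parameters. No multiple-testing correction is applied by
default - single-library designs cannot absorb an FDR - but a
Benjamini-Hochberg flag (`fdr = TRUE`) is provided.

# The synthetic world

`sim_config()` states the simulated world once; tests never tune it.

* **Libraries:** the four-library design, 1e5 raw reads each by default.
* **Lengths:** background read lengths follow a fixed mixture over
  18-30 nt with mode 21 nt (0.40), second mode 24 nt (0.20), and 84% of
  mass in 20-24 nt - the shape such libraries show. Locus reads have the
  length of their planted mature (sampled once per locus from
  20/21/22/24 at 0.15/0.55/0.10/0.20), so the goodness-of-fit invariant
  is asserted on the background class, where the mixture is the
  distribution.
* **Genome:** i.i.d. uniform ACGT, 2 chromosomes of 50 kb - the simplest
  null that does not generate accidental hairpins at a material rate.
* **Loci:** 20 conserved miRNA loci (weights: a dominant miR156 family
  with 60% of conserved expression, two 10% families, the rest sharing
  20% - the skew such catalogs report), 10 novel loci (first nucleotide
  G, the enrichment reported for new plant miRNAs), 6 ncRNA loci, 8
  two-exon genes, 5 repeats. Precursors are built as
  `flank + mature-arm + A/C loop + complementary arm + flank`, which
  guarantees a qualifying hairpin, with the star sequence carrying the
  canonical 2-nt 3' overhang by construction; arms are 5p with
  probability 0.6.
* **Counts:** negative-binomial (Gamma-Poisson) per locus with dispersion
  0.05; dispersion 0 degenerates to Poisson. Treated libraries multiply
  the mean by `2^log2fc`; by default three conserved loci are planted at
  +2, three at -2, one novel at +2 and one at -2. Star reads accompany
  matures at a fixed 0.15 fraction.
* **Contaminants:** adapter-null 2%, insert-null 1%, polyA 1%,
  low-quality 2% (genuine reads whose quality strings are rewritten below
  the threshold, so the quality filter specifically is exercised), 5'
  adapter 0.5%. Reads are insert + 20-nt 3' adapter, padded/truncated to
  40 nt, Phred+33.
* **References:** conserved matures (plus five decoys) form the
  miRBase-style reference in RNA space; novel matures are deliberately
  absent from it. Every planted mature gets one transcript containing a
  near-complementary site (0-2 mutations placed only against miRNA
  positions >= 14, so the site always scores <= 4).

What the generator does *not* emulate: sequencing error beyond the quality
rewrite, PCR duplication, strand bias, isomiR spread, genome repeat
structure, or realistic transcriptome composition. A green recovery test
therefore establishes that the pipeline's logic is correct on data obeying
its assumptions - not that the thresholds are well-calibrated for any real
library, whose depths and composition are unknown here. Library depths per
category were never published for this design; the class fractions
(conserved 38%, novel 5%, ncRNA 8%, exon 5%, intron 2%, repeat 2%,
background 40%) were chosen once to resemble the published category
distributions and are not revisited.

# Numerical choices and degenerate inputs

* Folding rejects sequences under 15 nt or outside `{A,C,G,U/T}`; a
  sequence with no favorable pairing returns the open chain at exactly
  0 kcal/mol.
* Tail sums in the exact test switch to the upper tail when `y` exceeds
  the conditional mode `x * N2/N1`, terminating when increments fall
  below 1e-17 of the accumulated mass.
* `rpm` refuses `N <= 0`; the exact test refuses negative counts.
* Ties in conserved naming break by lowest mismatch count, then
  alphabetical reference name; novel records are numbered in calling
  order (decreasing abundance).
* Percentages in the summary tables are rounded to 2 decimals at the
  table boundary only; nothing upstream is rounded.
* Stage caching in `run_all()` is checksum-based (md5); a corrupted
  intermediate halts the run naming the file, and a changed config
  invalidates every stage.

# Known limitations

* The energy parameters are Turner-style but abbreviated; absolute MFE
  values differ from full thermodynamic engines (published per-study MFE
  summary statistics are engine-specific and are not reproduction
  targets). The engine is pluggable in the sense that every consumer
  takes thresholds against whatever engine produced the fold.
* Gapped/spliced alignment and indel-tolerant matching are out of scope
  (the underlying analyses allow mismatches only).
* GO/KEGG enrichment is out of scope; `annotate_targets()` is a plain
  left join of user-supplied labels.
* Cross-species homolog search of novel miRNAs against a full miRBase is
  out of scope (external database dependent).

# A worked example

```{r example, eval = FALSE}
library(saltmir)
out <- file.path(tempdir(), "demo")
run_all(list(seed = 1, outdir = out,
             simulate = list(enabled = TRUE, reads_per_library = 20000)))
read.delim(file.path(out, "de_3dSL_vs_3dCKL.tsv"))[1:5, ]
```

The README shows the output this produces and how to read it.
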