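---
title: "Calling RNA-RNA interactions from CLASH chimeric reads"
author: "clashr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA-RNA interactions from CLASH chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clashr)
```

## The problem

CLASH (crosslinking, ligation and sequencing of hybrids) captures RNA-RNA
interactions physically: the two strands of a protein-bound RNA duplex are
ligated into one chimeric molecule, reverse-transcribed and sequenced. A
chimeric read therefore contains two non-contiguous fragments -- in the
miRNA/AGO setting, typically a full mature miRNA joined to a short mRNA
fragment. Chimeras are rare: the bulk of the library is ordinary contiguous
cDNA, so the computational task is to find a small number of two-fragment
reads among millions of one-fragment reads, assign each fragment to a
transcript, and reject the many ways a read can *look* chimeric without
being evidence of an interaction (splicing, multi-mapping, unremoved
adapter, PCR duplication).

`clashr` implements the complete analysis as composable R functions plus a
shell-style front end, with a synthetic-library generator so that every
stage can be exercised and benchmarked without external data.

## Preprocessing model

**Demultiplexing.** 5' barcodes combine a sample-specific multiplexing code
with random positions (`N`) used to monitor PCR amplification. We enumerate,
once, every read prefix compatible with a barcode under 0 (default) or 1
substitutions at coded positions (never at `N` positions, no indels) into a
hash table; demultiplexing then performs one substring extraction and one
hash lookup per read -- no per-read string comparisons. Codes whose Hamming
distance is not greater than twice the allowed mismatches are rejected as
ambiguous at table-build time; prefixes compatible with two samples (possible
when patterns place their `N`s differently) route to `unassigned`, as do
unmatched reads, so the output is an exact partition of the input.

**Adapter trimming.** The 3' linker is removed by finding the longest read
suffix matching a prefix of the linker with at most one mismatch per 10
matched nucleotides (floor), subject to a minimum match length `min`
(default 4 nt; 0 disables trimming). A full internal occurrence of the
linker removes it and everything 3' of it. The tolerance approximates the
behaviour of the common standalone trimmers; the trimmer is deliberately
pluggable -- externally trimmed FASTQ is accepted unchanged.

**Quality trimming** uses the BWA-style running-sum rule: scanning from the
3' end, the read is cut at the position maximising the accumulated
`(threshold - quality)`; threshold 0 disables. Only Phred+33 is accepted;
other encodings are rejected rather than silently misread. Reads shorter
than `len` (default 17 nt) are then discarded.

**Collapsing.** Identical sequences are collapsed to one record named
`K-L_M` (or `K_M` without barcodes): K the frequency rank (ties broken
lexicographically by sequence -- the tie-break is arbitrary but must be
deterministic), L the number of distinct random barcodes, M the number of
reads collapsed. L distinguishes PCR duplicates (one barcode, many copies)
from genuinely abundant molecules (many barcodes). The sum of M over
records always equals the input size.

## Alignment model

Reads are mapped against a transcript database (a plain FASTA whose
underscore-delimited headers end in `displayName_biotype`, keeping the
transcript class in-band) with a built-in seed-and-extend local aligner:

* exact `word`-length seeds (default 11 nt) located through a k-mer hash
  of the database;
* seeds on one subject are clustered (cluster break when consecutive seed
  positions are farther apart than the read length), and each cluster
  window is aligned by full Smith-Waterman with affine gaps. Within a
  window the reported score therefore *equals* the exhaustive
  local-alignment score -- the test suite checks this against an
  independent full-matrix oracle;
* scoring +1 match, -2 mismatch, gap of length L costs 5 + L (the local
  short-read aligner convention); hits require score >= 15; both strands
  are searched and reverse-strand hits carry `s_start > s_end`, the
  blast-tabular antisense convention;
* hit lists are deterministic: sorted by score, ties broken by
  (subject id, subject start), capped at 20 per read.

Externally produced 12-column blast-tabular alignments can be ingested
instead (`align=none`); both routes feed the chimera caller through the
identical hit contract.

**E-values.** The caller thresholds fragments on e-values for every
backend, so the built-in aligner must produce one. We use ungapped
Karlin-Altschul statistics: `E = m * n * 2^(-B)` with
`B = (lambda * S - ln K) / ln 2`, where lambda is the unique positive root
of `sum_ij p_i p_j exp(lambda * s(i,j)) = 1` under uniform base composition
(1.3327... for +1/-2, solved numerically and checked against a frozen
bisection constant) and K = 0.621, the standard published ungapped value
for this scoring scheme. `m` is the read length and `n` the total database
length; no edge correction is applied, for simplicity and determinism. The
default threshold `hval = 0.1` is calibrated against this formula: a 15-nt
exact match passes comfortably at desk-scale database sizes. This
score-to-E conversion is a documented design choice; external aligner
e-values are used verbatim.

## Chimera calling

For each read, processing hits in descending score order, we *record*: the
top-scoring match; all matches tying the top score; any match whose gap or
overlap with the union of already-recorded read intervals is at most
`gmax` nt (default 4); and alternative equal-score placements of an
already-recorded fragment (same read interval and score), which is how
multi-mapping is observed. Hits with e-value above `hval` are never
recorded. A *fragment* is the set of recorded hits sharing a read
interval; fragments with more than `hmax` (default 10) distinct
(subject, strand, interval) locations are excluded outright -- in practice
this is what removes reads whose mRNA segment comes from a gene with many
identical database isoforms.

*Candidates* are all pairs of recorded matches, in read order, with
`|gap_or_overlap| <= gmax`, excluding self-pairs and read-interval
containment, where `gap_or_overlap = second.q_start - first.q_end - 1`
(positive gap, negative overlap, 0 adjacent). A read whose best match
covers at least `read_len - gmax` nucleotides is non-chimeric (contiguous
match) and yields no candidates at all; this single rule is what sends
ordinary cDNA reads, including spliced mRNA reads mapped to transcripts,
to zero calls.

One call per read is then selected lexicographically: (1) maximum sum of
the two fragments' scores; (2) with `pref=mim`, miRNA-mRNA pairs outrank
others among score ties; (3) best transcript ranks from the *alignment
reference* -- transcripts ranked by total mapped reads (collapse-weighted,
each read counted once per transcript), shareable across samples so
related experiments make consistent assignments; rank pairs are compared
better-rank-first, then worse (ranking by total mapped reads leaves the
pair comparison open; this ordering is our concretisation); (4) a final
lexicographic tie-break on transcript ids for determinism. Antisense
fragments disqualify a pair unless `anti=1` (genomic databases). With
`type=mim`, only miRNA-mRNA pairs are eligible, and surviving calls are
*extended*: the miRNA fragment to the full mature miRNA, the target by 25
nt on each side (clamped to the transcript), compensating for reads that
do not cover the whole chimeric cDNA.

Open point resolved here: a read with a contiguous full-length match is
rejected even if a higher-scoring fragment pair exists -- the rejection
rule is applied first, as the conservative reading.

## Duplex folding

Chimera fragments are folded as an intermolecular RNA-RNA duplex. We fold
*database-extracted* transcript subsequences at the (possibly extended)
call coordinates, never the read, because crosslinking-induced
substitutions and deletions in reads are irrelevant to in vivo pairing.

The model is a nearest-neighbor stacking model restricted to
intermolecular pairs (no hairpins): Watson-Crick and GU pairs; Turner-style
stacking free energies at 37 degrees C with the strand-flip symmetry
`G[p,q] = G[rev(q), rev(p)]` enforced (making `dG(s1,s2) = dG(s2,s1)`
exact); a duplex initiation penalty of +4.09 kcal/mol; interior/bulge
loops penalised affinely as `2.0 + 0.5 * n_unpaired` kcal/mol, capped at
30 unpaired nt per loop. The affine loop penalty is a documented
simplification of the fully tabulated loop model used by the standalone
hybridization programs; any consistent nearest-neighbor table satisfies
the package's correctness obligations (the MFE is checked against an
exhaustive enumeration oracle sharing only the energy tables, and every
reported structure is re-scored independently). Consequently absolute dG
values are comparable *within* a clashr analysis but are not calibrated to
match any particular external program's output. `N` never pairs; `T` is
read as `U`; if the best chain is non-negative the empty structure with
dG = 0 is returned, so dG <= 0 always and dG = 0 iff no pairs. The
temperature/ionic convention is the standard 37 degrees C, 1 M NaCl of the
published tables.

Structures are written in dot-bracket notation with `(` in strand 1, `)` in
strand 2 and `&` between the strands (the viennad block layout used here --
six lines: read id, each fragment sequence with its coordinates, the joined
sequences, the structure, and the energy -- is fixed by this package; the
format's originators did not print an example).

## Merging and QC

Calls of the same ordered transcript pair merge transitively when their
fragment-1 intervals *and* fragment-2 intervals each overlap by at least
1 nt (the both-fragment requirement distinguishes this from a plain
interval merge; 1 nt is the minimal reading of "overlap required"; merging
uses extended coordinates when extension was enabled). Interactions report
envelope spans, chimera and collapse-weighted read counts, mean dG over
folded members (unfolded members are ignored rather than failing), and
sorted supporting read ids, making the result independent of input order.

Three intrinsic QC statistics summarise a run: mean folding energy,
fraction of miRNA-mRNA chimeras with a seed match (defined canonically as
an exact occurrence of the Watson-Crick complement of miRNA nt 2-7 in the
target fragment -- the minimal 6-mer seed), and the fraction of chimeras
with zero gap/overlap. In true interactions folding is stronger, seed
fraction higher, and fragments more often exactly adjacent.

## The synthetic generator

The generator emulates the components of a CLASH library so the pipeline is
testable end to end without downloads:

* `make_transcript_db()`: uniform-i.i.d. random mRNAs (default 300-600 nt)
  plus 22-nt miRNAs; a fraction of genes (default 10%) carries extra
  *exact-duplicate* isoforms (`redundancy` copies), emulating transcript
  databases in which isoforms share exons, the dominant cause of
  multi-mapping losses;
* `make_fusion_reads()`: mature miRNA concatenated with a 30-nt mRNA
  segment (either order), optional linker remnant, with a ground-truth
  table; segments are drawn per *gene*, so database redundancy affects
  mapping, not sampling. The optional `plant_site` mode writes the
  complement of miRNA nt 2-8 into the database target window, giving the
  folding/seed statistics genuine positives;
* `make_contiguous_reads()`: 50-nt mRNA segments, the non-chimeric null;
* `make_multiplexed_fastq()`: barcoded molecules with Poisson PCR
  duplication for the demultiplex/collapse stages.

All generators are pure functions of (parameters, seed). The benchmark
conditions used by the acceptance suite are 10,000 fusion reads against a
database of 300 genes + 30 miRNAs with 12-fold redundancy on 10% of genes;
under these conditions the pipeline recovers 88-89% of planted chimeras
with default parameters, with losses dominated by the `hmax` exclusion of
redundant-gene fragments plus occasional chance overlaps at the
breakpoint -- the same two loss modes reported for real benchmark data.
Contiguous libraries yield exactly zero calls.

What the generator does *not* emulate: realistic base composition and
repeat structure, sequencing errors beyond an optional uniform model,
crosslinking-induced deletions, partial linker read-through, or the true
length distribution of CLASH inserts. Passing the synthetic benchmark
therefore demonstrates the correctness of the algorithms, not the
end-to-end sensitivity on biological libraries.

## Numerical and design choices

* Oracle suites in the tests run at deliberately small sizes (alignment
  instances up to 60 x 200 nt, duplex pairs up to 12 + 12 nt, and the
  full benchmark at 10,000 reads) -- sizes chosen to make exhaustive
  reference computations practical while exercising every code path.
* All tie-breaks (rank ties, score ties, collapse-rank ties, hit ordering)
  are lexicographic and documented, so identical inputs give byte-identical
  outputs; reruns of the command-line pipeline are verified byte-identical.
* Coordinates are 1-based inclusive everywhere (.hyb, viennad, GFF3,
  blast-tabular); BED12 input is converted on ingestion. Antisense
  orientation exists only in alignment hits (`s_start > s_end`); .hyb
  output stores ascending coordinates.
* The `.hyb` energy column is `.` when a call is unfolded, parsed back as
  missing; e-values below 1e-3 print in minimal scientific notation
  (`2e-04`) so written files round-trip byte-identically.
* `transcript_to_genome()` projects through ordered exon blocks with exact
  length conservation; it is implemented as direct interval arithmetic and
  validated by a length-conservation property over random intervals.
* The command-line front end re-uses intermediates only when the output is
  newer than its input *and* carries an identical parameter fingerprint,
  replacing a build-system-style dependency mechanism with an ordinary,
  inspectable rule.

## Known limitations

* One call per read: reads supporting three-fragment chimeras or several
  alternative interactions yield a single best call.
* The built-in aligner requires an exact `word`-length seed; heavily
  mutated or very short fragments can be missed where an exhaustive
  aligner would still find a scoring alignment (mitigated by lowering
  `word`).
* Folding reports a single MFE structure, not an ensemble, and its
  absolute energies depend on the embedded parameter table (see above).
* Genome-mode calling (`anti=1`) accepts antisense fragments but performs
  no splice-aware reasoning; transcript databases remain the recommended
  reference, as splice-junction reads then map contiguously.
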