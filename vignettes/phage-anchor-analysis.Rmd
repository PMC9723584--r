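---
title: "Anchor-gene context, CRISPR host prediction and transcriptional activity: methods"
author: "phagecontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene context, CRISPR host prediction and transcriptional activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Setting

Some large phages carry a copy of the bacterial ribosomal protein S21 gene
(bS21). In the genomes this package was designed around, that gene sits on
the reverse strand inside a conserved region that also encodes the core
structural proteins — large terminase (TerL), portal vertex protein,
prohead protease and major capsid protein (MCP) — flanked immediately by two
conserved hypothetical-protein families. Three questions follow naturally:
*is the architecture conserved?* (neighborhood profiling), *who is the
host?* (CRISPR spacer targeting), and *when is the gene used?*
(metatranscriptome-derived expression). `phagecontext` implements each as a
reusable, tested computation over standard formats, and couples them to a
synthetic-data generator whose ground truth makes every stage falsifiable.

## Conventions

* **Coordinates** are 0-based half-open everywhere inside the package; GFF3
  1-based inclusive coordinates are converted at the I/O boundary only.
  Wrap-around genes on circular genomes are rejected at parse time — there
  is no accepted convention for them, and the generator never emits them.
* **Read identity** is `1 − mismatches / read_length`, with mismatches taken
  from the NM-style edit count: 3 mismatches on a 150 bp read is 98%. The
  alternative (edit distance over the *aligned* length) is arguably more
  robust to clipping; we chose read length because it reproduces the
  "three mismatches ≡ 98%" arithmetic exactly and is what a mapper's
  post-filter sees. The threshold and the statistic are both per-record;
  supplementary lines of a split read are filtered independently.
* **Ties** break lexicographically (labels, residues, IDs) and windows break
  leftmost; every such rule is deterministic and documented at the function.

## Neighborhood profiling

`extract_neighborhood()` takes up to 10 genes each side of the anchor in
scaffold order (position 0 = anchor; truncation at scaffold ends is
recorded). Because assemblies arrive in arbitrary orientation, an optional
reorientation flips all signs when the designated marker family (default:
the major capsid protein label) falls on the negative side — mirrored
assemblies then produce identical profiles, which the test suite checks on
a constructed mirror pair.

Neighbor proteins are clustered by **single-pass greedy centroid
clustering**: proteins are sorted by length (descending, ties by ID) and
each joins the first centroid reached at identity ≥ 0.30 with the local
BLOSUM62 alignment covering ≥ 0.75 of both sequences, else founds a new
family. This replaces a published two-step pipeline (subfamily clustering
followed by profile–profile HMM merging at the same 0.75 coverage): building
and comparing profile HMMs is out of scope here, but the contract that
matters downstream — families defined by identity plus *mutual* coverage —
is preserved, and both thresholds are arguments. The 0.30 identity default
is our stated choice (the upstream pipeline does not publish one); the sort
makes the partition canonical under input permutation, which is asserted in
tests. A length-ratio prefilter (`min/max ≥ 0.75 × 0.8`) skips alignments
that could never satisfy mutual coverage; the 0.8 slack leaves room for
gapped spans.

Identity here is matches / alignment length (gaps count against identity),
and coverage is the aligned span over each sequence's own length — the same
semantics as the common greedy clusterers (CD-HIT, usearch-style) in
local-alignment mode.

**Consensus annotation**: among hits with e-value < 1e−5, the label hitting
the most distinct member proteins wins if it hits ≥ 5% of members; ties
break lexicographically; otherwise the family is `"hyp"`. The comparison
`count ≥ min_frac × size` carries a 1e−9 epsilon so binary floating point
cannot flip an exact-boundary case (0.05 × 60 is not representable).

**Position profiles** count *genomes*, not genes, per (family, relative
position) cell — the published bubble plots size circles by the number of
phages — so a genome with two anchors still contributes at most one count
per cell. Per-family mean |distance| to the anchor is reported alongside.

**Presence/absence clustering** of genomes ≥ 100 kbp (configurable; the
synthetic tests lower it to admit test-scale genomes) uses the binary
genome × family matrix, Jaccard distances (`stats::dist(method =
"binary")`), average-linkage `hclust`, and `ape` for the newick export. The
shared core is the count of families present in every retained genome.

## CRISPR spacers and the dual rule

`detect_arrays()` is a desk-scale stand-in for a dedicated array finder:
exact seed words of the minimum repeat length (21 bp) that recur at
spacings compatible with the repeat (21–48 bp) and spacer (18–72 bp) ranges
are chained (≥ 3 copies) and extended outward. A column joins the repeat
only if it is ≥ 80% unanimous across copies *and* keeps every copy within
the per-copy Hamming budget (default 2) of the first copy — the unanimity
test is what stops extension from eating into the random spacers. Two
consequences are documented limitations: a repeat copy whose every
length-21 window is disrupted by mismatches will not seed, and in a 3-copy
array a single deviant copy blocks extension at its column. With exact
repeats — the generator's default, and typical of real arrays — recovery is
byte-exact, which the tests assert.

`match_spacers()` applies the dual acceptance rule — **≥ 24 nt with ≤ 1
mismatch, or ≥ 30 nt with ≤ 3 mismatches** — as a substitution-only
(Hamming) scan of every diagonal of the spacer × target comparison, both
strands. Indels are excluded deliberately: the rule is expressed purely in
match length and mismatch count, so a gapped alignment would make the
contract ambiguous. The published heuristic pre-search (blastn-short at 70%
identity) is not reproduced; at desk scale the final filter can be applied
exhaustively, and it is the filter that defines the result. Overlapping
qualifying windows on one (spacer, target, strand, diagonal) locus reduce
to a single hit: maximal length, then minimal mismatches, then leftmost.
The implementation uses cumulative mismatch sums and two-pointer maximal
windows per diagonal; the test oracle enumerates every (spacer offset,
window length, target offset) triple by direct character comparison — two
independent routes that must agree exactly, which is the package's primary
acceptance property. Whether a "minimum match of 24 nt" should mean window
length or whole-spacer length is genuinely open; we use window length, so a
longer spacer may match through a 24 nt sub-window.

`predict_hosts()` aggregates hits per (phage, host); an empty table is a
valid, successful outcome — in real surveys a catalogue of thousands of
spacers can yield no qualifying hit at all, or a single exact one.

## Detection, abundance, NTL

A genome is **detected** in a sample when ≥ 90% of its positions are
covered by at least one read of ≥ 97% identity; its **coverage** is total
aligned bases of passing reads divided by the *covered* length (so coverage
is conditional on presence, not diluted by undetected span). "Total length
of mapped reads" is interpreted as aligned target bases rather than raw
read lengths — robust to soft-clipping, and identical for the indel-free
simulated reads; this is a documented divergence risk from the unstated
original. Breadth via `IRanges::reduce()` is checked against per-position
boolean arrays in tests.

**NTL** of a gene is `total_base_gene / length_gene / total_read_genome` at
≥ 98% RNA identity, defined only when ≥ 80% of gene bases are covered.
`total_read_genome` counts every passing record mapped anywhere on the
genome — including reads outside all genes — because the formula normalises
by the genome's transcriptional recruitment, not the gene set's. Records of
multi-mapped reads count once per target genome with no rescaling or
deduplication. Partial overlaps contribute only overlapping bases. Useful
invariants, all tested: duplicating every record leaves NTL fixed; adding
reads outside a gene strictly decreases its NTL; summed `ntl × length ×
reads` never exceeds total mapped RNA bases.

**rpS3 profiling** mirrors the cd-hit-est dereplication contract
(`-c 0.97 -aS 0.5 -aL 0.5`): markers ≥ 300 nt, greedy longest-first
dereplication at 0.97 identity with 0.5 mutual coverage, reads filtered at
≤ 3% mismatch, coverage = mapped bases / representative length, summed per
taxon.

## Two-group divergence

External divergence/conservation scorers (Zebra2, TwinCons) are replaced by
an explicit modal-frequency statistic, because their internals are not
described in the motivating work and a reusable pipeline needs a defined
contract: a column is **divergent** when both groups are internally
conserved at ≥ `tau_group` (default 0.7) on *different* modal residues, and
**conserved** when the pooled modal frequency is ≥ `tau_cons` (default
0.9). Columns with > 50% gaps are uncallable. The statistic is symmetric
under group exchange; because "significant divergence" has no agreed
quantitative meaning across scorers, these flags are threshold-based and
labelled as such. Consensus sequences emit the modal non-gap residue at ≥ 50% (else
`x`; majority-gap columns emit `-`). Reference numbering maps alignment
columns to 1-based residue numbers of a designated reference by ungapped
counting — reporting follows the Tyr54 style — and the aromatic check tests
membership in {F, Y, W, H}, since tyrosine, histidine and phenylalanine are
the residues observed at that position.

## The synthetic world

The generator's defaults are the stated conditions of the emulated data,
chosen once:

* **Genome length 30 kb** at test scale (the real curated genomes are
  293–331 kbp; `genome_length = 300000` reproduces that scale — everything
  else is length-agnostic). **GC 0.32** and **coding density 0.93** sit
  inside the reported 31.0–33.7% and 91.1–94.9% ranges. The codon sampler's
  base-level GC is calibrated analytically (inverting the stop-codon
  exclusion and mutation drift) so realized genome GC centers on the
  target; the generator contract — GC within ±2 points, density within ±3 —
  is asserted in tests.
* **Architecture**: bS21 (strand −) between two hypothetical families at
  ±1, TerL/portal/prohead-protease/MCP within 5 genes, all on the opposite
  strand to the anchor.
* **Clades**: conserved-module and shared-core proteins derive from common
  ancestors mutated at 8% per residue per clade (cross-clade amino-acid
  identity ≥ ~80%, comfortably above the 0.30 clustering threshold);
  members are whole-genome substitution-only copies of their founder at
  `within_clade_divergence = 0.02` per site, so two siblings share expected
  nucleotide identity `(1−d)² + d²/3 ≈ 0.9601`. Clade-specific accessory
  genes and per-genome singletons make presence/absence clustering
  informative; note the singletons dilute whole-genome sibling identity in
  the full multi-clade simulation (the pure mutated-copy identity applies
  to `generate_phage_genome(clade_seed = )`).
* **Reads**: 150 bp, Poisson read counts at the requested depth, per-read
  mismatches Binomial(length, `error_rate = 0.005`) — the error rate is a
  stated default, not inferred from the study, whose read error model is
  unpublished. RNA reads fall wholly inside one gene with probability
  proportional to weight × length, because base-level per-gene counting
  does not define junction handling. DNA reads may wrap the circular
  origin (two blocks).
* **Expression profile**: anchor and structural genes high (MCP highest),
  flanking co-transcribed hypothetical high, background 1 — the qualitative
  pattern of a late-stage replication transcriptome.
* **CRISPR hosts**: one array of exact repeats (28–36 bp) with spacers
  sampled from the phages at exact, controlled substitution counts, which
  is what makes the dual-rule recovery tests sharp.
* **Group MSAs**: gapless, with planted divergent columns (groups ≥ 90%
  internally conserved on different residues) and an aromatic column drawn
  from Y/H/F with Y predominant.

What a green recovery test establishes is that the implementation honours
its contracts on data with exactly the assumed structure. It does not
establish performance on real data: no indels or rearrangements, no strand
bias, no chimeric reads, no quality scores, no diverged repeat arrays, no
alignment uncertainty — the generator states its world; real metagenomes
are messier in all of these directions.

## Other numerical choices and limitations

* The detection boundary is inclusive (breadth exactly 0.90 is detected);
  tests pin the flip at one base below.
* The ORF caller is deliberately naive (ATG-only starts, no RBS model,
  linear scan even on circular genomes, N-containing codons void a
  putative ORF since N-runs mark scaffolding gaps); real users should
  supply annotations.
* Whether published coding densities count overlapping genes once or twice
  is unstated; we use union semantics (once), checked against a per-base
  oracle.
* SAM support is a narrow dialect (POS/FLAG/CIGAR/SEQ-length/NM + `@SQ`),
  written and read by the package itself; BAM/CRAM, qualities and proper
  pair handling are out of scope. Multi-block records export as one
  primary plus soft-clipped supplementary lines carrying the full mismatch
  count on the primary.
* The CLI (`pcx_cli()`, thin Rscript in `inst/exec/`) emits deterministic
  bytes for fixed seeds; its parameters are plain flags rather than a
  config file, which keeps the chain reproducible from shell history.
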