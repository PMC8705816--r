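---
title: "Models and methods behind bifidophage"
author: "bifidophage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bifidophage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bifidophage` is a desk-scale pipeline for the comparative genomics of
prophages and CRISPR-mediated phage immunity in human-associated
*Bifidobacterium* (B. adolescentis, B. bifidum, B. breve and the two
B. longum subspecies). This vignette explains the models the package
implements, the tunable parameters, the synthetic-data generator used for
validation, and the numerical choices and limitations a careful user
should know about.

## Prophage region curation

Detection is annotation-driven. A **candidate region** is a maximal run of
CDS features whose products match a small, editable **phage lexicon**
(keyword to module: integrase/recombinase/excisionase for
integration/excision; holin/endolysin for lysis;
primase/helicase/polymerase/replication for DNA replication;
capsid/head/tail/baseplate/tape measure/scaffolding for head/tail
morphogenesis; terminase/portal/packaging for DNA packaging), with
consecutive matches at most `max_gap` (5 kb) apart and at least `min_hits`
(4) matches. The lexicon replaces HMM-based viral-protein annotation,
which requires an external profile database; keyword matching against
annotation products is transparent, editable
(`inst/extdata/phage_lexicon.tsv`) and sufficient for annotated genomes.

**Boundary refinement** iterates three absorption criteria to a fixed
point, separately on each side:

1. a tRNA gene or an integrase-product CDS within 2 kb beyond the edge is
   absorbed — temperate phages integrate site-specifically, typically at
   tRNA genes, with the integrase at the prophage boundary;
2. a run of hypothetical-protein CDS bridged by a lexicon-matching CDS is
   absorbed together with that CDS (unannotated phage genes frequently
   sit between recognisable ones);
3. the next CDS is absorbed while it lies on the same strand as the
   current edge CDS with an intergenic gap under 1 kb — a proxy for
   co-transcription.

Refinement only widens intervals and is capped at 15 kb per side; the 2 kb
window and the cap are package choices (the criteria themselves state no
distances beyond the 1 kb gap rule) that prevent runaway absorption of
host operons. Refinement is idempotent, which the test suite checks
directly.

**Completeness** is a three-way call. A region is a `remnant` if it is
shorter than 13 kb *or* carries neither head/tail nor DNA-packaging genes;
`likely_complete` if it is at least 30 kb, or at least 20 kb with four of
the five modules and a boundary integrase; `partial` otherwise. The
remnant rule takes precedence over the 30 kb rule: a long region with no
structural or packaging genes cannot make virions, a situation actually
observed when size-only heuristics call such regions complete. The
partial class makes both of the field's dichotomies (complete vs not,
remnant vs not) expressible. Classification is monotone in the module
set: adding a module never demotes a region.

Regions are named `<abbrev><strain>ph<ordinal>` (Bad/Bif/Bre/Blong),
ordinals by genomic position, e.g. `BifBIOML-A4ph1`.

## Fragment ANI and clustering

Average nucleotide identity uses the ANIb convention: the query is cut
into 1020 bp fragments, each locally aligned (match +2, mismatch −3, gap
open 5, extend 2) against the subject on both strands; fragments are
accepted at ≥ 30% identity over ≥ 70% of their length; ANI is the mean
identity over accepted fragments, and coverage the accepted query length
fraction. Entries are symmetrised by the arithmetic mean of the two
directions. Clustering is single linkage at ANI ≥ 0.9: connected
components of the threshold graph. Single linkage matches the
contiguity-based reading of a clustered heatmap; coverage is reported but
deliberately not used in clustering.

Numerically, each fragment is anchored by exact 11-mers: the subject
window around the modal seed diagonal (±200) is aligned, and a band
supported by fewer than 4 seeds is rejected without alignment. This is a
banded-alignment heuristic: any fragment that can pass the 30%/70%
acceptance retains dozens of exact 11-mers, whereas chance seeds between
unrelated sequences almost never co-occur on one band. Subjects of at
most 5 kb are aligned directly, so on short pairs fragment ANI equals the
direct local-alignment identity to machine precision (tested at 1e−9).

## Protein families and cluster selection

ORFs are predicted with a conventional six-frame scan (starts ATG/GTG/TTG,
stops TAA/TAG/TGA, table 11, minimum 30 aa, longest ORF per stop; codons
containing N never match start/stop and translate to X; proteins over 10%
X are discarded). The scanner is deliberately exhaustive and is verified
against a brute-force oracle. For protein comparison the pipeline then
applies a greedy non-overlapping selection (longest first, ≤ 30 bp
overlap): six-frame scanning of stop-poor high-GC DNA reports roughly 16
ORFs/kb, most of them shadows of real genes on other frames, and the
selection plays the role of a gene caller without re-implementing one.

All-vs-all protein similarity uses BLOSUM62 local alignment (gap open 11,
extend 1). Raw scores become bit scores via ungapped Karlin–Altschul
parameters (λ = 0.267, K = 0.041) and E = m·n·2^(−S′) with m the query
length and n the summed protein length of the dataset; edges require
E ≤ 1e−5 and are weighted −log10 E (capped at 200). Pairs sharing no
exact amino-acid 5-mer are skipped by default — an alignment passing the
cut-off carries identity runs that essentially always contain one — and
alignments are batched per subject; `prefilter = FALSE` restores the
exhaustive scan.

**MCL** is implemented from scratch: the weighted adjacency matrix plus
self-loops is column-normalised, then expansion (matrix self-product)
alternates with inflation (entrywise power 2.0, column renormalisation),
pruning entries below 1e−6, until the maximum entry change falls below
1e−9 (cap 200 iterations; non-convergence is a warning, never silent).
Self-loops take each node's maximum incident edge weight (1 when
isolated): with unit loops and −log10 E weights in the hundreds, a pair
of identical proteins forms a near-permutation matrix whose expansion
limit is the identity, and the walk's period-2 oscillation would split
verbatim gene copies into singleton families; column-max loops are the
usual damping and reduce to unit loops on unit-weight graphs. Clusters are the connected components of the
limit's non-zero structure; the 3-node-path limit is verified doubly
idempotent against a hand-run iteration. Inflation 2.0 and the −log10 E
weight transform are the conventional defaults of the mclblastline tool
chain; both are exposed.

The **presence/absence matrix** is binary — rows are prophages, columns
gene families, an entry is 1 iff the prophage contributes at least one
ORF. The binary yes/no reading (family present or absent, rather than a
literal 100% inter-member identity requirement) is the interpretation
that keeps Markov clustering meaningful. An ANI cluster becomes a
**selected cluster** iff it has ≥ 2 members, mean pairwise row-Jaccard
≥ 0.5, at least one `likely_complete` member, and no member under 13 kb;
`shared_integration` is flagged when two members have identical flanking
products on both sides (2 kb window, either orientation). The Jaccard
threshold quantifies an otherwise qualitative "degree of gene sharing"
and is a config parameter.

## CRISPR arrays and protospacers

Array detection chains exact 23-mer seed occurrences whose periods are
compatible with a repeat–spacer structure (repeat 23–55 bp, spacer 25–60
bp), extends the repeat maximally while all copies remain identical, and
requires ≥ 3 copies; a truncated terminal copy of at least half the
repeat length counts as a copy. Overlapping candidates resolve by copy
count, then repeat length, then position. Exact-copy matching is the
simplest testable rule (the detector is verified against brute-force
enumeration of repeat triples); real tools tolerate repeat degeneracy,
and a mismatch allowance is deliberately deferred. Arrays are reported on
the forward strand — leader-side orientation calling is out of scope.

Spacer dedup is greedy incremental clustering at 90% ungapped identity
over the shorter sequence, both strands, longest-first with
lexicographic ties — deterministic and idempotent.

Protospacer matching seeds with exact 11-mers on both strands, aligns
each candidate locus with the affine-gap nucleotide scores above, and
computes E-values with λ = 0.625, K = 0.41, m the spacer length and n the
summed region length. Hits require E ≤ 0.01 **and** identity ≥ 98%
(identical columns over all alignment columns, gaps included) — so a
single substitution in a 33 bp spacer (32/33 ≈ 97.0%) is rejected, which
the tests force explicitly. "Unique sequences" are operationalised as
subject intervals merged at ≥ 1 bp overlap; targeted genes are the ORFs
with maximal hit overlap (ties leftmost), aggregated with supporting-hit
and distinct-spacer counts.

## Intergenomic distances and trees

HSPs between two regions come from the package's seed-and-extend
ungapped aligner (per-diagonal maximal scoring segments, match +2,
mismatch −3), filtered at E ≤ 1e−3 and made non-overlapping greedily
(highest score first, both sequences). With lengths L1, L2, total HSP
length H and identities I:

* d0 = 1 − 2H/(L1+L2) — coverage,
* d4 = 1 − I/H (1 when H = 0) — identity within matches,
* d6 = 1 − 2I/(L1+L2) — combined,

all clamped to [0, 1]. Arguments are canonicalised internally so each
distance is exactly symmetric. Trees are built by neighbor joining with
negative branch lengths clamped to zero, then midpoint-rooted. NJ
replaces balanced minimum evolution with SPR postprocessing: NJ is
exactly testable (it provably recovers additive matrices, which the
suite exercises on random 4–8-taxon trees) and adequate at this scale.
Pseudo-bootstrap support is omitted: no site-resampling scheme is defined
for whole-sequence distances, and inventing one would fake support
values. Taxon grouping uses link-fraction clustering: clusters fuse iff
at least a fraction F (default 0.5) of cross-pairs lie within the
distance threshold t, smallest mean cross-distance first; F = 1 is
complete linkage.

## The synthetic-data generator

Because the real inputs are hundreds of RefSeq assemblies and a web
detection service, validation runs on simulated genomes with known
truth. The generator emulates: host chromosomes at the species' GC
(59–62%, defaults per species), 0–6 implanted prophages per genome drawn
from a shared pool of phage templates, degraded remnants, tRNA genes
adjacent to integration sites (≤ 500 bp, 70% of implants), and one
CRISPR array per phage-carrying genome whose spacers are sampled from the
genome's own implants (either strand) and mutated per base at a
configurable rate (default 0 — the mutation-free condition under which
exact recovery is asserted).

Phage templates fix the canonical module order (integration/excision
first, so the integrase sits at the boundary; head/tail and packaging
adjacent), gene counts, and a log-normal gene length distribution
(mean ≈ 900 bp, clamped 150–2400 bp). Genes are clean ORFs (ATG … stop,
no internal in-frame stops) sampled base-wise at the phage GC; gaps are
uniform 2–200 bp; strands alternate across module boundaries only, so
intact implants satisfy the same-strand/\<1 kb co-transcription rule
internally. Intact implants target 22–47 kb — the upper part of the
4.5–51.2 kb size range, so that a structurally complete phage is also
classifiable as such — and remnants are the same phages with the
head/tail and DNA-packaging modules deleted (≈ 45% of genes), landing at
8–26 kb. Host background genes never carry phage-lexicon products, so
every false-positive candidate is measurable, and integration sites keep
a 1.2 kb feature-free margin so the co-transcription criterion cannot
chain from an implant into host operons; the residual boundary error is
the absorbed flanking tRNA (≤ ~450 bp), within the ±500 bp recovery
tolerance asserted in the tests.

What the generator does **not** model, and what passing tests therefore
do not show: real bifidophage sequence composition beyond GC and module
structure (host genes are annotation-only, not real ORFs), repeat
degeneracy in CRISPR arrays, Cas operons, partially deleted genes,
mosaicism within a template pool, assembly gaps and ambiguity codes, and
integration-site duplication (attL/attR). Recovery at precision/recall
1.0 on this simulator demonstrates the pipeline's internal consistency,
not field performance on RefSeq data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive end to end — the native convention of
  GFF3, GenBank and IRanges — so emitted files need no conversion and the
  coordinate bijection is the identity.
* Ambiguity codes other than N are rejected at parse time; N is excluded
  from GC, never matches start/stop codons or alignment seeds, and
  translates to X.
* Empty inputs: an empty region list yields a header-only GFF3; an empty
  genome set runs the whole pipeline to a valid manifest; precision on an
  empty prediction set is 1 by convention.
* Ties: ANI clusters order by size then smallest member; MCL is
  permutation-invariant; greedy HSP selection breaks score ties by
  coordinates; targeted-gene ties go to the leftmost ORF; array overlaps
  resolve by copies, repeat length, then position.
* Determinism: all stochastic steps flow through R's RNG seeded from the
  mandatory config seed; two runs of the pipeline under one seed produce
  byte-identical artefact bundles (checked via md5 in the tests; the run
  log with wall times is excluded from the manifest for this reason).

## Problem sizes

The test suite and the acceptance script run entirely on simulated data
sized for a single CPU: 20 genomes of 100 kb for the recovery study,
2–6 genomes for end-to-end pipeline runs, ≤ 10 kb sequences for
brute-force oracle comparisons, and 4–8 taxa for tree recovery. These
sizes are the package's validation choices; all stages accept larger
inputs unchanged.

## Worked example

```{r example}
library(bifidophage)

cfg <- pipeline_config(
  generator = generator_config(n_genomes = 6, seed = 11),
  outdir = "bifidophage_out")
res <- run_pipeline(cfg)
res$metrics
```

See the README for the numbers this prints and how to reproduce the
acceptance quantities with `scripts/acceptance.R`.
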