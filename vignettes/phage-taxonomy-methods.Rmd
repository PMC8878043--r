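---
title: "Genome-based phage taxonomy with phagetax: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based phage taxonomy with phagetax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacteriophage taxonomy below the family level is built on two genomic
signals. Closely related phages (species and genus rank) are separated by
*intergenomic nucleotide similarity*: the length-normalised percentage of
identical bases aggregated over reciprocal local alignments, with the
conventional demarcation thresholds of ≥95% for species and ≥65% for a
genus. More distant, subfamily-level relationships leave too little
nucleotide signal, so they are resolved from *shared protein content*:
proteins are grouped into orthologous families ("phams"), and genomes that
share at least 30% of their proteins are placed in the same cluster
(subfamily). `phagetax` implements this two-tier scheme end to end,
together with core/accessory/unique pangenome accounting per cluster and
gene presence/absence distance matrices for splits-network visualisation.

## Intergenomic nucleotide similarity

For genomes $a$ and $b$ with lengths $L_a$, $L_b$, both directions are
aligned ($a$ as query against $b$, then $b$ against $a$), high-scoring
pairs (HSPs) are merged on each query's own axis so no base is counted
twice, and

$$\mathrm{sim}(a,b) \;=\; 100 \times \frac{\mathrm{id}_{ab} + \mathrm{id}_{ba}}{L_a + L_b},$$

where $\mathrm{id}_{ab}$ is the merged identity count with $a$ as query.
Self-similarity is exactly 100 by construction, and the value is symmetric
because both directions enter every evaluation.

The aligner is a seed-and-extend local aligner in compiled code with the
blastn-style scoring used for phage similarity screens: exact 7-mer seeds,
match +2, mismatch −3, gap open 5, gap extend 2 (a gap of length $k$ costs
$5 + 2k$). Seeds are extended ungapped under an X-drop rule first; seeds
reaching a trigger score (default 40) are re-extended with a banded
affine-gap X-drop dynamic program with full traceback, so identity counts
are exact rather than estimated. HSPs scoring below 50 (the score of a 25
bp exact match) are discarded as noise. Both subject strands are searched,
which makes every reported statistic orientation-invariant: genome
re-orientation, which some published workflows apply before comparison, is
deliberately not performed. `N` characters never count as identities. An
optional `blastn` backend wraps the external binary behind the same HSP
contract and agrees with the internal aligner within ±2 similarity points
on synthetic populations; tests also verify the internal aligner against
an exhaustive dynamic-programming reference (optimal local alignment via
`Biostrings`) on sequences up to 200 bp, with merged identity counts
matching within ±2.

Overlapping HSPs are merged by a deterministic trimming rule: HSPs are
taken in decreasing score order (ties: smaller start coordinate, then
input order) and kept intact; later HSPs have their overlapping span
trimmed, with identities reduced proportionally to the trimmed length and
rounded down. The merged identity total can therefore never exceed the
merged aligned length.

## Protein grouping and shared content

All translated CDSs are compared pairwise by optimal local alignment
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1, in compiled code; the
`Biostrings` implementation of the same alignment serves as an independent
reference in the test suite). A pair is linked when

* identity — identical residues over alignment columns — is ≥ 0.35, and
* coverage — aligned span over sequence length, evaluated on **both**
  sequences and taken as the minimum — is ≥ 0.50.

Published workflows quote a 30–40% identity range; 35% is the default here
and both thresholds are exposed as arguments. Measuring coverage on both
sequences (not only on the HSP) is the stricter reading of "≥50% coverage"
and prevents domain-level chaining of multidomain proteins; it also
licenses a provably safe pre-filter that skips pairs whose lengths differ
by more than 4× (such pairs cannot reach 50% coverage of the longer
sequence), which the test suite verifies against brute-force all-pairs
grouping. Groups are the connected components of the match graph (single
linkage) — simpler than the iterative refinement some pangenome tools
apply, but deterministic and dependency-free; the downstream shared-content
percentages are robust to this simplification. A group with one member is
an orpham.

Shared protein content between genomes $a$ and $b$ is pooled over both
proteomes: with $s_a$ = number of $a$'s proteins whose group also contains
a protein of $b$ (and vice versa), and $n_a$, $n_b$ the proteome sizes,

$$\mathrm{shared}(a,b) = 100 \times \frac{s_a + s_b}{n_a + n_b}.$$

Published heatmaps of this quantity are symmetric but do not state their
normalisation; the pooled form is this package's fixed convention (min- or
max-normalised variants would differ only for very unequal proteome
sizes).

## Two-tier classification

*Sub-clusters (genera)* are connected components of the graph joining
genome pairs with nucleotide similarity ≥ 65 (single linkage — the
behaviour of threshold-based demarcation), and *species* are components at
≥ 95 within each sub-cluster, so species always nest inside genera.
*Clusters (subfamilies)* come from complete-linkage hierarchical
clustering of `100 − shared%`, cut at distance 70 (= 30% shared). Because
two different linkage rules are in play, a dendrogram cut can in principle
split a nucleotide-defined sub-cluster; in that case the offending
clusters are merged so sub-clusters stay atomic, and a warning is logged.
A genome alone in both its sub-cluster and its cluster is a *singleton* —
a single-species genus with no subfamily relationship.

Labels are deterministic: clusters are lettered by size (descending, ties
by smallest member genome id), sub-clusters numbered the same way within
each cluster, giving the conventional "A1" style labels. Reports written
twice from the same input are byte-identical.

For each cluster, protein groups restricted to the cluster are partitioned
as **core** (members in every cluster genome), **accessory** (in ≥2 but
not all), with remaining single-genome occurrences counted per protein as
**unique**; every in-cluster group lands in exactly one class.
`n_core_exclusive` additionally counts core groups absent from all other
clusters (signature genes). Single-genome clusters report `N/A` core and
accessory counts, following the conventional report shape. Genomes flagged
as partial assemblies stay in their cluster but are excluded from the
all-members requirement for core groups.

## Gene-content distances and exports

The binary genome × protein-group presence/absence matrix yields the
content distance

$$d(a,b) = \frac{|\,\text{groups in exactly one of } a,b\,|}{|\,\text{groups in at least one of } a,b\,|},$$

a Jaccard distance. The figure legends this mirrors ("gene differences per
gene site") are ambiguous between this union normalisation and dividing by
the total number of groups; the union form is the default because
families absent from both genomes carry no signal for that pair, and the
total-denominator variant is available by argument. The matrix is written
as a NEXUS `DISTANCES` block (lower-triangular, labels quoted when
needed) loadable by splits-network software, with a companion reader used
for round-trip verification.

## The synthetic population generator

Because the reference datasets are external sequence records, every stage
is validated against simulated populations with *planted* taxonomy. The
generator (`simulate_population()`) draws a pool of ancestral gene
families as random codon sequences (start codon, sense codons, stop), then
builds a hierarchy: each cluster takes a family subset — a core fraction
shared by all cluster members (`intra_cluster_shared_gene_frac`, default
0.5 of the 20 genes per genome), with a controlled fraction drawn from a
pool common to all clusters (`inter_cluster_shared_gene_frac`, default
0.1); of the non-core genes, 80% are genus-level accessory families and
20% genome-private (the fixed rule that exercises core/accessory/unique
logic). Genera diverge from their cluster ancestor at
`inter_genus_divergence` substitutions per site (default 0.12) and genomes
from their genus ancestor at `intra_genus_divergence` (default 0.02), so
the expected identity of aligned orthologs within a genus is the product
of the branch factors, $(1-d)^2$. Substitutions are uniform point changes
that reject in-frame stop creation (start/stop codons held fixed), keeping
the translated proteome valid; intergenic spacers (20–200 bp) belong to
the genus layout — gene order, strands and spacer ancestors are drawn once
per genus — and diverge at the same rate, so the zero-divergence limit
yields byte-identical genomes and exactly 100% similarity. Singletons draw
entirely private families.

Everything is deterministic given `rng_seed`. The default configuration
(3 clusters × 2 genera × 3 genomes + 2 singletons, 20 genes of ~900 nt,
seed 42) places the planted structure far from every threshold:
within-genus similarity ≈ 87%, between-genera ≈ 34% (thresholds 95/65),
within-cluster shared content ≈ 50%, between-cluster ≈ 10% (threshold 30).
These sizes keep a full pipeline run on a single CPU to a few minutes
while leaving every stage non-trivial.

What the simulation does *not* emulate — and hence what passing tests do
not certify about real data: recombination and horizontal transfer,
terminal repeats and genome re-opening, codon-usage and GC biases,
insertion/deletion divergence between orthologs (the aligner handles gaps,
but the generator introduces none), paralogy, and annotation noise from
real gene callers. The regression hooks against named public records
exist for exactly that reason and run whenever those records are staged
locally.

## Numerical choices and edge cases

* HSP score floor 50 and gapped-extension trigger 40, X-drop 30
  (ungapped) / 100 (gapped): conventional screening values for these
  scoring parameters; the floor suppresses spurious short matches between
  unrelated genomes (verified empirically: ≤5 of 100 random 200-mer pairs
  produce any HSP).
* Identity proportional trimming in HSP merging rounds down, so merged
  identities never exceed the aligned length.
* GC% excludes `N` from the denominator; ambiguity codes other than `N`
  are normalised to `N` with a warning; `U` becomes `T`.
* The ORF caller (for unannotated/synthetic genomes only) scans six
  frames, uses bacterial start codons ATG/GTG/TTG and translation table
  11, writes the initial residue as M, keeps only the longest ORF per
  in-frame stop, and requires ≥120 nt including the stop. Candidates
  overlapping a longer kept ORF by more than half the shorter one's length
  are discarded (the usual heuristic against spurious nested antisense
  calls; the tie-break keys are reverse-complement invariant so the caller
  stays strand-symmetric, and `max_overlap = 1` disables the filter). It
  makes no claim to the calling quality of a production annotator (no RBS
  model, no tRNA detection).
* Tie-breaks everywhere (group ids, cluster letters, sub-cluster numbers,
  HSP ordering) are lexicographic/deterministic so repeated runs are
  byte-identical.
* Divergence recovery uses the estimator $\hat d = 1 - \sqrt{I}$ with $I$
  the identity over aligned positions of a within-genus pair, inverting
  the two-branch expectation $I = (1-d)^2$.

## Known limitations

Single-linkage protein grouping can chain families through promiscuous
domains when identity thresholds are permissive; the both-sequence
coverage rule mitigates but does not eliminate this. The sub-cluster
atomicity repair merges clusters rather than re-cutting the dendrogram,
which is conservative (it can only lump, never split). Shared-content
percentages depend on the gene caller used for unannotated genomes, so
comparisons against published values computed from curated annotations
carry a few points of annotation-induced slack. The pipeline holds all
genomes and alignments in memory; it is designed for collections of
hundreds of phage genomes, not bacterial-scale pangenomes.
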