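---
title: "Methods: repository model and comparative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repository model and comparative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genorepo)
```

`genorepo` is a headless toolkit for comparative microbial genomics built
on a versioned plain-folder repository. This vignette documents the
methods, the assumptions behind them, and the design decisions taken where
several defensible choices existed.

## The repository model

A repository is a directory tree, not a database. Each organism (a
biological entity such as a bacterial strain) owns a folder with an
`organism.json` metadata record and a `genomes/` folder holding one
subfolder per genome *version*. Versions arise from re-sequencing,
re-assembly or re-annotation; exactly one version is designated the
*representative* in `organism.json`, and all default queries operate on
representatives only. The model's central contract is that imports are
non-destructive: a new version is a new folder, and pre-existing folders
are never modified. `validate_repo()` enforces the structural invariants
(metadata present and consistent with directory names, the
`.fna`/`.gbk`/`.gff` triplet present, identifiers unique repository-wide,
exactly one resolvable representative per organism) and reports
violations as data rather than raising errors, so a partially broken
repository can be diagnosed in one pass. Reports are sorted by path then
rule identifier, making them diffable.

Metadata schemas are deliberately minimal — a fixed required core
(organism: name, representative, taxid, tags, restricted flag; genome:
identifier, organism, provenance strings) plus an open `custom` map.
Real projects accumulate dozens of ad-hoc metadata columns; a closed
schema would either bloat or be wrong. JSON is written with sorted keys,
UTF-8 and a trailing newline so repeated writes are byte-identical and
version-control friendly.

Selector syntax is intentionally small: bare genome identifiers,
`@tag:name`, `@tax:Name` and `@taxrank:Name`, with comma-separated union.
Tag and taxon selectors resolve to representative genomes only, matching
the default scope of genome listings; bare identifiers may name any
version, since pointing at a historical assembly is the reason versions
are kept. Taxonomy comes from a four-column lineage TSV (`taxid`,
`parent`, `rank`, `name`, root being its own parent); nothing is ever
downloaded.

## Annotations and coverage

Annotation tables are two-column TSV files (gene, annotation identifier)
per genome and per annotation type; each type carries a validating
regular expression (EC numbers, KEGG genes `K#####`, KEGG reactions,
GO terms, plus a permissive custom type). Two parsing decisions matter
downstream:

* **Set semantics.** A gene listed twice with the same annotation counts
  once. Every statistic in the package counts *genes* or *genomes*, not
  file lines, so duplicated lines must not inflate anything.
* **Strictness.** Lines that are not exactly two tab-separated fields
  fail with a line number; identifiers violating the type pattern are
  collected and reported rather than silently kept or dropped.

The coverage matrix is `C[a, g] = |{genes of g carrying a}|`, rows and
columns in input order (so permuting the genome list permutes columns and
nothing else). `genes_for_annotation()` is the cell drill-down and is, by
construction and by test, always consistent with the matrix.

## Gene–trait matching

Given two disjoint genome groups differing in a binary phenotype, every
annotation present in at least one selected genome is tested for
association: the 2×2 table counts genomes (presence/absence, not gene
counts — the phenotype is a genome-level property, so the evidence unit
is the genome), the test is Fisher's exact test, and p-values are
corrected with the Benjamini–Hochberg step-up procedure at a default
FDR of 10 %.

Decisions taken where conventions diverge:

* **Sidedness.** Two-sided by probability-mass ordering — the p-value is
  the sum of probabilities of all same-margin tables no more probable
  than the observed one, the `stats::fisher.test` convention. A one-sided
  test would presuppose the direction of the association.
* **Tie handling.** With margins fixed, all candidate tables share the
  denominator `choose(n, k)`, so tables are compared through integer
  binomial-coefficient numerators. At the group sizes this tool targets
  (tens of genomes) these are exactly representable in doubles, so
  probability ties — which are common in discrete tables — are resolved
  exactly rather than by floating-point noise; a `1e-7` relative guard
  covers very large margins. The implementation is verified against
  exhaustive enumeration for every table with `n ≤ 30` (46,376 tables).
* **The testing family.** Annotations absent from every selected genome
  are excluded from `m`. They are untestable (p ≡ 1) and including them
  would dilute the correction arbitrarily, since the universe of
  never-observed annotations is unbounded.
* **Degenerate margins** (an empty row or column) yield p = 1: with such
  margins only one table is possible, so the data carry no information
  about association.

The planted-signal behaviour is worth stating precisely: with two groups
of three, the smallest achievable two-sided p is 2/C(6,3) = 0.1, reached
exactly by a perfectly separating annotation. After BH correction across
tens of annotations such a p cannot clear α = 0.1 — small screens rank
candidates; they do not certify them.

## Trees

**Taxonomy trees** prune the lineage table to the selected genomes'
lineages, collapse unary internal nodes, and hang each genome below its
organism's taxon with unit branch lengths. They reflect metadata, not
sequence divergence.

**Similarity trees** are alignment-free. Each assembly is reduced to its
hexanucleotide signature: every 6-bp window consisting only of A/C/G/T is
mapped to its canonical form — the lexicographic minimum of the word and
its reverse complement — and counts are normalised to frequencies.
Canonicalisation makes the signature independent of contig orientation,
which is arbitrary in de novo assemblies; windows containing ambiguity
codes are skipped rather than expanded (expansion would weight uncertain
positions as data). `k = 6` is the default because it is the smallest
word size whose signature resolves species-level structure in bacteria
while remaining robust on draft assemblies; `k` is a parameter.
Signatures are compared by total-variation distance,
`d(p, q) = ½ Σ |pᵢ − qᵢ|` ∈ \[0, 1\] — a proper metric on frequency
vectors with a direct reading (the largest probability mass on which the
two signatures disagree), and similarity is `1 − d`.

The dendrogram is classic UPGMA: merge the closest pair, replace it by a
cluster whose distance to the others is the size-weighted mean, place the
node at half the merge distance. Two numerical choices make the output
reproducible: ties in the minimum distance are broken by the
lexicographically smallest pair of cluster labels (a cluster is labelled
by its smallest leaf), and children of every node are ordered the same
way. The implementation is checked against a naive reference that
recomputes all cluster distances from the original matrix each round, and
every output is checked ultrametric to 1e-9.

Newick serialization uses 6 significant digits for branch lengths and
single-quotes labels containing syntax characters; the in-memory tree
(an `ape` `phylo`) always carries full-precision branch lengths —
display rounding never feeds back into computation. Parsing delegates to
`ape::read.tree`, with quote normalisation and a single-leaf stub that
standard Newick allows but `ape` does not represent.

## Pathway coverage

Pathway maps are ordinary SVG files in which coverable reaction boxes
carry a unique `id` and a `data-annotations` attribute listing the
annotation identifiers behind the reaction. The dialect is deliberately
self-contained: widely used reference maps cannot be redistributed, so
the package defines a format any SVG editor can produce instead of
depending on licensed artwork. A genome covers a box if at least one of
its genes carries at least one of the box's annotations; a genome with
five such genes still counts once, because the question is "can this
organism perform the reaction". Colors: no covering genome is white
`#FFFFFF`; from one (yellow `#FFFF00`) to all (red `#FF0000`) genomes the
fill interpolates linearly in RGB. The endpoints are fixed constants so
rendering is bit-exact; a single-genome group jumps straight to red. With
two groups each box is filled by a two-stop hard-edge linear gradient
(left half group 1, right half group 2) — gradients are shape-agnostic,
whereas geometrically splitting arbitrary SVG shapes is not. At most two
groups are supported; a half/half split does not generalise legibly.

## Flower-plot statistics

For n genomes, each annotation is classified by how many of them carry
it: in all n (*core*), in exactly one (*unique* to that genome), or in
between (*shared*). Per genome, `unique + shared + core = total` distinct
annotations — an identity the tests verify on random configurations.
Statistics are computed on distinct annotation identifiers, not gene
counts: paralogs would otherwise inflate every petal, and the annotation
type to count is a parameter rather than a baked-in choice.

## The synthetic repository generator

`generate_fixture_repo()` builds a complete valid repository from a seed:
by default 6 organisms split half/half over two tags (giving two groups
of three representatives, the smallest configuration where trait matching
is meaningful), 2 genome versions each, 4 kb assemblies with 20 genes
whose GFF3 and GenBank coordinates agree, two populated annotation types,
and a miniature two-phylum taxonomy. Every byte is a deterministic
function of the seed (fixed RNG kind, no timestamps), and the generator
restores the caller's RNG state.

The planted annotation structure is the point: five core annotations
present everywhere, one unique annotation per organism, one
trait-associated annotation present in every genome of the first tag
group and no other, and a background pool of 50 annotations assigned to
random organism subsets. Background assignments that would exactly
reproduce a tag group are toggled away, so the planted annotation is the
*only* perfect separator by construction — without this exclusion a
background annotation can tie it at the minimal p and make recovery
tests ambiguous.

What the generator does *not* emulate: real genomes share sequence by
descent, so signature distances correlate with taxonomy — fixture
assemblies are i.i.d. random DNA and their mutual distances are
uniformly large; gene density, paralogy, operon structure and annotation
error are absent; GenBank files are minimal (LOCUS/FEATURES/ORIGIN).
Green tests therefore demonstrate correctness of the computations and
contracts, not biological performance of, say, signature trees on real
assemblies.

## Verification sizes

The shipped checks run at desk scale, chosen so the full suite completes
in well under a minute of compute: exhaustive Fisher verification over
all 46,376 tables with n ≤ 30; 1,000 random p-vectors (m ≤ 50) against
the literal step-up rule; a 500-replicate null (200 annotations, two
groups of 10) for empirical FDR; 500 random distance matrices (n ≤ 12)
against the naive UPGMA reference; 1,000 random sequences for strand
independence; 1,000 random set configurations for the flower partition
identity.

## Known limitations

* Gene–trait matching applies no phylogenetic or population-structure
  correction; clonal sampling can make lineage markers look
  trait-associated. Treat hits as candidates.
* The hexanucleotide signature is a genome-wide average; it will not
  resolve very closely related strains, and plasmid-rich or heavily
  contaminated assemblies distort it.
* Taxonomy trees are only as good as the metadata taxids and the
  supplied lineage table.
* The annotation importer expects the two-column TSV contract; converting
  annotator-specific output (EggNOG, InterPro, ...) is upstream work.
* Repository scans re-read annotation tables per query; collections far
  beyond a few hundred genomes would want an index layer.
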