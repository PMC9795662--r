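# genorepo

Headless comparative genomics on a versioned genome repository.

Sequencing microbial genomes has become routine, and the bottleneck has
moved to data management: keeping dozens to hundreds of assemblies, their
re-assemblies and re-annotations, and all associated metadata in a form
that is findable, automatable and reproducible. `genorepo` implements a
plain-folder repository for genome collections — no database, no server —
together with the comparative analyses that such collections are kept for:

* **Repository model** — an `organisms/<organism>/genomes/<genome>/`
  folder layout with JSON metadata (`organism.json`, `genome.json`), one
  *representative* genome version per organism, strict validation, and a
  non-destructive importer for Prokka/PGAP-style output
  (`.fna`/`.gbk`/`.gff`). Legacy versions are kept, never overwritten.
* **Genome selectors** — query tokens resolving to genome sets:
  `G1`, `@tag:halophile`, `@tax:Firmicutes`, `@taxphylum:Firmicutes`.
* **Annotation coverage matrices** — for annotations a ∈ A and genomes
  g ∈ G, the matrix C\[a, g\] = |{genes of g annotated with a}|, with
  per-cell drill-down to the gene identifiers.
* **Gene–trait matching** — for two disjoint genome groups and every
  annotation, a 2×2 presence/absence table is tested with a two-sided
  Fisher exact test (probability-mass ordering over all tables with the
  observed margins), followed by Benjamini–Hochberg step-up correction,
  q₍ᵢ₎ = minⱼ≥ᵢ m·p₍ⱼ₎/j, at FDR α = 10 % by default.
* **Trees** — (1) taxonomy trees pruned from an NCBI-style lineage table;
  (2) alignment-free similarity trees: canonical hexanucleotide frequency
  signatures per assembly, total-variation distance
  d(p, q) = ½ Σᵢ |pᵢ − qᵢ|, and a UPGMA dendrogram with deterministic
  tie-breaking; Newick in and out.
* **Pathway coverage** — SVG pathway maps whose reaction boxes carry
  `data-annotations` attributes are recolored by the number of genomes
  covering each reaction (white → yellow → red; a 50/50 split fill for
  two groups).
* **Flower-plot statistics** — per-genome partition of annotations into
  unique / shared-but-not-universal / core (shared by all).
* **Synthetic repositories** — a seed-deterministic generator that builds
  a complete valid repository (assemblies, GenBank/GFF3 gene models,
  annotation tables with planted core/unique/trait-associated structure),
  so everything above is testable offline.

## Worked example

```r
library(genorepo)

generate_fixture_repo(fixture_spec(seed = 1), "demo")
g1 <- resolve_selector("@tag:halophile", "demo")   # ORG1-2 ORG2-2 ORG3-2
g2 <- resolve_selector("@tag:mesophile", "demo")   # ORG4-2 ORG5-2 ORG6-2

head(gene_trait_match(g1, g2, "demo", annotation_type = "KG"), 3)
#>   annotation a b c d   p q significant
#> 1     K77777 3 0 0 3 0.1 1       FALSE
#> 2     K00101 1 2 3 0 0.4 1       FALSE
#> 3     K00105 2 1 0 3 0.4 1       FALSE
```

The planted trait-associated annotation `K77777` is present in all three
genomes of the first group (`a = 3`) and none of the second (`d = 3`);
its two-sided exact p-value is 2/C(6,3) = 0.1, the smallest achievable
with groups of three, and it ranks first. After correction across the 61
testable annotations no q-value clears α = 0.1 — groups this small cannot
survive multiple testing, which is exactly what the q column shows.

```r
coverage_matrix(c("K00001", "K77777"), c(g1, g2), "demo")
#>        ORG1-2 ORG2-2 ORG3-2 ORG4-2 ORG5-2 ORG6-2
#> K00001      1      1      1      1      1      1
#> K77777      1      1      1      0      0      0

compute_flower_stats(c(g1, g2), "demo", "KG")
#> <flower_stats> 6 genomes, core = 7
#>   genome unique shared core total
#> 1 ORG1-2 1      26     7    34
#> ...

write_newick(taxid_tree(c(g1, g2), "demo"))
#> (((ORG1-2:1,ORG3-2:1)Bacillus:1,(ORG2-2:1)Lactobacillus:1)Firmicutes:1,
#>  (ORG4-2:1,ORG5-2:1,ORG6-2:1)Bifidobacterium:1)Bacteria;
```

`K00001` is a core annotation (one gene in every genome); the flower
statistics count seven annotations shared by all six genomes, and for
every genome `unique + shared + core = total`. The taxonomy tree groups
the two Firmicutes genera against the Bifidobacterium clade.

A command-line interface wraps the same operations:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "genorepo", package = "genorepo"))')" \
    trait-match --root demo --group1 '@tag:halophile' --group2 '@tag:mesophile' --type KG
```

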