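#' Specification for a synthetic genome repository
#'
#' Describes the deterministic synthetic repository produced by
#' [generate_fixture_repo()]: a small collection of organisms with tagged
#' metadata, taxonomic lineages, one or two genome versions each, random
#' assemblies with consistent GenBank/GFF3 gene coordinates, and annotation
#' tables with a planted sharing structure. The emulated scale — a handful
#' of organisms, kilobase assemblies, a few annotation types — mirrors a
#' small in-house comparative-genomics project and keeps every downstream
#' analysis runnable in seconds without downloads.
#'
#' The planted annotation structure is what makes the repository useful as
#' a test bed:
#'
#' * five *core* KEGG-gene annotations (`K00001`–`K00005`) present in every
#'   genome;
#' * one *unique* annotation per organism (`K9xxxx`);
#' * when `plant_trait` is `TRUE`, one annotation (`trait_annotation`)
#'   carried by every genome of the organisms tagged `tags[1]` and by none
#'   of the others — a perfectly trait-separating gene;
#' * remaining genes draw from a shared pool (`K00100`–`K00149`), so
#'   annotation content varies between genomes.
#'
#' @param n_organisms Number of organisms (default 6, split half/half over
#'   the two tags, giving two groups of three representatives for
#'   trait-matching examples).
#' @param versions_per_organism Genome versions per organism (default 2;
#'   the latest version is the representative).
#' @param genome_length Assembly length in bp (default 4000).
#' @param n_genes Genes per genome (default 20).
#' @param n_annotation_types How many of the default annotation types to
#'   populate, in the order KG, EC, GO, KR (default 2).
#' @param tags Two tag names partitioning the organisms (default
#'   `c("halophile", "mesophile")`).
#' @param plant_trait Plant a perfectly tag-separating annotation
#'   (default `TRUE`).
#' @param trait_annotation Identifier of the planted annotation.
#' @param seed Integer seed; fully determines every generated byte.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_organisms = 6L, versions_per_organism = 2L,
                         genome_length = 4000L, n_genes = 20L,
                         n_annotation_types = 2L,
                         tags = c("halophile", "mesophile"),
                         plant_trait = TRUE, trait_annotation = "K77777",
                         seed = 1L) {
  stopifnot(n_organisms >= 2L, versions_per_organism >= 1L,
            genome_length >= 600L, n_genes >= 8L,
            n_annotation_types >= 1L, n_annotation_types <= 4L,
            length(tags) == 2L)
  structure(list(n_organisms = as.integer(n_organisms),
                 versions_per_organism = as.integer(versions_per_organism),
                 genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 n_annotation_types = as.integer(n_annotation_types),
                 tags = as.character(tags),
                 plant_trait = isTRUE(plant_trait),
                 trait_annotation = trait_annotation,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Built-in miniature taxonomy: two bacterial phyla with one or two genera
# each, enough to exercise rank-restricted selectors and taxonomy trees.
#' @keywords internal
#' @noRd
fixture_taxonomy <- function() {
  data.frame(
    taxid  = c(1L, 2L, 1239L, 201174L, 1578L, 1386L, 1678L),
    parent = c(1L, 1L, 2L, 2L, 1239L, 1239L, 201174L),
    rank   = c("no rank", "superkingdom", "phylum", "phylum", "genus",
               "genus", "genus"),
    name   = c("root", "Bacteria", "Firmicutes", "Actinobacteria",
               "Lactobacillus", "Bacillus", "Bifidobacterium"),
    stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic gene layout: genes tile the sequence with a fixed margin;
# coordinates are 1-based inclusive as in GFF3.
#' @keywords internal
#' @noRd
fixture_gene_layout <- function(identifier, genome_length, n_genes) {
  slot <- genome_length %/% n_genes
  glen <- max(30L, slot - 20L)
  start <- (seq_len(n_genes) - 1L) * slot + 10L
  data.frame(gene = sprintf("%s_%04d", identifier, seq_len(n_genes)),
             start = start, end = start + glen - 1L,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
write_fixture_gff <- function(path, identifier, contig, genome_length,
                              layout) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", contig, genome_length),
             sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
                     contig, layout$start, layout$end, layout$strand,
                     layout$gene, layout$gene))
  writeLines(lines, path)
}

# Minimal but structurally conventional GenBank flat file: LOCUS header,
# FEATURES with source and gene records, ORIGIN with 60 bases per line in
# groups of 10.
#' @keywords internal
#' @noRd
write_fixture_genbank <- function(path, identifier, contig, organism, seq,
                                  layout) {
  n <- nchar(seq)
  hdr <- c(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT",
                   contig, n),
           sprintf("DEFINITION  Synthetic genome %s of %s.", identifier,
                   organism),
           sprintf("ACCESSION   %s", contig),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n),
           sprintf("                     /organism=\"%s\"", organism))
  feat <- unlist(lapply(seq_len(nrow(layout)), function(i) {
    loc <- sprintf("%d..%d", layout$start[i], layout$end[i])
    if (layout$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    c(sprintf("     gene            %s", loc),
      sprintf("                     /locus_tag=\"%s\"", layout$gene[i]))
  }))
  lower <- tolower(seq)
  starts <- seq(1L, n, by = 60L)
  origin <- vapply(starts, function(s) {
    chunk <- substr(lower, s, min(s + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, "")
  writeLines(c(hdr, feat, "ORIGIN", origin, "//"), path)
}

# Organism-level assignment of the shared KEGG-gene pool: each pool
# annotation goes to a random subset of organisms, but never to a subset
# that exactly reproduces one tag group — the planted trait annotation must
# stay the only perfectly separating one, by construction rather than by
# chance.
#' @keywords internal
#' @noRd
fixture_pool_assignment <- function(n_organisms, n_group1) {
  pool <- sprintf("K%05d", 100:149)
  group1 <- seq_len(n_group1)
  group2 <- setdiff(seq_len(n_organisms), group1)
  assign <- lapply(pool, function(a) {
    members <- which(stats::runif(n_organisms) < 0.5)
    while (setequal(members, group1) || setequal(members, group2)) {
      flip <- sample.int(n_organisms, 1L)
      members <- if (flip %in% members) setdiff(members, flip) else
        sort(c(members, flip))
    }
    members
  })
  names(assign) <- pool
  assign
}

# Assign annotations of one type to the genes of one genome. Returns an
# annotation_table ready for write_annotation_table().
#' @keywords internal
#' @noRd
fixture_annotations <- function(spec, type_key, identifier, org_index,
                                has_trait, layout, pool_annos = character()) {
  genes <- layout$gene
  entries <- list()
  add <- function(gene, anno) {
    entries[[gene]] <<- sort(unique(c(entries[[gene]], anno)))
  }
  if (type_key == "KG") {
    core <- sprintf("K%05d", 1:5)
    for (i in 1:5) add(genes[i], core[i])
    add(genes[6L], sprintf("K9%04d", org_index))
    if (has_trait) add(genes[7L], spec$trait_annotation)
    for (a in pool_annos) {
      add(genes[sample(8:length(genes), 1L)], a)
    }
  } else if (type_key == "EC") {
    add(genes[1L], "EC:1.1.1.1")
    pool <- sprintf("EC:2.7.1.%d", 1:30)
    for (i in seq(2L, length(genes), by = 2L)) {
      add(genes[i], sample(pool, 1L))
    }
  } else if (type_key == "GO") {
    add(genes[1L], "GO:0008150")
    pool <- sprintf("GO:%07d", 3674:3700)
    for (i in seq(3L, length(genes), by = 3L)) {
      add(genes[i], sample(pool, 1L))
    }
  } else if (type_key == "KR") {
    pool <- sprintf("R%05d", 1:20)
    for (i in seq(4L, length(genes), by = 4L)) {
      add(genes[i], sample(pool, 1L))
    }
  }
  structure(list(genome = identifier, type_key = type_key,
                 entries = entries, invalid = character()),
            class = "annotation_table")
}

#' @keywords internal
#' @noRd
fixture_pathway_svg <- function(path, spec) {
  boxes <- c(
    sprintf('<rect id="box-core" x="10" y="10" width="60" height="30" data-annotations="K00001 EC:1.1.1.1" fill="#CCCCCC"/>'),
    sprintf('<rect id="box-trait" x="90" y="10" width="60" height="30" data-annotations="%s" fill="#CCCCCC"/>',
            spec$trait_annotation),
    '<rect id="box-absent" x="170" y="10" width="60" height="30" data-annotations="K99998" fill="#CCCCCC"/>',
    '<text x="10" y="60">synthetic demo pathway</text>')
  writeLines(c('<svg xmlns="http://www.w3.org/2000/svg" width="240" height="80">',
               boxes, "</svg>"), path)
}

#' Generate a deterministic synthetic repository
#'
#' Builds a complete, valid repository from a [fixture_spec()]: folder
#' structure, `config.json`, taxonomy table, organism and genome metadata,
#' assemblies (FASTA) with consistent GenBank and GFF3 gene models,
#' annotation tables with the planted sharing structure, annotation
#' descriptions and one demo pathway map. Every byte is a deterministic
#' function of `spec$seed`: running the generator twice with the same spec
#' produces byte-identical trees.
#'
#' @param spec A [fixture_spec()].
#' @param root Target directory; must not exist or be empty.
#' @return The [validate_repo()] report of the generated repository
#'   (empty by construction), invisibly.
#' @export
generate_fixture_repo <- function(spec = fixture_spec(), root) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  type_keys <- c("KG", "EC", "GO", "KR")[seq_len(spec$n_annotation_types)]
  types <- default_annotation_types()[type_keys]
  init_folder_structure(root, annotation_types = types)

  tax <- fixture_taxonomy()
  utils::write.table(tax, file.path(root, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = c(sprintf("K%05d", 1:5), spec$trait_annotation),
               desc = c("alcohol dehydrogenase-like core gene 1",
                        "core housekeeping gene 2", "core housekeeping gene 3",
                        "core housekeeping gene 4", "core housekeeping gene 5",
                        "planted trait-associated gene")),
    file.path(root, "annotation-descriptions", "KG.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  fixture_pathway_svg(file.path(root, "pathway-maps", "demo_pathway.svg"),
                      spec)

  n1 <- ceiling(spec$n_organisms / 2)
  pool_assign <- fixture_pool_assignment(spec$n_organisms, n1)
  genera <- c(1578L, 1386L, 1678L)  # Lactobacillus, Bacillus, Bifidobacterium
  for (o in seq_len(spec$n_organisms)) {
    org <- sprintf("ORG%d", o)
    in_group1 <- o <= n1
    tag <- if (in_group1) spec$tags[1L] else spec$tags[2L]
    # group-1 organisms alternate over the two Firmicutes genera,
    # group-2 organisms are Actinobacteria
    taxid <- if (in_group1) genera[1L + (o %% 2L)] else genera[3L]
    ids <- sprintf("%s-%d", org, seq_len(spec$versions_per_organism))
    write_organism_record(
      organism_record(org, representative = ids[length(ids)], taxid = taxid,
                      tags = tag), root)
    for (v in seq_len(spec$versions_per_organism)) {
      id <- ids[v]
      gdir <- genome_dir(root, org, id)
      dir.create(gdir, recursive = TRUE)
      contig <- paste0(id, "_c1")
      seq <- random_dna(spec$genome_length)
      layout <- fixture_gene_layout(id, spec$genome_length, spec$n_genes)
      dna <- Biostrings::DNAStringSet(stats::setNames(seq, contig))
      Biostrings::writeXStringSet(dna, file.path(gdir, paste0(id, ".fna")))
      write_fixture_genbank(file.path(gdir, paste0(id, ".gbk")), id, contig,
                            org, seq, layout)
      write_fixture_gff(file.path(gdir, paste0(id, ".gff")), id, contig,
                        spec$genome_length, layout)
      org_pool <- names(pool_assign)[vapply(pool_assign, function(m) {
        o %in% m
      }, FALSE)]
      for (key in type_keys) {
        tab <- fixture_annotations(spec, key, id, o,
                                   has_trait = spec$plant_trait && in_group1,
                                   layout = layout, pool_annos = org_pool)
        write_annotation_table(tab, file.path(gdir,
                                              paste0(id, ".", key, ".tsv")))
      }
      write_genome_record(
        genome_record(id, org, sequencing_tech = "synthetic",
                      assembly_tool = "fixture-generator",
                      annotation_tool = "fixture-generator",
                      custom = list(version = v)), root)
    }
  }
  invisible(validate_repo(root))
}
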