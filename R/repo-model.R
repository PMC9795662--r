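#' Versioned genome repository layout
#'
#' A repository is a plain folder structure designed for FAIR, versioned
#' storage of genome collections:
#'
#' ```
#' <root>/
#'   config.json                  # declared annotation types, taxonomy path
#'   organisms/
#'     <organism>/
#'       organism.json            # name, representative, taxid, tags, ...
#'       genomes/
#'         <genome-id>/
#'           genome.json
#'           <genome-id>.fna     # assembly FASTA
#'           <genome-id>.gbk     # GenBank
#'           <genome-id>.gff     # GFF3
#'           <genome-id>.<type>.tsv  # gene -> annotation tables
#'   annotation-descriptions/     # <type>.tsv: annotation -> description
#'   pathway-maps/                # SVG pathway maps
#' ```
#'
#' Each organism owns one or more genome versions; exactly one of them is
#' designated the *representative* genome in `organism.json`. Updating an
#' assembly means importing a new version and re-pointing the representative;
#' legacy versions are kept, never overwritten.
#'
#' @name repo-model
NULL

#' Create an organism metadata record
#'
#' @param name Unique organism identifier (also the directory name).
#' @param representative Genome identifier of the representative version.
#' @param taxid Integer NCBI taxonomy identifier.
#' @param tags Character vector of tag names (no whitespace).
#' @param restricted Logical; access flag carried as metadata.
#' @return Object of class `organism_record`.
#' @export
organism_record <- function(name, representative, taxid = NA_integer_,
                            tags = character(), restricted = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(representative), length(representative) == 1L)
  tags <- as.character(tags)
  if (any(!nzchar(tags) | grepl("\\s", tags))) {
    stop("tags must be non-empty strings without whitespace", call. = FALSE)
  }
  structure(list(name = name, representative = representative,
                 taxid = as.integer(taxid), tags = tags,
                 restricted = isTRUE(restricted)),
            class = "organism_record")
}

#' Create a genome metadata record
#'
#' @param identifier Unique genome identifier (also the directory name).
#' @param organism Owning organism name.
#' @param sequencing_tech,assembly_tool,annotation_tool Free-text provenance.
#' @param custom Named list of additional open metadata.
#' @return Object of class `genome_record`.
#' @export
genome_record <- function(identifier, organism, sequencing_tech = "",
                          assembly_tool = "", annotation_tool = "",
                          custom = list()) {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            nzchar(identifier),
            is.character(organism), length(organism) == 1L)
  structure(list(identifier = identifier, organism = organism,
                 sequencing_tech = sequencing_tech,
                 assembly_tool = assembly_tool,
                 annotation_tool = annotation_tool,
                 custom = custom),
            class = "genome_record")
}

#' @keywords internal
#' @noRd
write_organism_record <- function(rec, root) {
  dir <- file.path(organisms_dir(root), rec$name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_repo_json(unclass(rec), file.path(dir, "organism.json"))
}

#' @keywords internal
#' @noRd
read_organism_record <- function(root, organism) {
  path <- file.path(organisms_dir(root), organism, "organism.json")
  x <- read_repo_json(path)
  organism_record(x$name, x$representative, x$taxid %||% NA_integer_,
                  unlist(x$tags) %||% character(), x$restricted %||% FALSE)
}

#' @keywords internal
#' @noRd
write_genome_record <- function(rec, root) {
  dir <- genome_dir(root, rec$organism, rec$identifier)
  write_repo_json(unclass(rec), file.path(dir, "genome.json"))
}

#' @keywords internal
#' @noRd
read_genome_record <- function(root, organism, identifier) {
  path <- file.path(genome_dir(root, organism, identifier), "genome.json")
  x <- read_repo_json(path)
  genome_record(x$identifier, x$organism, x$sequencing_tech %||% "",
                x$assembly_tool %||% "", x$annotation_tool %||% "",
                x$custom %||% list())
}

#' Initialise a bare repository folder structure
#'
#' Creates the `organisms/`, `annotation-descriptions/` and `pathway-maps/`
#' directories plus a `config.json` declaring the annotation types. Refuses
#' to touch a non-empty directory: existing data is never overwritten.
#'
#' @param root Target directory; must not exist or be empty.
#' @param annotation_types Named list of [annotation_type()] objects to
#'   declare; defaults to [default_annotation_types()].
#' @return A [validation_report()] for the fresh repository (empty on
#'   success), invisibly.
#' @export
init_folder_structure <- function(root,
                                  annotation_types = default_annotation_types()) {
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) > 0L) {
    stop("refusing to initialise non-empty directory: ", root, call. = FALSE)
  }
  if (file.exists(root) && !dir.exists(root)) {
    stop("path exists and is not a directory: ", root, call. = FALSE)
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (d in c("organisms", "annotation-descriptions", "pathway-maps")) {
    dir.create(file.path(root, d))
  }
  cfg <- list(annotation_types = lapply(unname(annotation_types), unclass),
              taxonomy = "taxonomy.tsv")
  write_repo_json(cfg, file.path(root, "config.json"))
  invisible(validate_repo(root))
}

#' Import a genome into the repository
#'
#' Copies the assembly FASTA (`.fna`), GenBank (`.gbk`) and GFF3 (`.gff`)
#' files found in `import_dir` into
#' `organisms/<organism>/genomes/<identifier>/`, renaming them to
#' `<identifier>.<suffix>`, and writes `genome.json`. Output directories of
#' common prokaryote annotation pipelines (Prokka, PGAP) are directly
#' compatible: the importer picks files by suffix, whatever their base name.
#'
#' If the organism is new, `organism.json` is created with this genome as
#' representative. For an existing organism the representative is changed
#' only when `set_representative = TRUE`. Pre-existing genome folders are
#' never modified: importing a duplicate identifier is an error.
#'
#' @param import_dir Directory containing exactly one `.fna`, one `.gbk`
#'   (or `.gbff`) and one `.gff` (or `.gff3`) file.
#' @param root Repository root.
#' @param organism Organism name the genome belongs to.
#' @param identifier New unique genome identifier.
#' @param set_representative Make this genome the organism's representative
#'   (implied when the organism is new).
#' @param metadata Named list merged into the genome record's fields
#'   (`sequencing_tech`, `assembly_tool`, `annotation_tool`, `custom`).
#' @return The written [genome_record()], invisibly.
#' @export
import_genome <- function(import_dir, root, organism, identifier,
                          set_representative = FALSE, metadata = list()) {
  find_one <- function(exts, label) {
    hits <- list.files(import_dir,
                       pattern = paste0("\\.(", paste(exts, collapse = "|"),
                                        ")$"),
                       full.names = TRUE)
    if (length(hits) == 0L) {
      stop("import dir is missing the required ", label, " file (.",
           exts[1L], "): ", import_dir, call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop("ambiguous import: multiple ", label, " candidates: ",
           paste(basename(hits), collapse = ", "), call. = FALSE)
    }
    hits
  }
  fna <- find_one("fna", "assembly FASTA")
  gbk <- find_one(c("gbk", "gbff"), "GenBank")
  gff <- find_one(c("gff", "gff3"), "GFF3")

  existing <- list_genomes(root)
  if (identifier %in% existing$identifier) {
    stop("genome identifier already present in repository: ", identifier,
         call. = FALSE)
  }

  gdir <- genome_dir(root, organism, identifier)
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(c(fna, gbk, gff),
                  file.path(gdir, paste0(identifier, c(".fna", ".gbk", ".gff"))))
  if (!all(ok)) stop("failed to copy genome files into ", gdir, call. = FALSE)

  rec <- genome_record(identifier, organism,
                       sequencing_tech = metadata$sequencing_tech %||% "",
                       assembly_tool = metadata$assembly_tool %||% "",
                       annotation_tool = metadata$annotation_tool %||% "",
                       custom = metadata$custom %||% list())
  write_genome_record(rec, root)

  org_json <- file.path(organisms_dir(root), organism, "organism.json")
  if (!file.exists(org_json)) {
    write_organism_record(organism_record(organism, identifier), root)
  } else if (isTRUE(set_representative)) {
    org <- read_organism_record(root, organism)
    org$representative <- identifier
    write_organism_record(org, root)
  }
  invisible(rec)
}

#' Validation reports
#'
#' A validation report lists every invariant violation found in a
#' repository as `(path, rule, message)` rows, ordered deterministically by
#' path then rule. An empty report means the repository is well-formed.
#'
#' @param violations data.frame with columns `path`, `rule`, `message`.
#' @return Object of classes `validation_report` and `data.frame`.
#' @export
validation_report <- function(violations = NULL) {
  if (is.null(violations)) {
    violations <- data.frame(path = character(), rule = character(),
                             message = character(), stringsAsFactors = FALSE)
  }
  violations <- violations[order(violations$path, violations$rule), ,
                           drop = FALSE]
  rownames(violations) <- NULL
  class(violations) <- c("validation_report", "data.frame")
  violations
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation_report> OK: no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x)))
    print.data.frame(x, right = FALSE)
  }
  invisible(x)
}

#' Validate a repository against its structural invariants
#'
#' Checks every organism and genome directory: metadata files present and
#' parseable, names matching directory names, the representative genome
#' existing, the `.fna`/`.gbk`/`.gff` triplet present, genome identifiers
#' unique across the whole repository, and tags well-formed. Problems are
#' returned as report rows, never raised as errors.
#'
#' @param root Repository root.
#' @return A [validation_report()].
#' @export
validate_repo <- function(root) {
  if (!dir.exists(root)) stop("repository root does not exist: ", root,
                              call. = FALSE)
  v <- list()
  add <- function(path, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(path = path, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  for (d in c("organisms", "annotation-descriptions", "pathway-maps")) {
    if (!dir.exists(file.path(root, d))) {
      add(d, "ROOT_DIR_MISSING", paste0("required directory '", d,
                                        "' is missing"))
    }
  }
  if (!file.exists(file.path(root, "config.json"))) {
    add("config.json", "CONFIG_MISSING", "config.json is missing")
  }
  if (!dir.exists(organisms_dir(root))) return(validation_report(do.call(rbind, v)))

  orgs <- sort(list.dirs(organisms_dir(root), recursive = FALSE,
                         full.names = FALSE))
  seen_ids <- list()
  for (org in orgs) {
    opath <- file.path("organisms", org)
    ojson <- file.path(organisms_dir(root), org, "organism.json")
    rec <- NULL
    if (!file.exists(ojson)) {
      add(file.path(opath, "organism.json"), "ORG_JSON_MISSING",
          "organism.json is missing")
    } else {
      rec <- tryCatch(read_organism_record(root, org), error = function(e) {
        add(file.path(opath, "organism.json"), "ORG_JSON_INVALID",
            conditionMessage(e))
        NULL
      })
    }
    gdir <- file.path(organisms_dir(root), org, "genomes")
    ids <- if (dir.exists(gdir)) {
      sort(list.dirs(gdir, recursive = FALSE, full.names = FALSE))
    } else {
      add(file.path(opath, "genomes"), "ORG_GENOMES_MISSING",
          "genomes/ directory is missing")
      character()
    }
    if (!is.null(rec)) {
      if (!identical(rec$name, org)) {
        add(file.path(opath, "organism.json"), "ORG_NAME_MISMATCH",
            sprintf("record name '%s' does not match directory '%s'",
                    rec$name, org))
      }
      if (!rec$representative %in% ids) {
        add(file.path(opath, "organism.json"), "ORG_REPRESENTATIVE_MISSING",
            sprintf("representative genome '%s' not found under genomes/",
                    rec$representative))
      }
      bad_tags <- rec$tags[!nzchar(rec$tags) | grepl("\\s", rec$tags)]
      for (tg in bad_tags) {
        add(file.path(opath, "organism.json"), "ORG_TAG_INVALID",
            sprintf("invalid tag '%s'", tg))
      }
    }
    for (id in ids) {
      gpath <- file.path(opath, "genomes", id)
      seen_ids[[id]] <- c(seen_ids[[id]], gpath)
      gjson <- file.path(gdir, id, "genome.json")
      if (!file.exists(gjson)) {
        add(file.path(gpath, "genome.json"), "GEN_JSON_MISSING",
            "genome.json is missing")
      } else {
        grec <- tryCatch(read_genome_record(root, org, id),
                         error = function(e) {
          add(file.path(gpath, "genome.json"), "GEN_JSON_INVALID",
              conditionMessage(e))
          NULL
        })
        if (!is.null(grec)) {
          if (!identical(grec$identifier, id)) {
            add(file.path(gpath, "genome.json"), "GEN_ID_MISMATCH",
                sprintf("record identifier '%s' does not match directory '%s'",
                        grec$identifier, id))
          }
          if (!identical(grec$organism, org)) {
            add(file.path(gpath, "genome.json"), "GEN_ORGANISM_MISMATCH",
                sprintf("record organism '%s' does not match directory '%s'",
                        grec$organism, org))
          }
        }
      }
      for (suffix in c("fna", "gbk", "gff")) {
        f <- file.path(gdir, id, paste0(id, ".", suffix))
        if (!file.exists(f)) {
          add(file.path(gpath, paste0(id, ".", suffix)), "GEN_FILE_MISSING",
              sprintf("required data file %s.%s is missing", id, suffix))
        }
      }
    }
  }
  dup <- names(seen_ids)[vapply(seen_ids, length, 0L) > 1L]
  for (id in dup) {
    for (p in seen_ids[[id]]) {
      add(p, "GEN_ID_DUPLICATE",
          sprintf("genome identifier '%s' used by %d directories", id,
                  length(seen_ids[[id]])))
    }
  }
  validation_report(do.call(rbind, v))
}

#' Representative genomes of a repository
#'
#' @param root Repository root.
#' @return data.frame with columns `organism`, `genome` (the representative
#'   identifier), `taxid` and a list-column `tags`.
#' @export
representative_genomes <- function(root) {
  orgs <- sort(list.dirs(organisms_dir(root), recursive = FALSE,
                         full.names = FALSE))
  recs <- lapply(orgs, function(o) read_organism_record(root, o))
  data.frame(organism = orgs,
             genome = vapply(recs, `[[`, "", "representative"),
             taxid = vapply(recs, `[[`, NA_integer_, "taxid"),
             tags = I(lapply(recs, `[[`, "tags")),
             stringsAsFactors = FALSE)
}

#' Resolve a genome selector expression
#'
#' Selectors are the query tokens used throughout the toolkit to name sets
#' of genomes:
#'
#' * `G1` — that genome identifier (any version);
#' * `@tag:halophile` — representative genomes of organisms carrying the tag;
#' * `@tax:Firmicutes` — representative genomes whose taxonomic lineage
#'   contains the name at any rank;
#' * `@taxphylum:Firmicutes` — as above, restricted to the given rank.
#'
#' Comma-separated selectors are resolved independently and unioned. Tag and
#' taxon selectors operate on representative genomes only, mirroring the
#' default scope of genome listings.
#'
#' @param query Selector string.
#' @param root Repository root.
#' @param taxonomy Taxonomy table from [read_lineage()]; required for
#'   `@tax...` selectors. Defaults to the repository's own `taxonomy.tsv`
#'   when present.
#' @return Sorted character vector of genome identifiers.
#' @export
resolve_selector <- function(query, root, taxonomy = NULL) {
  stopifnot(is.character(query), length(query) == 1L)
  tokens <- trimws(strsplit(query, ",", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty selector", call. = FALSE)
  ids <- unlist(lapply(tokens, resolve_one_selector, root = root,
                       taxonomy = taxonomy))
  sort(unique(ids))
}

#' @keywords internal
#' @noRd
resolve_one_selector <- function(token, root, taxonomy = NULL) {
  reps <- representative_genomes(root)
  if (startsWith(token, "@tag:")) {
    tag <- substring(token, nchar("@tag:") + 1L)
    hit <- vapply(reps$tags, function(t) tag %in% t, FALSE)
    if (!any(hit)) stop("unknown tag: '", tag, "'", call. = FALSE)
    return(reps$genome[hit])
  }
  if (startsWith(token, "@tax")) {
    m <- regmatches(token, regexec("^@tax([a-z]*):(.+)$", token))[[1L]]
    if (length(m) != 3L) stop("malformed taxon selector: '", token, "'",
                              call. = FALSE)
    rank <- m[2L]
    name <- m[3L]
    if (is.null(taxonomy)) {
      taxfile <- file.path(root, "taxonomy.tsv")
      if (!file.exists(taxfile)) {
        stop("taxonomy required to resolve '", token,
             "' but none was supplied", call. = FALSE)
      }
      taxonomy <- read_lineage(taxfile)
    }
    hit <- vapply(reps$taxid, function(tid) {
      lin <- lineage_of(tid, taxonomy)
      if (nzchar(rank)) {
        any(lin$name == name & lin$rank == rank)
      } else {
        any(lin$name == name)
      }
    }, FALSE)
    if (!any(hit)) {
      stop("no genome matches taxon selector: '", token, "'", call. = FALSE)
    }
    return(reps$genome[hit])
  }
  all_ids <- list_genomes(root)$identifier
  if (!token %in% all_ids) {
    stop("unknown genome identifier: '", token, "'", call. = FALSE)
  }
  token
}
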