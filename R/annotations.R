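#' Parse a gene-to-annotation table
#'
#' Annotation tables are two-column TSV files (gene identifier, annotation
#' identifier), one pair per line; repeated rows for a gene accumulate into
#' its annotation set. A gene listed twice with the same annotation counts
#' once (set semantics): downstream statistics count genes, not lines.
#' Identifiers are whitespace-trimmed and case-sensitive.
#'
#' @param path Path to the TSV file.
#' @param type An [annotation_type()]; identifiers violating its pattern are
#'   collected in the `invalid` field rather than silently dropped.
#' @return Object of class `annotation_table`: list with `genome` (guessed
#'   from the file name), `type_key`, `entries` (named list: gene ->
#'   character vector of annotation identifiers) and `invalid`.
#' @export
parse_annotation_table <- function(path, type) {
  stopifnot(inherits(type, "annotation_type"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  genome <- sub("\\..*$", "", basename(path))
  entries <- list()
  invalid <- character()
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    bad <- which(nfield != 2L)
    if (length(bad)) {
      stop(sprintf("malformed annotation line %d in %s: expected 2 tab-separated columns, got %d",
                   bad[1L], path, nfield[bad[1L]]), call. = FALSE)
    }
    gene <- trimws(vapply(parts, `[[`, "", 1L))
    anno <- trimws(vapply(parts, `[[`, "", 2L))
    if (any(!nzchar(gene)) || any(!nzchar(anno))) {
      i <- which(!nzchar(gene) | !nzchar(anno))[1L]
      stop(sprintf("malformed annotation line %d in %s: empty field", i, path),
           call. = FALSE)
    }
    ok <- grepl(type$pattern, anno)
    invalid <- sort(unique(anno[!ok]))
    entries <- lapply(split(anno[ok], gene[ok]), function(x) sort(unique(x)))
  }
  structure(list(genome = genome, type_key = type$key, entries = entries,
                 invalid = invalid),
            class = "annotation_table")
}

#' Serialize an annotation table back to TSV
#'
#' Inverse of [parse_annotation_table()]: genes sorted, annotations sorted
#' within gene, so that parse -> serialize -> parse is the identity.
#'
#' @param table An `annotation_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  genes <- sort(names(table$entries))
  lines <- unlist(lapply(genes, function(g) {
    paste(g, sort(unique(table$entries[[g]])), sep = "\t")
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Read an annotation description map
#'
#' Description maps are two-column TSV files (annotation identifier,
#' human-readable description) stored under `annotation-descriptions/` as
#' `<type-key>.tsv`.
#'
#' @param root Repository root.
#' @param type_key Annotation type key, e.g. `"EC"`.
#' @return Named character vector mapping identifier to description; empty
#'   when no map is installed for the type.
#' @export
read_description_map <- function(root, type_key) {
  path <- file.path(root, "annotation-descriptions",
                    paste0(type_key, ".tsv"))
  if (!file.exists(path)) return(stats::setNames(character(), character()))
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

# Load every annotation table of a genome into one long data.frame
# (gene, type, annotation). `types` restricts to given type keys.
#' @keywords internal
#' @noRd
load_genome_annotations <- function(root, genome, types = NULL) {
  gens <- list_genomes(root)
  idx <- match(genome, gens$identifier)
  if (is.na(idx)) stop("unknown genome: '", genome, "'", call. = FALSE)
  gdir <- gens$path[idx]
  all_types <- repo_annotation_types(root)
  if (!is.null(types)) {
    missing <- setdiff(types, names(all_types))
    if (length(missing)) {
      stop("annotation type(s) not declared in config.json: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    all_types <- all_types[types]
  }
  out <- list()
  for (key in names(all_types)) {
    path <- file.path(gdir, paste0(genome, ".", key, ".tsv"))
    if (!file.exists(path)) next
    tab <- parse_annotation_table(path, all_types[[key]])
    if (length(tab$entries)) {
      out[[key]] <- data.frame(
        gene = rep(names(tab$entries), lengths(tab$entries)),
        type = key,
        annotation = unlist(tab$entries, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), type = character(),
                      annotation = character(), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Annotation coverage matrix
#'
#' Builds the annotation x genome coverage matrix: cell `(a, g)` is the
#' number of distinct genes of genome `g` that carry annotation `a`. Rows
#' and columns keep the order of the inputs, so the matrix is
#' permutation-equivariant in the genome list.
#'
#' @param annotations Character vector of annotation identifiers (rows).
#' @param genomes Character vector of genome identifiers (columns).
#' @param root Repository root.
#' @param types Optional character vector of type keys to restrict the
#'   lookup to.
#' @return Integer matrix with `annotations` as rownames and `genomes` as
#'   colnames.
#' @export
coverage_matrix <- function(annotations, genomes, root, types = NULL) {
  annotations <- as.character(annotations)
  genomes <- as.character(genomes)
  m <- matrix(0L, nrow = length(annotations), ncol = length(genomes),
              dimnames = list(annotations, genomes))
  for (g in genomes) {
    long <- load_genome_annotations(root, g, types)
    long <- long[long$annotation %in% annotations, , drop = FALSE]
    if (nrow(long)) {
      counts <- tapply(long$gene, long$annotation,
                       function(x) length(unique(x)))
      m[names(counts), g] <- as.integer(counts)
    }
  }
  m
}

#' Genes behind one coverage-matrix cell
#'
#' Returns the distinct genes of a genome carrying a given annotation — the
#' drill-down behind a coverage-matrix cell. Its length always equals the
#' corresponding [coverage_matrix()] value.
#'
#' @param annotation Annotation identifier.
#' @param genome Genome identifier.
#' @param root Repository root.
#' @param types Optional character vector of type keys to restrict to.
#' @return Sorted character vector of gene identifiers (possibly empty).
#' @export
genes_for_annotation <- function(annotation, genome, root, types = NULL) {
  long <- load_genome_annotations(root, genome, types)
  sort(unique(long$gene[long$annotation == annotation]))
}

#' Export a coverage matrix as TSV
#'
#' @param m Matrix from [coverage_matrix()].
#' @param path Output path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(m, path = "") {
  df <- data.frame(annotation = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
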