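#' Annotation types
#'
#' An annotation type is a namespace of functional identifiers (Enzyme
#' Commission numbers, KEGG genes, KEGG reactions, Gene Ontology terms, ...)
#' together with a validating regular expression. The set of types a
#' repository accepts is declared in its `config.json`; additional types can
#' be configured freely.
#'
#' @param key Short unique key, e.g. `"KG"`. Used in annotation file names
#'   (`<genome>.<key>.tsv`).
#' @param name Human-readable display name.
#' @param pattern Regular expression every identifier of this type must match.
#' @return An object of class `annotation_type`.
#' @examples
#' annotation_type("KG", "KEGG gene", "^K\\d{5}$")
#' @export
annotation_type <- function(key, name, pattern) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key),
            is.character(name), length(name) == 1L,
            is.character(pattern), length(pattern) == 1L)
  structure(list(key = key, name = name, pattern = pattern),
            class = "annotation_type")
}

#' Default annotation types
#'
#' The types shipped by default: EC numbers, KEGG genes, KEGG reactions,
#' Gene Ontology terms, and a permissive custom namespace.
#'
#' @return Named list of [annotation_type()] objects, keyed by type key.
#' @export
default_annotation_types <- function() {
  types <- list(
    annotation_type("EC", "Enzyme Commission number",
                    "^EC:\\d+(\\.(\\d+|-)){0,3}$"),
    annotation_type("KG", "KEGG gene", "^K\\d{5}$"),
    annotation_type("KR", "KEGG reaction", "^R\\d{5}$"),
    annotation_type("GO", "Gene Ontology term", "^GO:\\d{7}$"),
    annotation_type("CU", "Custom annotation", "^\\S+$")
  )
  stats::setNames(types, vapply(types, `[[`, "", "key"))
}

#' @export
print.annotation_type <- function(x, ...) {
  cat(sprintf("<annotation_type> %s (%s), pattern: %s\n",
              x$key, x$name, x$pattern))
  invisible(x)
}

#' Read the annotation types declared in a repository's config file
#'
#' @param root Repository root directory.
#' @return Named list of [annotation_type()] objects.
#' @export
repo_annotation_types <- function(root) {
  cfg_path <- file.path(root, "config.json")
  if (!file.exists(cfg_path)) {
    stop("no config.json found under ", root, call. = FALSE)
  }
  cfg <- read_repo_json(cfg_path)
  types <- lapply(cfg$annotation_types, function(t) {
    annotation_type(t$key, t$name, t$pattern)
  })
  stats::setNames(types, vapply(types, `[[`, "", "key"))
}
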