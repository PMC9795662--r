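# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else {
    x
  }
}

# JSON files are written with sorted keys, UTF-8 and a trailing newline so
# that repeated writes produce byte-identical, diff-friendly output.
#' @keywords internal
#' @noRd
write_repo_json <- function(x, path) {
  txt <- jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, pretty = 2,
                          null = "null", na = "null", digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_repo_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' @keywords internal
#' @noRd
organisms_dir <- function(root) file.path(root, "organisms")

#' @keywords internal
#' @noRd
genome_dir <- function(root, organism, identifier) {
  file.path(root, "organisms", organism, "genomes", identifier)
}

# Map every genome identifier in the repository to its organism directory.
# Returns a data.frame(identifier, organism, path); duplicated identifiers
# appear once per directory that houses them.
#' @keywords internal
#' @noRd
list_genomes <- function(root) {
  orgs <- list.dirs(organisms_dir(root), recursive = FALSE, full.names = FALSE)
  out <- list()
  for (org in sort(orgs)) {
    gdir <- file.path(organisms_dir(root), org, "genomes")
    if (!dir.exists(gdir)) next
    ids <- sort(list.dirs(gdir, recursive = FALSE, full.names = FALSE))
    if (length(ids)) {
      out[[org]] <- data.frame(identifier = ids, organism = org,
                               path = file.path(gdir, ids),
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(identifier = character(), organism = character(),
                      path = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
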