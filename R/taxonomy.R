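#' Read a taxonomy lineage table
#'
#' The taxonomy used for selectors and taxonomy trees is a four-column TSV
#' (`taxid`, `parent`, `rank`, `name`), one node per line. The root node is
#' its own parent (NCBI taxdump convention, taxid 1). No download is ever
#' performed; the table ships with the repository.
#'
#' @param path Path to the TSV file (with header).
#' @return data.frame with integer `taxid`/`parent` and character
#'   `rank`/`name` columns; class `taxonomy`.
#' @export
read_lineage <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "integer", "character",
                                          "character"))
  need <- c("taxid", "parent", "rank", "name")
  if (!all(need %in% names(tab))) {
    stop("lineage table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$taxid)) {
    stop("duplicate taxid in lineage table", call. = FALSE)
  }
  class(tab) <- c("taxonomy", "data.frame")
  tab
}

#' Lineage of a taxonomy node
#'
#' Walks the parent chain from `taxid` up to the root (a node that is its
#' own parent).
#'
#' @param taxid Integer taxonomy identifier.
#' @param taxonomy Table from [read_lineage()].
#' @return data.frame of lineage nodes, ordered from `taxid` to the root.
#' @export
lineage_of <- function(taxid, taxonomy) {
  idx <- match(taxid, taxonomy$taxid)
  if (is.na(idx)) stop("taxid not found in taxonomy: ", taxid, call. = FALSE)
  chain <- integer()
  cur <- idx
  repeat {
    if (taxonomy$taxid[cur] %in% taxonomy$taxid[chain]) {
      stop("cycle detected in taxonomy at taxid ", taxonomy$taxid[cur],
           call. = FALSE)
    }
    chain <- c(chain, cur)
    parent <- taxonomy$parent[cur]
    if (parent == taxonomy$taxid[cur]) break
    cur <- match(parent, taxonomy$taxid)
    if (is.na(cur)) {
      stop("broken parent link: taxid ", parent, " missing from taxonomy",
           call. = FALSE)
    }
  }
  taxonomy[chain, , drop = FALSE]
}
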