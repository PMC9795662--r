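#' Parse a pathway map SVG
#'
#' Pathway maps are ordinary SVG drawings in which coverable reaction boxes
#' carry two extra attributes: a unique `id` and `data-annotations`, a
#' whitespace-separated list of the annotation identifiers behind the
#' reaction (e.g. `data-annotations="K00031 EC:1.1.1.42"`). Shapes without
#' `data-annotations` are inert decoration. This dialect keeps maps fully
#' self-describing while avoiding redistribution of licensed map artwork;
#' any SVG editor can produce it.
#'
#' @param path Path to the SVG file.
#' @return Object of class `pathway_map`: list with `name`, `path`, `doc`
#'   (the parsed XML document) and `boxes`, a named list mapping shape id
#'   to its character vector of annotation identifiers.
#' @export
parse_pathway_svg <- function(path) {
  doc <- xml2::read_xml(path)
  shapes <- xml2::xml_find_all(doc, "//*[@data-annotations]")
  ids <- xml2::xml_attr(shapes, "id")
  if (any(is.na(ids))) {
    stop("pathway SVG dialect error: shape with data-annotations but no id",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("pathway SVG dialect error: duplicate shape id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  annos <- lapply(xml2::xml_attr(shapes, "data-annotations"), function(a) {
    ids <- strsplit(trimws(a), "\\s+")[[1L]]
    ids[nzchar(ids)]
  })
  if (any(!lengths(annos))) {
    stop("pathway SVG dialect error: empty data-annotations attribute",
         call. = FALSE)
  }
  structure(list(name = sub("\\.svg$", "", basename(path)), path = path,
                 doc = doc, boxes = stats::setNames(annos, ids)),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("<pathway_map> %s: %d annotated box(es)\n", x$name,
              length(x$boxes)))
  invisible(x)
}

#' Pathway coverage of one or two genome groups
#'
#' A genome *covers* a reaction box when at least one of its genes carries
#' at least one of the box's annotations; a genome with several such genes
#' still counts once. For each box and each group, the number of covering
#' genomes and the group size are reported, together with the display
#' color from [color_for_count()].
#'
#' @param map A [parse_pathway_svg()] map.
#' @param groups A list of 1 or 2 disjoint, non-empty character vectors of
#'   genome identifiers (a plain character vector is treated as one group).
#' @param root Repository root.
#' @return data.frame of class `pathway_coverage` with columns `box`,
#'   `group`, `count`, `size`, `color`.
#' @export
compute_coverage <- function(map, groups, root) {
  stopifnot(inherits(map, "pathway_map"))
  if (is.character(groups)) groups <- list(groups)
  if (!length(groups) || length(groups) > 2L) {
    stop("coverage supports 1 or 2 genome groups, got ", length(groups),
         call. = FALSE)
  }
  groups <- lapply(groups, function(g) unique(as.character(g)))
  if (any(!lengths(groups))) stop("empty genome group", call. = FALSE)
  if (length(groups) == 2L) {
    overlap <- intersect(groups[[1L]], groups[[2L]])
    if (length(overlap)) {
      stop("genome groups must be disjoint; shared: ",
           paste(overlap, collapse = ", "), call. = FALSE)
    }
  }
  all_genomes <- unique(unlist(groups))
  presence <- lapply(all_genomes, function(g) {
    unique(load_genome_annotations(root, g)$annotation)
  })
  names(presence) <- all_genomes
  rows <- list()
  for (gi in seq_along(groups)) {
    for (box in names(map$boxes)) {
      covering <- sum(vapply(groups[[gi]], function(g) {
        any(map$boxes[[box]] %in% presence[[g]])
      }, FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        box = box, group = gi, count = covering,
        size = length(groups[[gi]]),
        color = color_for_count(covering, length(groups[[gi]])),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("pathway_coverage", "data.frame")
  res
}

#' Coverage color scale
#'
#' Maps a covering-genome count onto the white/yellow-to-red scale used on
#' pathway maps: no covering genome is white (`#FFFFFF`); from one genome
#' (yellow, `#FFFF00`) the color interpolates linearly in RGB up to red
#' (`#FF0000`) when all genomes of the group cover the reaction. A group of
#' size one with coverage is red.
#'
#' @param count Number of covering genomes (0..`group_size`).
#' @param group_size Number of genomes in the group (>= 1).
#' @return Hex RGB color string.
#' @examples
#' color_for_count(0, 19)   # "#FFFFFF"
#' color_for_count(19, 19)  # "#FF0000"
#' @export
color_for_count <- function(count, group_size) {
  stopifnot(length(count) == 1L, length(group_size) == 1L, group_size >= 1L)
  if (count < 0 || count > group_size) {
    stop("count must lie in [0, group_size]", call. = FALSE)
  }
  if (count == 0) return("#FFFFFF")
  t <- if (group_size == 1L) 1 else (count - 1) / (group_size - 1)
  grDevices::rgb(1, 1 - t, 0)
}

#' Recolor a pathway map by coverage
#'
#' Sets each annotated shape's fill to its coverage color. With two groups,
#' each shape is filled with a hard-edged linear gradient split 50/50: the
#' left half shows group 1, the right half group 2. Inert shapes are left
#' untouched and the output remains well-formed SVG.
#'
#' @param map A [parse_pathway_svg()] map.
#' @param coverage Result of [compute_coverage()] on the same map.
#' @param path Optional output path; when given the document is written
#'   there.
#' @return The recolored `xml_document`, invisibly when `path` is given.
#' @export
render_colored_svg <- function(map, coverage, path = NULL) {
  stopifnot(inherits(map, "pathway_map"),
            inherits(coverage, "pathway_coverage"))
  if (!all(coverage$box %in% names(map$boxes))) {
    stop("coverage refers to boxes not present in this map", call. = FALSE)
  }
  doc <- xml2::read_xml(map$path)
  svg_ns <- xml2::xml_ns(doc)
  n_groups <- max(coverage$group)
  root_node <- xml2::xml_root(doc)
  defs <- NULL
  if (n_groups == 2L) {
    defs <- xml2::xml_add_child(root_node, "defs", .where = 0)
  }
  shapes <- xml2::xml_find_all(doc, "//*[@data-annotations]")
  shape_ids <- xml2::xml_attr(shapes, "id")
  for (box in unique(coverage$box)) {
    shape <- shapes[[match(box, shape_ids)]]
    cols <- coverage$color[coverage$box == box][order(
      coverage$group[coverage$box == box])]
    if (n_groups == 1L) {
      xml2::xml_set_attr(shape, "fill", cols[1L])
    } else {
      grad_id <- paste0("coverage-split-", box)
      grad <- xml2::xml_add_child(defs, "linearGradient", id = grad_id,
                                  x1 = "0", y1 = "0", x2 = "1", y2 = "0")
      xml2::xml_add_child(grad, "stop", offset = "0.5",
                          `stop-color` = cols[1L])
      xml2::xml_add_child(grad, "stop", offset = "0.5",
                          `stop-color` = cols[2L])
      xml2::xml_set_attr(shape, "fill", paste0("url(#", grad_id, ")"))
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}
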