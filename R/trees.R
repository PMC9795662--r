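#' Oligonucleotide-frequency genome signature
#'
#' Computes a genome's k-mer signature: every k-length window consisting
#' only of A/C/G/T is counted (windows containing ambiguity codes such as N
#' are skipped), each k-mer is mapped to its canonical form — the
#' lexicographic minimum of the k-mer and its reverse complement, making the
#' signature strand-independent — and counts are normalised to frequencies.
#' With the default `k = 6` this is the hexanucleotide signature used for
#' fast alignment-free genome comparison.
#'
#' @param fasta Path to an assembly FASTA file.
#' @param k Word length (default 6).
#' @return Object of class `kmer_profile`: list with `genome` (file base
#'   name), `k`, and `freq`, a named numeric vector over all `4^k` words in
#'   which all mass sits on canonical words and which sums to 1.
#' @export
kmer_profile <- function(fasta, k = 6L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) stop("no sequences in FASTA: ", fasta, call. = FALSE)
  kmer_profile_seq(seqs, k = k,
                   genome = sub("\\.(fna|fa|fasta)$", "", basename(fasta)))
}

# Signature of an in-memory DNAStringSet; kmer_profile() is the file-level
# wrapper around this.
#' @keywords internal
#' @noRd
kmer_profile_seq <- function(seqs, k = 6L, genome = "genome") {
  stopifnot(k >= 1L)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  if (is.matrix(counts)) counts <- colSums(counts)
  total <- sum(counts)
  if (total == 0) {
    stop("no valid ", k, "-mer window (only ambiguous bases?) in ", genome,
         call. = FALSE)
  }
  kmers <- names(counts)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canonical <- ifelse(kmers <= rc, kmers, rc)
  freq <- stats::setNames(numeric(length(kmers)), kmers)
  folded <- tapply(counts, canonical, sum)
  freq[names(folded)] <- folded / total
  structure(list(genome = genome, k = as.integer(k), freq = freq),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> %s: k=%d, %d canonical words with mass\n",
              x$genome, x$k, sum(x$freq > 0)))
  invisible(x)
}

#' Pairwise signature distance matrix
#'
#' Distances between k-mer profiles are total-variation distances,
#' `d(p, q) = 1/2 * sum_i |p_i - q_i|`, a proper metric on frequency
#' vectors with values in `[0, 1]`; similarity is `1 - d`.
#'
#' @param profiles List of [kmer_profile()] objects sharing the same `k`.
#' @param labels Optional labels (default: the profiles' genome names).
#' @return Symmetric numeric matrix with zero diagonal and the labels as
#'   dimnames.
#' @export
distance_matrix <- function(profiles, labels = NULL) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, FALSE, "kmer_profile")))
  ks <- vapply(profiles, `[[`, 0L, "k")
  if (length(unique(ks)) != 1L) {
    stop("profiles have incompatible k: ", paste(unique(ks), collapse = ", "),
         call. = FALSE)
  }
  labels <- labels %||% vapply(profiles, `[[`, "", "genome")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      d[i, j] <- d[j, i] <- sum(abs(profiles[[i]]$freq -
                                      profiles[[j]]$freq)) / 2
    }
  }
  d
}

# Format a branch length with 6 significant digits, trimmed.
#' @keywords internal
#' @noRd
format_brlen <- function(x) as.character(signif(x, 6))

# Quote a Newick label when it contains characters with syntactic meaning.
#' @keywords internal
#' @noRd
newick_label <- function(label) {
  if (grepl("[][\\s():;,']", label, perl = TRUE)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

# Convert a nested node list(label=, length=, children=list(...)) into an
# ape phylo object at full numeric precision (Newick serialization would
# truncate branch lengths to display digits).
#' @keywords internal
#' @noRd
nested_to_phylo <- function(root_node) {
  ntip <- 0L
  nnode <- 0L
  count <- function(nd) {
    if (length(nd$children)) {
      nnode <<- nnode + 1L
      lapply(nd$children, count)
    } else {
      ntip <<- ntip + 1L
    }
    invisible(NULL)
  }
  count(root_node)
  if (ntip == 1L) {
    return(structure(list(tip.label = root_node$label, Nnode = 0L,
                          edge = matrix(integer(), 0L, 2L)),
                     class = "phylo"))
  }
  tip_labels <- character(ntip)
  node_labels <- character(nnode)
  edge_from <- integer()
  edge_to <- integer()
  edge_len <- numeric()
  tip_i <- 0L
  node_i <- ntip
  build <- function(nd) {
    if (length(nd$children)) {
      node_i <<- node_i + 1L
      my <- node_i
      node_labels[my - ntip] <<- nd$label %||% ""
      for (ch in nd$children) {
        ch_id <- build(ch)
        edge_from <<- c(edge_from, my)
        edge_to <<- c(edge_to, ch_id)
        edge_len <<- c(edge_len, ch$length %||% NA_real_)
      }
      my
    } else {
      tip_i <<- tip_i + 1L
      tip_labels[tip_i] <<- nd$label
      tip_i
    }
  }
  build(root_node)
  tree <- list(edge = matrix(c(edge_from, edge_to), ncol = 2L),
               tip.label = tip_labels, Nnode = nnode)
  if (!all(is.na(edge_len))) tree$edge.length <- edge_len
  if (any(nzchar(node_labels))) tree$node.label <- node_labels
  class(tree) <- "phylo"
  tree
}

# Serialize a nested node list(label=, length=, children=list(...)) to the
# Newick fragment for that node.
#' @keywords internal
#' @noRd
node_to_newick <- function(node) {
  body <- if (length(node$children)) {
    paste0("(", paste(vapply(node$children, node_to_newick, ""),
                      collapse = ","), ")",
           if (!is.null(node$label)) newick_label(node$label) else "")
  } else {
    newick_label(node$label)
  }
  if (!is.null(node$length)) {
    paste0(body, ":", format_brlen(node$length))
  } else {
    body
  }
}

#' UPGMA dendrogram from a distance matrix
#'
#' Classic agglomerative UPGMA (unweighted pair group method with
#' arithmetic mean): the closest pair of clusters is merged, the new
#' cluster's distance to every other cluster is the size-weighted
#' arithmetic mean of its members' distances, and the merge node is placed
#' at half the merge distance, yielding an ultrametric tree. Ties in the
#' minimum distance are broken deterministically by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' leaf), so the result does not depend on input order. Children of each
#' node are likewise ordered by smallest leaf.
#'
#' @param dm Symmetric distance matrix with labels as dimnames (e.g. from
#'   [distance_matrix()]), or a `dist` object.
#' @return An [ape::read.tree()]-style `phylo` tree with branch lengths.
#' @examples
#' dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' write_newick(upgma(dm))  # "((A:1,B:1):1,C:2);"
#' @export
upgma <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  labels <- rownames(dm) %||% as.character(seq_len(nrow(dm)))
  if (nrow(dm) < 2L) stop("UPGMA needs at least 2 labels", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-9 || any(abs(diag(dm)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  clusters <- lapply(labels, function(l) {
    list(min_leaf = l, size = 1L, height = 0,
         node = list(label = l, length = NULL, children = list()))
  })
  d <- dm
  while (length(clusters) > 1L) {
    n <- length(clusters)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        key <- sort(c(clusters[[i]]$min_leaf, clusters[[j]]$min_leaf))
        if (is.null(best) || d[i, j] < best$dist - 1e-15 ||
            (abs(d[i, j] - best$dist) <= 1e-15 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, dist = d[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    ci <- clusters[[i]]; cj <- clusters[[j]]
    h <- best$dist / 2
    kids <- list(ci, cj)
    kids <- kids[order(vapply(kids, `[[`, "", "min_leaf"))]
    new_node <- list(label = NULL, length = NULL, children = lapply(
      kids, function(cl) {
        nd <- cl$node
        nd$length <- h - cl$height
        nd
      }))
    merged <- list(min_leaf = min(ci$min_leaf, cj$min_leaf),
                   size = ci$size + cj$size, height = h, node = new_node)
    keep <- setdiff(seq_len(n), c(i, j))
    new_d <- (ci$size * d[i, keep, drop = TRUE] +
                cj$size * d[j, keep, drop = TRUE]) / (ci$size + cj$size)
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    clusters <- c(clusters[keep], list(merged))
  }
  nested_to_phylo(clusters[[1L]]$node)
}

#' Taxonomy-based tree for a set of genomes
#'
#' Builds a quick taxonomic overview tree from metadata alone: the
#' taxonomy is pruned to the union of the lineages of the selected genomes'
#' organisms, internal nodes with a single child are collapsed, and each
#' genome is attached as a leaf under its organism's taxon. All branch
#' lengths are 1 (the tree reflects taxonomic rank structure, not
#' divergence), so unlike [upgma()] output it is not ultrametric in any
#' meaningful sense.
#'
#' @param genomes Character vector of genome identifiers.
#' @param root Repository root (used to look up each genome's organism and
#'   taxid).
#' @param taxonomy Table from [read_lineage()]; defaults to the
#'   repository's `taxonomy.tsv`.
#' @return A `phylo` tree with genome identifiers as tips and taxon names
#'   as internal node labels (a single-tip stub for one genome).
#' @export
taxid_tree <- function(genomes, root, taxonomy = NULL) {
  genomes <- unique(as.character(genomes))
  if (!length(genomes)) stop("no genomes selected", call. = FALSE)
  if (is.null(taxonomy)) {
    taxfile <- file.path(root, "taxonomy.tsv")
    if (!file.exists(taxfile)) {
      stop("taxonomy required but no taxonomy.tsv in repository",
           call. = FALSE)
    }
    taxonomy <- read_lineage(taxfile)
  }
  gens <- list_genomes(root)
  taxid_of <- vapply(genomes, function(g) {
    idx <- match(g, gens$identifier)
    if (is.na(idx)) stop("unknown genome: '", g, "'", call. = FALSE)
    org <- read_organism_record(root, gens$organism[idx])
    if (is.na(org$taxid) || !org$taxid %in% taxonomy$taxid) {
      stop("genome '", g, "' has unresolvable taxid ", org$taxid,
           call. = FALSE)
    }
    org$taxid
  }, 0L)

  if (length(genomes) == 1L) {
    return(structure(list(tip.label = genomes, Nnode = 0L,
                          edge = matrix(integer(), 0L, 2L)),
                     class = "phylo"))
  }

  lineages <- lapply(unique(taxid_of), lineage_of, taxonomy = taxonomy)
  nodes <- unique(unlist(lapply(lineages, `[[`, "taxid")))
  tax <- taxonomy[match(nodes, taxonomy$taxid), , drop = FALSE]
  children <- split(tax$taxid[tax$parent != tax$taxid],
                    tax$parent[tax$parent != tax$taxid])
  roots <- tax$taxid[tax$parent == tax$taxid]
  stopifnot(length(roots) == 1L)
  leaves_at <- split(names(taxid_of), taxid_of)

  build <- function(taxid) {
    kid_tax <- sort(children[[as.character(taxid)]] %||% integer())
    genome_leaves <- sort(leaves_at[[as.character(taxid)]] %||% character())
    kid_nodes <- c(
      lapply(genome_leaves,
             function(g) list(label = g, length = 1, children = list())),
      lapply(kid_tax, build))
    if (length(kid_nodes) == 1L && !length(genome_leaves)) {
      # unary taxon: collapse it away
      return(kid_nodes[[1L]])
    }
    name <- tax$name[match(taxid, tax$taxid)]
    list(label = name, length = 1, children = kid_nodes)
  }
  top <- build(roots)
  top$length <- NULL
  nested_to_phylo(top)
}

#' Serialize a tree to Newick
#'
#' Standard Newick output with branch lengths (6 significant digits) and
#' internal node labels where present. Labels containing whitespace or
#' Newick syntax characters are single-quoted, with embedded quotes
#' doubled. `parse_newick(write_newick(t))` reproduces `t`.
#'
#' @param tree A `phylo` tree (single-tip stubs allowed).
#' @return A single Newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip == 1L && nrow(tree$edge) == 0L) {
    return(paste0(newick_label(tree$tip.label), ";"))
  }
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ser <- function(node_id) {
    edge_rows <- kids[[as.character(node_id)]]
    if (is.null(edge_rows)) {
      newick_label(tree$tip.label[node_id])
    } else {
      lbl <- if (!is.null(tree$node.label)) {
        l <- tree$node.label[node_id - ntip]
        if (is.na(l) || !nzchar(l)) "" else newick_label(l)
      } else ""
      paste0("(", paste(vapply(edge_rows, function(e) {
        s <- ser(tree$edge[e, 2L])
        if (!is.null(tree$edge.length)) {
          s <- paste0(s, ":", format_brlen(tree$edge.length[e]))
        }
        s
      }, ""), collapse = ","), ")", lbl)
    }
  }
  paste0(ser(ntip + 1L), ";")
}

#' Parse a Newick string
#'
#' Reads standard Newick (via [ape::read.tree()]) and normalises quoted
#' labels: surrounding single quotes are stripped and doubled quotes
#' unescaped. A bare label (`"A;"`) yields a single-tip stub tree.
#'
#' @param text Newick string.
#' @return A `phylo` tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) stop("Newick string must end with ';'",
                                   call. = FALSE)
  if (!grepl("(", text, fixed = TRUE)) {
    if (grepl(")", text, fixed = TRUE)) {
      stop("unbalanced parentheses in Newick string", call. = FALSE)
    }
    lbl <- sub(";\\s*$", "", text)
    return(structure(list(tip.label = unquote_label(lbl), Nnode = 0L,
                          edge = matrix(integer(), 0L, 2L)),
                     class = "phylo"))
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, " ')')", call. = FALSE)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick string", call. = FALSE)
  tree$tip.label <- vapply(tree$tip.label, unquote_label, "",
                           USE.NAMES = FALSE)
  if (!is.null(tree$node.label)) {
    tree$node.label <- vapply(tree$node.label, unquote_label, "",
                              USE.NAMES = FALSE)
  }
  tree
}

#' @keywords internal
#' @noRd
unquote_label <- function(label) {
  if (grepl("^'.*'$", label)) {
    gsub("''", "'", substr(label, 2L, nchar(label) - 1L), fixed = TRUE)
  } else {
    label
  }
}

#' Genome-similarity tree for a repository selection
#'
#' Convenience wrapper: computes [kmer_profile()] signatures for the
#' selected genomes' assemblies, the total-variation [distance_matrix()],
#' and the [upgma()] dendrogram.
#'
#' @param genomes Character vector of genome identifiers.
#' @param root Repository root.
#' @param k Word length (default 6).
#' @return A `phylo` tree.
#' @export
kmer_tree <- function(genomes, root, k = 6L) {
  genomes <- unique(as.character(genomes))
  if (length(genomes) < 2L) {
    stop("a similarity tree needs at least 2 genomes", call. = FALSE)
  }
  gens <- list_genomes(root)
  profiles <- lapply(genomes, function(g) {
    idx <- match(g, gens$identifier)
    if (is.na(idx)) stop("unknown genome: '", g, "'", call. = FALSE)
    kmer_profile(file.path(gens$path[idx], paste0(g, ".fna")), k = k)
  })
  upgma(distance_matrix(profiles, labels = genomes))
}
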