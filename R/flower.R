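#' Shared-genomic-content (flower plot) statistics
#'
#' Partitions every annotation observed in a genome selection by how many
#' of the selected genomes carry it, giving the numbers drawn on a flower
#' plot: the *core* (annotations shared by all genomes, the flower's
#' center) and, per genome, the *unique* annotations (in this genome and no
#' other) and the *shared* ones (in this genome and at least one — but not
#' all — of the others). For every genome,
#' `unique + shared + core = total` distinct annotations.
#'
#' Statistics are computed on distinct annotation identifiers, not gene
#' counts: two genes of one genome carrying the same annotation contribute
#' one annotation.
#'
#' @param genomes Character vector of at least two genome identifiers.
#' @param root Repository root.
#' @param annotation_type Optional type key to restrict to (e.g. `"KG"`).
#' @return Object of class `flower_stats`: list with `core` (integer) and
#'   `per_genome`, a data.frame with columns `genome`, `unique`, `shared`,
#'   `core`, `total`.
#' @export
compute_flower_stats <- function(genomes, root, annotation_type = NULL) {
  genomes <- unique(as.character(genomes))
  if (length(genomes) < 2L) {
    stop("flower statistics need at least 2 genomes", call. = FALSE)
  }
  types <- if (is.null(annotation_type)) NULL else annotation_type
  sets <- lapply(genomes, function(g) {
    unique(load_genome_annotations(root, g, types)$annotation)
  })
  names(sets) <- genomes
  flower_stats_from_sets(sets)
}

# Core of the computation, shared with tests that build sets directly:
# classify each annotation by the number of genomes carrying it.
#' @keywords internal
#' @noRd
flower_stats_from_sets <- function(sets) {
  n <- length(sets)
  membership <- table(unlist(lapply(sets, unique)))
  core <- sum(membership == n)
  per <- do.call(rbind, lapply(names(sets), function(g) {
    cnt <- membership[sets[[g]]]
    data.frame(genome = g,
               unique = sum(cnt == 1L),
               shared = sum(cnt > 1L & cnt < n),
               core = core,
               total = length(sets[[g]]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(core = as.integer(core), per_genome = per),
            class = "flower_stats")
}

#' @export
print.flower_stats <- function(x, ...) {
  cat(sprintf("<flower_stats> %d genomes, core = %d\n",
              nrow(x$per_genome), x$core))
  print.data.frame(x$per_genome, right = FALSE)
  invisible(x)
}

#' Draw a flower plot
#'
#' Minimal static rendering: one petal (ellipse) per genome around a
#' central disc showing the core count; each petal is labelled with its
#' genome's unique and shared counts.
#'
#' @param stats A [compute_flower_stats()] result.
#' @param main Plot title.
#' @return `stats`, invisibly.
#' @export
plot_flower <- function(stats, main = "Shared genomic content") {
  stopifnot(inherits(stats, "flower_stats"))
  per <- stats$per_genome
  n <- nrow(per)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  graphics::plot.new()
  graphics::plot.window(xlim = c(-2.2, 2.2), ylim = c(-2.2, 2.2), asp = 1)
  graphics::title(main = main)
  for (i in seq_len(n)) {
    phi <- seq(0, 2 * pi, length.out = 120)
    # petal: ellipse of half-axes (1, 0.35) rotated to angle theta[i],
    # centred 1 unit from the origin
    ex <- cos(phi); ey <- 0.35 * sin(phi)
    xr <- ex * cos(theta[i]) - ey * sin(theta[i]) + cos(theta[i])
    yr <- ex * sin(theta[i]) + ey * cos(theta[i]) + sin(theta[i])
    graphics::polygon(xr, yr, col = grDevices::adjustcolor("lightgoldenrod",
                                                           alpha.f = 0.6),
                      border = "grey40")
    lx <- 1.65 * cos(theta[i]); ly <- 1.65 * sin(theta[i])
    graphics::text(lx, ly, sprintf("%s\nu=%d s=%d", per$genome[i],
                                   per$unique[i], per$shared[i]), cex = 0.7)
  }
  phi <- seq(0, 2 * pi, length.out = 120)
  graphics::polygon(0.45 * cos(phi), 0.45 * sin(phi), col = "white",
                    border = "grey20")
  graphics::text(0, 0, as.character(stats$core), cex = 1.1, font = 2)
  invisible(stats)
}
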