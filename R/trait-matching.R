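#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value for a 2x2 contingency table by
#' probability-mass ordering: conditioning on the margins, the p-value is
#' the sum of hypergeometric probabilities of all tables with the same
#' margins whose probability does not exceed that of the observed table
#' (the convention of `stats::fisher.test`).
#'
#' With margins fixed, every candidate table's probability shares the
#' denominator `choose(n, a + c)`, so tables are compared through their
#' integer numerators `choose(a + b, x) * choose(c + d, a + c - x)`. For the
#' table sizes this toolkit works with (tens of genomes) these products are
#' exactly representable in doubles, so ties in probability are resolved
#' exactly rather than by floating-point noise; a tiny relative guard
#' (`1e-7`) keeps the comparison robust for very large margins.
#'
#' @param a,b Genomes in group 1 with / without the annotation.
#' @param c,d Genomes in group 2 with / without the annotation.
#' @return The exact two-sided p-value in `[0, 1]`. Degenerate margins
#'   (an empty row or column) yield `p = 1`.
#' @examples
#' fisher_exact(2, 0, 0, 2)  # 1/3
#' fisher_exact(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact <- function(a, b, c, d) {
  if (length(a) == 4L && missing(b)) {
    d <- a[[4L]]; c <- a[[3L]]; b <- a[[2L]]; a <- a[[1L]]
  }
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L,
            length(d) == 1L)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d)))) {
    stop("contingency table cells must be non-negative integers",
         call. = FALSE)
  }
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
  x <- max(0, k - r2):min(k, r1)
  num <- choose(r1, x) * choose(r2, k - x)
  obs <- choose(r1, a) * choose(r2, c)
  sum(num[num <= obs * (1 + 1e-7)]) / sum(num)
}

#' Benjamini-Hochberg step-up correction
#'
#' Applies the Benjamini-Hochberg false-discovery-rate procedure: sort the
#' m p-values ascending, set `q_(i) = min_{j >= i} m * p_(j) / j` capped at
#' 1, and map back to the input order. A test is rejected when its q-value
#' is at most `alpha`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target false discovery rate (default 0.1).
#' @return List with `q` (adjusted values, input order) and `rejected`
#'   (logical vector).
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.1)
#' @export
benjamini_hochberg <- function(pvalues, alpha = 0.1) {
  if (!length(pvalues)) return(list(q = numeric(), rejected = logical()))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  q_sorted <- pmin(1, rev(cummin(rev(m * p_sorted / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  list(q = q, rejected = q <= alpha)
}

#' Gene-trait matching across two genome groups
#'
#' Finds annotations associated with a binary phenotype. The input is two
#' non-intersecting genome sets that differ in a trait. For every annotation
#' present in at least one selected genome, a 2x2 presence/absence table is
#' built (a genome "has" an annotation if at least one of its genes carries
#' it), tested with [fisher_exact()], and the resulting p-values are
#' jointly corrected with [benjamini_hochberg()]. Annotations absent from
#' every selected genome are untestable and excluded from the family.
#'
#' @param group1,group2 Character vectors of genome identifiers; must be
#'   disjoint and non-empty.
#' @param root Repository root.
#' @param alpha False discovery rate for the correction (default 0.1).
#' @param annotation_type Optional type key to restrict testing to (e.g.
#'   `"KG"`); all declared types by default.
#' @return data.frame with one row per tested annotation — columns
#'   `annotation`, `a`, `b`, `c`, `d` (the contingency table), `p`, `q`,
#'   `significant` — sorted by `q`, then `p`, then identifier.
#' @export
gene_trait_match <- function(group1, group2, root, alpha = 0.1,
                             annotation_type = NULL) {
  group1 <- unique(as.character(group1))
  group2 <- unique(as.character(group2))
  if (!length(group1) || !length(group2)) {
    stop("both genome groups must be non-empty", call. = FALSE)
  }
  overlap <- intersect(group1, group2)
  if (length(overlap)) {
    stop("genome groups must be disjoint; shared: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  types <- if (is.null(annotation_type)) NULL else annotation_type
  presence <- lapply(c(group1, group2), function(g) {
    unique(load_genome_annotations(root, g, types)$annotation)
  })
  names(presence) <- c(group1, group2)
  annos <- sort(unique(unlist(presence)))
  if (!length(annos)) {
    return(data.frame(annotation = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  has1 <- vapply(annos, function(a) {
    sum(vapply(presence[group1], function(s) a %in% s, FALSE))
  }, 0L)
  has2 <- vapply(annos, function(a) {
    sum(vapply(presence[group2], function(s) a %in% s, FALSE))
  }, 0L)
  a <- has1
  b <- length(group1) - has1
  cc <- has2
  d <- length(group2) - has2
  p <- mapply(fisher_exact, a, b, cc, d)
  bh <- benjamini_hochberg(p, alpha)
  res <- data.frame(annotation = annos, a = a, b = b, c = cc, d = d,
                    p = p, q = bh$q, significant = bh$rejected,
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, res$p, res$annotation), , drop = FALSE]
  rownames(res) <- NULL
  res
}
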