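# Independent reference implementations used to verify the package's own
# algorithms. They are deliberately written differently from the code they
# check (stats:: distributions, literal textbook definitions, naive
# recomputation).

# Two-sided Fisher p-value by brute-force enumeration of all tables with
# the observed margins, using stats::dhyper for the probabilities.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
  x <- max(0, k - r2):min(k, r1)
  prob <- stats::dhyper(x, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Literal step-up rejection rule: reject the k* smallest p-values where
# k* = max{ i : p_(i) <= i * alpha / m }.
oracle_bh_rejected <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(m) * alpha / m)
  rejected <- logical(m)
  if (length(ok)) rejected[ord[seq_len(max(ok))]] <- TRUE
  rejected
}

# Naive UPGMA: cluster distances recomputed each round as the plain average
# of all leaf-pair distances read off the ORIGINAL matrix (O(n^3) total).
# Returns the cophenetic matrix (2 * merge height for each leaf pair),
# which determines the ultrametric tree completely. Same lexicographic
# tie-break as the implementation under test.
oracle_upgma_cophenetic <- function(dm) {
  labels <- rownames(dm)
  clusters <- lapply(labels, identity)
  coph <- matrix(0, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  while (length(clusters) > 1L) {
    n <- length(clusters)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    for (x in clusters[[best$i]]) {
      for (y in clusters[[best$j]]) {
        coph[x, y] <- coph[y, x] <- best$d
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  coph
}

# Random symmetric distance matrix with zero diagonal, entries in [0, 1].
random_distance_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2)
  d[lower.tri(d)] <- vals
  d <- d + t(d)
  d
}

# Brute-force flower classification: count each annotation's genome
# membership directly.
oracle_flower <- function(sets) {
  n <- length(sets)
  all_annos <- unique(unlist(sets))
  counts <- vapply(all_annos, function(a) {
    sum(vapply(sets, function(s) a %in% s, FALSE))
  }, 0L)
  names(counts) <- all_annos
  list(core = sum(counts == n),
       per_genome = lapply(sets, function(s) {
         c(unique = sum(counts[s] == 1L),
           shared = sum(counts[s] > 1L & counts[s] < n),
           total = length(s))
       }))
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
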