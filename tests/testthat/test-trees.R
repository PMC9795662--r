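make_profile <- function(freq, k = 1L, genome = "P") {
  structure(list(genome = genome, k = as.integer(k), freq = freq),
            class = "kmer_profile")
}

test_that("k-mer profiles count canonical ACGT-only windows", {
  f <- withr::local_tempfile(lines = c(">s", "AAAAAA"))
  p <- kmer_profile(f, k = 6)
  expect_equal(unname(p$freq["AAAAAA"]), 1)
  expect_equal(sum(p$freq), 1)

  # all four valid windows of ACGTNACGT at k=3 canonicalise to ACG
  f2 <- withr::local_tempfile(lines = c(">s", "ACGTNACGT"))
  p2 <- kmer_profile(f2, k = 3)
  expect_equal(unname(p2$freq["ACG"]), 1)
  expect_equal(sum(p2$freq > 0), 1L)

  f3 <- withr::local_tempfile(lines = c(">s", "NNNNNNNN"))
  expect_error(kmer_profile(f3, k = 6), "no valid")
})

test_that("profiles are strand-independent (canonicalisation)", {
  withr::local_seed(23)
  for (i in 1:50) {
    s <- random_dna_string(200)
    p <- genorepo:::kmer_profile_seq(s, k = 6)
    q <- genorepo:::kmer_profile_seq(revcomp_string(s), k = 6)
    expect_equal(p$freq, q$freq, tolerance = 1e-12)
  }
})

test_that("total-variation distances behave as a metric on [0, 1]", {
  p <- make_profile(c(A = .5, C = .5, G = 0, T = 0))
  q <- make_profile(c(A = .25, C = .25, G = .5, T = 0))
  disj <- make_profile(c(A = 0, C = 0, G = 0, T = 1))
  expect_equal(distance_matrix(list(p, p), c("a", "b"))["a", "b"], 0)
  expect_equal(distance_matrix(list(p, q), c("a", "b"))["a", "b"], 0.5)
  expect_equal(distance_matrix(list(p, disj), c("a", "b"))["a", "b"], 1)
  expect_error(distance_matrix(list(p, make_profile(rep(1 / 16, 16), k = 2))),
               "incompatible k")

  withr::local_seed(29)
  for (i in 1:30) {
    profs <- lapply(1:3, function(j) {
      genorepo:::kmer_profile_seq(random_dna_string(150), k = 4)
    })
    d <- distance_matrix(profs, c("x", "y", "z"))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), c(0, 0, 0))
    expect_true(all(d >= 0 & d <= 1))
    expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"] + 1e-12)
  }
})

test_that("upgma reproduces the worked dendrogram examples", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(write_newick(upgma(dm)), "((A:1,B:1):1,C:2);")

  dm2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(upgma(dm2)), "(A:0.3,B:0.3);")
  expect_error(upgma(dm[1, 1, drop = FALSE]), "at least 2")
})

test_that("tie-breaking makes upgma invariant under input permutation", {
  labels <- c("D", "B", "A", "C")
  d <- matrix(0.4, 4, 4, dimnames = list(labels, labels))
  diag(d) <- 0
  ref <- write_newick(upgma(d))
  withr::local_seed(31)
  for (i in 1:10) {
    perm <- sample(labels)
    expect_equal(write_newick(upgma(d[perm, perm])), ref)
  }
})

test_that("upgma agrees with the naive reference and is ultrametric", {
  withr::local_seed(37)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    d <- random_distance_matrix(n)
    tree <- upgma(d)
    coph <- as.matrix(ape::cophenetic.phylo(tree))
    oracle <- oracle_upgma_cophenetic(d)
    expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-9)
    depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
    expect_lt(diff(range(depths)), 1e-9)
  }
})

test_that("upgma cophenetic heights match phangorn's implementation", {
  skip_if_not_installed("phangorn")
  withr::local_seed(41)
  d <- random_distance_matrix(8)
  ours <- as.matrix(ape::cophenetic.phylo(upgma(d)))
  theirs <- as.matrix(ape::cophenetic.phylo(phangorn::upgma(stats::as.dist(d))))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-9)
})

test_that("a duplicated genome forms a zero-length cherry", {
  withr::local_seed(43)
  profs <- lapply(1:3, function(j) {
    genorepo:::kmer_profile_seq(random_dna_string(300), k = 4)
  })
  profs <- c(profs, profs[1])  # twin of the first genome
  d <- distance_matrix(profs, c("G1", "G2", "G3", "G1twin"))
  expect_equal(d["G1", "G1twin"], 0)
  tree <- upgma(d)
  coph <- as.matrix(ape::cophenetic.phylo(tree))
  expect_equal(coph["G1", "G1twin"], 0)
})

test_that("taxonomy trees prune, collapse and attach genomes", {
  repo <- shared_fixture_root()
  # two Actinobacteria + one Firmicutes outgroup: ((a, b), c) topology
  tree <- taxid_tree(c("ORG4-1", "ORG5-1", "ORG1-1"), repo)
  expect_setequal(tree$tip.label, c("ORG4-1", "ORG5-1", "ORG1-1"))
  coph <- as.matrix(ape::cophenetic.phylo(tree))
  expect_lt(coph["ORG4-1", "ORG5-1"], coph["ORG4-1", "ORG1-1"])

  single <- taxid_tree("ORG1-1", repo)
  expect_equal(write_newick(single), "ORG1-1;")

  # all same taxid: a star under one taxon
  star <- taxid_tree(c("ORG4-1", "ORG4-2", "ORG5-1"), repo)
  coph2 <- as.matrix(ape::cophenetic.phylo(star))
  expect_true(all(coph2[upper.tri(coph2)] == 2))

  expect_error(taxid_tree("NOPE-1", repo), "NOPE-1")
})

test_that("newick writing and parsing round-trip, with quoting", {
  expect_equal(write_newick(parse_newick("A;")), "A;")

  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(dm)
  rt <- parse_newick(write_newick(tree))
  expect_equal(write_newick(rt), write_newick(tree))

  spaced <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                   dimnames = list(c("strain one", "strain_two"),
                                   c("strain one", "strain_two")))
  nwk <- write_newick(upgma(spaced))
  expect_match(nwk, "'strain one'", fixed = TRUE)
  expect_setequal(parse_newick(nwk)$tip.label, c("strain one", "strain_two"))

  expect_error(parse_newick("((A:1,B:1):1;"), "parenthes")
  expect_error(parse_newick("(A:1,B:1)"), ";")
})

test_that("kmer_tree builds a tree over repository assemblies", {
  repo <- shared_fixture_root()
  genomes <- c("ORG1-1", "ORG1-2", "ORG2-1", "ORG4-1")
  tree <- kmer_tree(genomes, repo)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, genomes)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(kmer_tree("ORG1-1", repo), "at least 2")
})
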