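test_that("init creates the expected layout and refuses non-empty targets", {
  root <- withr::local_tempdir()
  target <- file.path(root, "repo")
  report <- init_folder_structure(target)
  expect_s3_class(report, "validation_report")
  expect_equal(nrow(report), 0L)
  expect_true(all(dir.exists(file.path(target, c(
    "organisms", "annotation-descriptions", "pathway-maps")))))
  expect_true(file.exists(file.path(target, "config.json")))
  expect_equal(nrow(validate_repo(target)), 0L)

  dirty <- file.path(root, "dirty")
  dir.create(dirty)
  writeLines("x", file.path(dirty, "stray.txt"))
  expect_error(init_folder_structure(dirty), "refusing")
  expect_equal(list.files(dirty), "stray.txt")
})

test_that("import renames the triplet, writes metadata, and validates clean", {
  root <- withr::local_tempdir()
  init_folder_structure(file.path(root, "repo"))
  repo <- file.path(root, "repo")
  imp <- make_import_dir()
  rec <- import_genome(imp, repo, organism = "Strain1", identifier = "S1-1")
  expect_s3_class(rec, "genome_record")
  gdir <- file.path(repo, "organisms", "Strain1", "genomes", "S1-1")
  expect_true(all(file.exists(file.path(gdir, c(
    "S1-1.fna", "S1-1.gbk", "S1-1.gff", "genome.json")))))
  org <- jsonlite::fromJSON(file.path(repo, "organisms", "Strain1",
                                      "organism.json"))
  expect_equal(org$representative, "S1-1")
  expect_equal(nrow(validate_repo(repo)), 0L)
})

test_that("import errors name the missing or ambiguous file", {
  root <- withr::local_tempdir()
  repo <- file.path(root, "repo")
  init_folder_structure(repo)
  imp <- make_import_dir()
  file.remove(list.files(imp, pattern = "\\.gff$", full.names = TRUE))
  expect_error(import_genome(imp, repo, "O", "G1"), "GFF3")

  imp2 <- make_import_dir()
  writeLines(">c", file.path(imp2, "second_assembly.fna"))
  expect_error(import_genome(imp2, repo, "O", "G1"), "ambiguous")
})

test_that("re-importing an identifier is refused and leaves bytes unchanged", {
  root <- withr::local_tempdir()
  repo <- file.path(root, "repo")
  init_folder_structure(repo)
  imp <- make_import_dir()
  import_genome(imp, repo, "Strain1", "S1-1")
  before <- md5_tree(repo)
  imp2 <- make_import_dir()
  expect_error(import_genome(imp2, repo, "Strain2", "S1-1"),
               "already present")
  expect_identical(md5_tree(repo), before)
  expect_equal(nrow(validate_repo(repo)), 0L)
})

test_that("the representative only moves when explicitly requested", {
  root <- withr::local_tempdir()
  repo <- file.path(root, "repo")
  init_folder_structure(repo)
  import_genome(make_import_dir(), repo, "Strain1", "S1-1")
  import_genome(make_import_dir(), repo, "Strain1", "S1-2")
  expect_equal(representative_genomes(repo)$genome, "S1-1")
  import_genome(make_import_dir(), repo, "Strain1", "S1-3",
                set_representative = TRUE)
  expect_equal(representative_genomes(repo)$genome, "S1-3")
  expect_equal(nrow(validate_repo(repo)), 0L)
})

test_that("validate_repo reports broken references, duplicates and missing files", {
  repo <- local_fixture_repo()
  expect_equal(nrow(validate_repo(repo)), 0L)

  # dangling representative
  ojson <- file.path(repo, "organisms", "ORG1", "organism.json")
  org <- jsonlite::fromJSON(ojson)
  org$representative <- "GHOST"
  jsonlite::write_json(org, ojson, auto_unbox = TRUE)
  rep1 <- validate_repo(repo)
  expect_true("ORG_REPRESENTATIVE_MISSING" %in% rep1$rule)
  expect_match(rep1$message[rep1$rule == "ORG_REPRESENTATIVE_MISSING"],
               "GHOST")
  org$representative <- "ORG1-2"
  jsonlite::write_json(org, ojson, auto_unbox = TRUE)

  # duplicate identifier in another organism
  dup <- file.path(repo, "organisms", "ORG2", "genomes", "ORG1-1")
  src <- file.path(repo, "organisms", "ORG1", "genomes", "ORG1-1")
  dir.create(dup)
  file.copy(list.files(src, full.names = TRUE), dup)
  rep2 <- validate_repo(repo)
  expect_true("GEN_ID_DUPLICATE" %in% rep2$rule)
  unlink(dup, recursive = TRUE)

  # missing data file
  fna <- file.path(repo, "organisms", "ORG3", "genomes", "ORG3-1",
                   "ORG3-1.fna")
  file.remove(fna)
  rep3 <- validate_repo(repo)
  expect_true("GEN_FILE_MISSING" %in% rep3$rule)
  expect_match(rep3$path[rep3$rule == "GEN_FILE_MISSING"], "ORG3-1.fna")
})

test_that("validation reports are ordered deterministically", {
  repo <- local_fixture_repo()
  file.remove(file.path(repo, "organisms", "ORG5", "genomes", "ORG5-1",
                        "ORG5-1.gff"))
  file.remove(file.path(repo, "organisms", "ORG2", "genomes", "ORG2-1",
                        "ORG2-1.fna"))
  rep <- validate_repo(repo)
  expect_identical(rep$path, sort(rep$path))
})

test_that("selectors resolve tags, taxa, ranks and identifiers", {
  repo <- shared_fixture_root()
  g1 <- resolve_selector("@tag:halophile", repo)
  g2 <- resolve_selector("@tag:mesophile", repo)
  expect_length(g1, 3L)
  expect_length(g2, 3L)
  expect_length(intersect(g1, g2), 0L)
  # representatives only (version 2 of each organism)
  expect_true(all(grepl("-2$", c(g1, g2))))

  expect_setequal(resolve_selector("@tax:Firmicutes", repo), g1)
  expect_setequal(resolve_selector("@taxphylum:Firmicutes", repo), g1)
  expect_setequal(resolve_selector("@tax:Bacteria", repo), c(g1, g2))
  # a rank-restricted match is always a subset of the rank-free match
  # (an unmatched rank resolves to nothing, reported as not-found)
  for (name in c("Firmicutes", "Bifidobacterium", "Lactobacillus")) {
    free <- resolve_selector(paste0("@tax:", name), repo)
    for (rank in c("phylum", "genus")) {
      restricted <- tryCatch(
        resolve_selector(paste0("@tax", rank, ":", name), repo),
        error = function(e) character())
      expect_true(all(restricted %in% free))
    }
  }
  # wrong rank finds nothing
  expect_error(resolve_selector("@taxgenus:Firmicutes", repo), "Firmicutes")

  expect_equal(resolve_selector("ORG1-1", repo), "ORG1-1")
  expect_setequal(resolve_selector("ORG1-1, @tag:mesophile", repo),
                  c("ORG1-1", g2))

  expect_error(resolve_selector("@tag:nosuchtag", repo), "nosuchtag")
  expect_error(resolve_selector("NOPE-1", repo), "NOPE-1")
})

test_that("selector resolution is idempotent and order-independent", {
  repo <- shared_fixture_root()
  a <- resolve_selector("@tag:halophile,ORG4-1", repo)
  b <- resolve_selector("ORG4-1,@tag:halophile", repo)
  expect_identical(a, b)
  expect_identical(resolve_selector(paste(a, collapse = ","), repo), a)
})
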