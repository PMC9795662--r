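# Shared synthetic repository: generated once per test run and used
# read-only by most tests. Tests that mutate a repository build their own.
shared_fixture_env <- new.env(parent = emptyenv())

shared_fixture_root <- function() {
  if (is.null(shared_fixture_env$root)) {
    root <- file.path(tempdir(), "genorepo-shared-fixture")
    unlink(root, recursive = TRUE)
    generate_fixture_repo(fixture_spec(seed = 42L), root)
    shared_fixture_env$root <- root
  }
  shared_fixture_env$root
}

# A fresh private fixture repository for tests that modify files.
local_fixture_repo <- function(spec = fixture_spec(seed = 42L),
                               env = parent.frame()) {
  root <- tempfile("genorepo-fixture-")
  generate_fixture_repo(spec, root)
  withr::defer(unlink(root, recursive = TRUE), envir = env)
  root
}

# A minimal import directory with Prokka-style file names.
make_import_dir <- function(base = "PROKKA_07082026",
                            env = parent.frame()) {
  dir <- tempfile("import-")
  dir.create(dir)
  writeLines(c(">contig_1", "ACGTACGTACGTACGTACGT"),
             file.path(dir, paste0(base, ".fna")))
  writeLines(c("LOCUS       contig_1 20 bp DNA linear BCT",
               "DEFINITION  import fixture.", "FEATURES             Location/Qualifiers",
               "     source          1..20", "ORIGIN",
               "        1 acgtacgtac gtacgtacgt", "//"),
             file.path(dir, paste0(base, ".gbk")))
  writeLines(c("##gff-version 3",
               "contig_1\ttest\tgene\t1\t9\t.\t+\t.\tID=gene1"),
             file.path(dir, paste0(base, ".gff")))
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

md5_tree <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  unname(tools::md5sum(files))
}
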