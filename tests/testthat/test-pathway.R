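write_svg <- function(lines, env = parent.frame()) {
  f <- tempfile(fileext = ".svg")
  writeLines(c('<svg xmlns="http://www.w3.org/2000/svg">', lines, "</svg>"),
             f)
  withr::defer(unlink(f), envir = env)
  f
}

test_that("pathway SVG parsing extracts annotated boxes only", {
  f <- write_svg(c(
    '<rect id="r1" data-annotations="K00031 EC:1.1.1.42"/>',
    '<rect id="r2" data-annotations="K00001"/>',
    '<rect id="decor"/>',
    '<text>label</text>'))
  map <- parse_pathway_svg(f)
  expect_length(map$boxes, 2L)
  expect_equal(map$boxes$r1, c("K00031", "EC:1.1.1.42"))
  expect_equal(map$boxes$r2, "K00001")

  plain <- write_svg('<rect id="r1"/>')
  expect_length(parse_pathway_svg(plain)$boxes, 0L)

  dup <- write_svg(c('<rect id="x" data-annotations="K00001"/>',
                     '<rect id="x" data-annotations="K00002"/>'))
  expect_error(parse_pathway_svg(dup), "duplicate")

  noid <- write_svg('<rect data-annotations="K00001"/>')
  expect_error(parse_pathway_svg(noid), "no id")

  bad <- withr::local_tempfile(lines = "<svg><rect</svg>")
  expect_error(parse_pathway_svg(bad))
})

test_that("coverage counts genomes (not genes) per box and group", {
  repo <- shared_fixture_root()
  map <- parse_pathway_svg(file.path(repo, "pathway-maps",
                                     "demo_pathway.svg"))
  g1 <- resolve_selector("@tag:halophile", repo)
  g2 <- resolve_selector("@tag:mesophile", repo)

  cov <- compute_coverage(map, list(g1, g2), repo)
  expect_setequal(unique(cov$box), names(map$boxes))
  core1 <- cov[cov$box == "box-core" & cov$group == 1, ]
  expect_equal(core1$count, 3)
  expect_equal(core1$size, 3)
  trait <- cov[cov$box == "box-trait", ]
  expect_equal(trait$count[trait$group == 1], 3)
  expect_equal(trait$count[trait$group == 2], 0)
  absent <- cov[cov$box == "box-absent", ]
  expect_true(all(absent$count == 0))
  expect_true(all(cov$count >= 0 & cov$count <= cov$size))

  # a genome with several genes behind one box still counts once
  m <- coverage_matrix(c("K00001", "EC:1.1.1.1"), g1[1], repo)
  expect_gte(sum(m), 2)  # two distinct annotations hit box-core
  expect_equal(cov$count[cov$box == "box-core" & cov$group == 1], 3)

  expect_error(compute_coverage(map, list(g1, g2, g1), repo), "1 or 2")
  expect_error(compute_coverage(map, list(g1, g1), repo), "disjoint")
})

test_that("coverage is monotone when a group grows", {
  repo <- shared_fixture_root()
  map <- parse_pathway_svg(file.path(repo, "pathway-maps",
                                     "demo_pathway.svg"))
  g1 <- resolve_selector("@tag:halophile", repo)
  g2 <- resolve_selector("@tag:mesophile", repo)
  small <- compute_coverage(map, list(g1[1:2]), repo)
  big <- compute_coverage(map, list(c(g1[1:2], g2[1])), repo)
  merged <- merge(small, big, by = "box")
  expect_true(all(merged$count.y >= merged$count.x))
})

test_that("the color ramp runs white, yellow, ..., red and is monotone", {
  expect_equal(color_for_count(0, 19), "#FFFFFF")
  expect_equal(color_for_count(1, 19), "#FFFF00")
  expect_equal(color_for_count(19, 19), "#FF0000")
  expect_equal(color_for_count(1, 1), "#FF0000")
  expect_error(color_for_count(5, 4), "group_size")

  greens <- vapply(1:19, function(i) {
    strtoi(substr(color_for_count(i, 19), 4, 5), 16L)
  }, 0L)
  expect_true(all(diff(greens) <= 0))
  expect_equal(greens[1], 255L)
  expect_equal(greens[19], 0L)
})

test_that("rendering recolors boxes, keeps the SVG valid, spares decoration", {
  repo <- shared_fixture_root()
  map <- parse_pathway_svg(file.path(repo, "pathway-maps",
                                     "demo_pathway.svg"))
  g1 <- resolve_selector("@tag:halophile", repo)
  g2 <- resolve_selector("@tag:mesophile", repo)

  # one group, full coverage boxes turn red
  cov1 <- compute_coverage(map, list(g1), repo)
  out1 <- withr::local_tempfile(fileext = ".svg")
  render_colored_svg(map, cov1, out1)
  re1 <- parse_pathway_svg(out1)
  expect_length(re1$boxes, length(map$boxes))
  doc1 <- xml2::read_xml(out1)
  fill_of <- function(doc, id) {
    xml2::xml_attr(xml2::xml_find_first(
      doc, sprintf("//*[@id='%s']", id)), "fill")
  }
  expect_equal(fill_of(doc1, "box-core"), "#FF0000")
  expect_equal(fill_of(doc1, "box-absent"), "#FFFFFF")

  # two groups: hard-stop gradients referenced per box
  cov2 <- compute_coverage(map, list(g1, g2), repo)
  out2 <- withr::local_tempfile(fileext = ".svg")
  render_colored_svg(map, cov2, out2)
  doc2 <- xml2::read_xml(out2)
  expect_match(fill_of(doc2, "box-trait"), "^url\\(#")
  grads <- xml2::xml_find_all(doc2, "//*[local-name()='linearGradient']")
  expect_length(grads, length(map$boxes))
  stops <- xml2::xml_find_all(grads[[1]], ".//*[local-name()='stop']")
  expect_length(stops, 2L)
  expect_equal(unique(xml2::xml_attr(stops, "offset")), "0.5")

  # inert decoration untouched
  expect_length(xml2::xml_find_all(doc2, "//*[local-name()='text']"), 1L)
})
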