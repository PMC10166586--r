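count_nodes <- function(doc, xpath) {
  length(xml2::xml_find_all(doc, xpath))
}

test_that("color assignment is deterministic, distinct, grey for private", {
  m1 <- mapping_of_motifs("ACG")
  c1 <- assign_symbol_colors(m1)
  expect_length(c1, 2L)  # one symbol + the private symbol
  expect_equal(c1[[private_symbol()]], "#9E9E9E")
  expect_false(c1[[1]] == c1[[private_symbol()]])

  m2 <- mapping_of_motifs(c("ACG", "TTG", "GGA"))
  c2 <- assign_symbol_colors(m2)
  expect_false(anyDuplicated(c2) > 0)
  expect_identical(assign_symbol_colors(m2), c2)

  # full alphabet remains distinct
  big <- mapping_of_motifs(all_4mers[1:90])
  cb <- assign_symbol_colors(big)
  expect_length(cb, 91L)
  expect_false(anyDuplicated(cb) > 0)
})

test_that("the SVG carries one band per allele and a faithful legend", {
  d <- decompose_alleles(c(s = "ACCTTGACCTTGACCTTTG"), "ACCTTG")
  m <- motif_mapping(d, 1)
  sm <- symbol_score_matrix(m)
  a <- align_encoded(encode_alleles(d, m), sm)
  cols <- assign_symbol_colors(m)
  f <- withr::local_tempfile(fileext = ".svg")
  write_composition_svg(a, colors = cols, mapping = m, file = f)
  doc <- xml2::read_xml(f)
  expect_equal(count_nodes(doc, "//*[local-name()='g'][@class='allele']"), 1L)
  expect_equal(count_nodes(doc, "//*[local-name()='rect'][@class='cell']"), 3L)
  expect_equal(count_nodes(doc, "//*[local-name()='g'][@class='legend-entry']"), 2L)
  # no group bar without annotations
  expect_equal(count_nodes(doc, "//*[local-name()='rect'][@class='group']"), 0L)
})

test_that("synthetic alleles render one band each with distinct symbol colors", {
  sim <- simulate_tr_alleles(c("ACGTGG", "ACGTAG"), n_alleles = 10,
                             copy_range = c(3, 6), sub_rate = 0.05, seed = 21,
                             groups = c("AFR", "EUR"))
  res <- tr_composition(sim$sequences, c("ACGTGG", "ACGTAG"),
                        annotations = sim$groups)
  f <- withr::local_tempfile(fileext = ".svg")
  write_composition_svg(res$alignment, res$order, res$colors, res$mapping,
                        res$annotations, f)
  doc <- xml2::read_xml(f)
  expect_equal(count_nodes(doc, "//*[local-name()='g'][@class='allele']"), 10L)
  expect_equal(count_nodes(doc, "//*[local-name()='rect'][@class='group']"), 10L)

  mat <- motifcomp:::.alignment_matrix(res$alignment)
  present <- setdiff(unique(as.vector(mat)), gap_symbol())
  fills <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='rect'][@class='cell']"), "fill")
  grey <- res$colors[[private_symbol()]]
  expect_equal(length(setdiff(unique(fills), grey)),
               length(setdiff(present, private_symbol())))
  # cell count equals total non-gap symbols
  expect_equal(length(fills), sum(mat != gap_symbol()))
})

test_that("the motif table lists symbol, motif, count and color", {
  m <- mapping_of_motifs(c("ACG", "TTG"))
  cols <- assign_symbol_colors(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motif_table(m, cols, f)
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(tab), c("symbol", "motif", "count", "color"))
  expect_equal(nrow(tab), 2L)
  expect_true(all(grepl("^#", tab$color)))
})

test_that("pdf rendering draws without error", {
  sim <- simulate_tr_alleles("ACGTGG", n_alleles = 4, copy_range = c(2, 4),
                             seed = 3)
  res <- tr_composition(sim$sequences, "ACGTGG")
  f <- withr::local_tempfile(fileext = ".pdf")
  render_composition(res$alignment, res$order, res$colors, res$mapping,
                     file = f, format = "pdf")
  expect_true(file.exists(f) && file.size(f) > 0)
})
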