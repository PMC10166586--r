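test_that("the symbol alphabet has 90 distinct safe characters", {
  ab <- symbol_alphabet()
  expect_length(ab, 90L)
  expect_false(anyDuplicated(ab) > 0)
  expect_false(gap_symbol() %in% ab)
  expect_false(private_symbol() %in% ab)
  expect_false(any(grepl("\\s", ab)))
  expect_equal(ab[1:3], c("1", "2", "3"))
})

test_that("mapping assigns symbols by descending count with lexicographic ties", {
  d <- decompose_alleles(c(s = "ACCTTGACCTTGACCTTTG"), "ACCTTG")
  m <- motif_mapping(d, threshold = 1)
  expect_equal(m$entries$symbol, c("1", "2"))
  expect_equal(m$entries$motif, c("ACCTTG", "ACCTTTG"))
  expect_equal(m$entries$count, c(2L, 1L))
  expect_equal(nrow(m$private), 0L)

  # counts must sum to the number of segments
  expect_equal(sum(m$entries$count) + sum(m$private$count), 3L)

  one <- motif_mapping(fake_decomposition("ACG"), "auto")
  expect_equal(nrow(one$entries), 1L)
  expect_equal(nrow(one$private), 0L)
})

test_that("auto threshold never errors and respects the 90-symbol cap", {
  motifs95 <- all_4mers[1:95]  # 95 distinct motifs, each observed once
  dec <- fake_decomposition(motifs95)
  m <- motif_mapping(dec, "auto")
  # t = 1 keeps 95 > 90, so auto moves to t = 2 and all collapse to private
  expect_equal(m$threshold, 2L)
  expect_equal(nrow(m$entries), 0L)
  expect_equal(nrow(m$private), 95L)

  expect_error(motif_mapping(dec, 1), "90 symbols")
})

test_that("auto picks the smallest threshold that fits, maximizing symbols", {
  # 88 motifs seen three times, 5 motifs seen once: t=1 would need 93 symbols,
  # t=2 keeps exactly the 88 frequent ones
  subs <- c(rep(all_4mers[1:88], each = 3), all_4mers[89:93])
  m <- motif_mapping(fake_decomposition(subs), "auto")
  expect_equal(m$threshold, 2L)
  expect_equal(nrow(m$entries), 88L)
  expect_equal(nrow(m$private), 5L)
})

test_that("encoding substitutes one symbol per segment", {
  d <- decompose_alleles(c(s = "ACCTTGACCTTGACCTTTG"), "ACCTTG")
  m <- motif_mapping(d, 1)
  expect_equal(encode_allele(d$decompositions$s, m), "112")
  expect_equal(unname(encode_alleles(d, m)), "112")

  # all segments private
  dec <- fake_decomposition(c("ACG", "ACT", "AGT"))
  mp <- motif_mapping(dec, threshold = 5)
  expect_equal(encode_allele(dec, mp), "???")

  # motif absent from the mapping
  other <- fake_decomposition("TTTT")
  expect_error(encode_allele(other, m), "TTTT")
})

test_that("non-private symbols decode back to the motif list", {
  set.seed(12)
  motifs <- c("ACGT", "ACGA", "TTGC", "GGC")
  subs <- sample(motifs, 40, replace = TRUE)
  dec <- fake_decomposition(subs)
  m <- motif_mapping(dec, 1)
  enc <- encode_allele(dec, m)
  lut <- stats::setNames(m$entries$motif, m$entries$symbol)
  decoded <- lut[strsplit(enc, "")[[1]]]
  expect_equal(unname(decoded), subs)
  # symbol rank order equals descending count order
  expect_false(is.unsorted(rev(m$entries$count)))
  expect_equal(m$entries$symbol, symbol_alphabet()[seq_len(nrow(m$entries))])
})

test_that("mapping TSV round-trips and rejects malformed files", {
  dec <- fake_decomposition(c(rep("ACGT", 4), rep("TTGC", 2), "GGC"))
  m <- motif_mapping(dec, threshold = 2)
  expect_equal(nrow(m$private), 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(m, path)
  m2 <- read_mapping(path)
  expect_equal(m2, m)
  # private row flagged with the reserved symbol
  lines <- readLines(path)
  expect_true(any(startsWith(lines, paste0(private_symbol(), "\t"))))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#private_threshold\t1", "symbol\tmotif\tcount",
               "1\tACG\t3", "1\tTTG\t2"), bad)
  expect_error(read_mapping(bad), "line 4: duplicate symbol")
  writeLines(c("#private_threshold\t1", "symbol\tmotif\tcount",
               "1\tACG"), bad)
  expect_error(read_mapping(bad), "line 3")
})
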