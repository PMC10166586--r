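test_that("symbol scores reflect motif similarity", {
  m <- mapping_of_motifs(c("ACCTTG", "ACCTTTG", "TGGAAC"))
  sm <- symbol_score_matrix(m, s_min = 0, s_max = 10)
  sy <- stats::setNames(m$entries$symbol, m$entries$motif)
  expect_equal(sm[sy[["ACCTTG"]], sy[["ACCTTG"]]], 10)          # identity
  expect_equal(sm[sy[["ACCTTG"]], sy[["ACCTTTG"]]], 9)          # ed 1 / len 7
  # completely disjoint motifs of equal length hit the floor
  expect_equal(sm[sy[["ACCTTG"]], sy[["TGGAAC"]]],
               round(10 - 10 * utils::adist("ACCTTG", "TGGAAC")[1] / 6))
  d <- mapping_of_motifs(c("AAAA", "CCCC"))
  sd <- symbol_score_matrix(d, 0, 10)
  expect_equal(sd["1", "2"], 0)
  # symmetry and row maxima on the diagonal
  expect_true(isSymmetric(unclass(sm)[, ]))
  expect_true(all(diag(sm[, ]) == apply(sm[, ], 1, max)))
  # private symbol floors against everything but itself
  expect_true(all(sm[private_symbol(), m$entries$symbol] == 0))
  expect_equal(sm[private_symbol(), private_symbol()], 10)
})

test_that("gap penalties must dominate the worst mismatch", {
  m <- mapping_of_motifs(c("ACG", "TTT"))
  expect_error(symbol_score_matrix(m, s_min = 0, s_max = 10, gap_open = -1),
               "gap")
  expect_error(symbol_score_matrix(m, s_min = 5, s_max = 2), "s_min")
})

test_that("identical sequences align gap-free and singles pass through", {
  m <- mapping_of_motifs(c("ACCTTG", "ACCTTTG"))
  sm <- symbol_score_matrix(m)
  a <- align_encoded(c(p = "112", q = "112", r = "112"), sm)
  expect_equal(unname(a$rows), rep("112", 3))
  expect_equal(a$width, 3L)

  s <- align_encoded(c(only = "1212"), sm)
  expect_equal(unname(s$rows), "1212")
  expect_equal(s$width, 4L)
})

test_that("a two-sequence alignment places one gap in the shorter row", {
  m <- mapping_of_motifs(c("ACCTTG", "ACCTTTG"))
  sm <- symbol_score_matrix(m)
  a <- align_encoded(c(x = "112", y = "12"), sm)
  expect_equal(a$width, 3L)
  expect_equal(a$rows[["x"]], "112")
  expect_true(a$rows[["y"]] %in% c("1-2", "-12"))
  # and the score is the pairwise optimum
  expect_equal(a$score,
               oracle_pairwise_score(c("1", "1", "2"), c("1", "2"), sm,
                                     attr(sm, "gap_open"),
                                     attr(sm, "gap_extend")))
})

test_that("unknown symbols are reported by name", {
  m <- mapping_of_motifs(c("ACG", "TTG"))
  sm <- symbol_score_matrix(m)
  expect_error(align_encoded(c(a = "1Z2"), sm), "Z")
})

test_that("degapping every aligned row reproduces its input", {
  set.seed(77)
  motifs <- c("ACGTGG", "ACGTAG", "TTGACC", "GGGAAA", "ACGTGC")
  m <- mapping_of_motifs(motifs)
  sm <- symbol_score_matrix(m)
  syms <- m$entries$symbol
  for (r in 1:8) {
    n <- sample(2:7, 1)
    enc <- stats::setNames(
      vapply(seq_len(n), function(i)
        paste(sample(syms, sample(3:9, 1), replace = TRUE), collapse = ""), ""),
      paste0("s", seq_len(n)))
    a <- align_encoded(enc, sm)
    expect_equal(degap(a$rows), enc)
    expect_true(all(nchar(a$rows) == a$width))
    expect_gte(a$width, max(nchar(enc)))
    # no all-gap column
    mat <- motifcomp:::.alignment_matrix(a)
    expect_true(all(colSums(mat != "-") > 0))
  }
})

test_that("two-sequence alignments are optimal against a brute-force DP", {
  set.seed(88)
  motifs <- c("ACGTGG", "ACGTAG", "TTGACC", "GGGAAA")
  m <- mapping_of_motifs(motifs)
  sm <- symbol_score_matrix(m)
  go <- attr(sm, "gap_open"); ge <- attr(sm, "gap_extend")
  syms <- c(m$entries$symbol, private_symbol())
  for (r in 1:15) {
    a <- sample(syms, sample(1:8, 1), replace = TRUE)
    b <- sample(syms, sample(1:8, 1), replace = TRUE)
    enc <- c(A = paste(a, collapse = ""), B = paste(b, collapse = ""))
    al <- align_encoded(enc, sm)
    expect_equal(al$score, oracle_pairwise_score(a, b, sm, go, ge),
                 info = paste(enc, collapse = " / "))
    expect_equal(degap(al$rows), enc)
  }
})
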