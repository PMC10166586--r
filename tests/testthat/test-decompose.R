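test_that("a single-motif allele parses into its copies plus a novel motif", {
  d <- decompose_tr("ACCTTGACCTTGACCTTTG", "ACCTTG")
  expect_equal(d$segments$substring, c("ACCTTG", "ACCTTG", "ACCTTTG"))
  expect_equal(d$segments$origin, c("input", "input", "novel"))
  expect_equal(d$total_score, 86)
  expect_equal(d$segments$segment_score, c(30, 30, 26))
  expect_equal(d$segments$is_exact, c(TRUE, TRUE, FALSE))
})

test_that("perfect single and repeated copies decompose exactly", {
  d1 <- decompose_tr("ACG", "ACG")
  expect_equal(nrow(d1$segments), 1L)
  expect_true(d1$segments$is_exact)
  expect_equal(d1$total_score, 15)

  d3 <- decompose_tr("ACGACGACG", "ACG")
  expect_equal(nrow(d3$segments), 3L)
  expect_true(all(d3$segments$is_exact))
  expect_equal(d3$total_score, 45)
})

test_that("DP optimum equals the brute-force partition oracle", {
  set.seed(2024)
  for (r in 1:60) {
    x <- random_dna(sample(1:12, 1))
    motifs <- random_motif_set()
    d <- decompose_tr(x, motifs)
    expect_equal(d$total_score, brute_force_decompose(x, motifs),
                 info = paste(x, paste(motifs, collapse = ",")))
    # partition conservation
    expect_identical(paste(d$segments$substring, collapse = ""), x)
    # per-segment score consistency
    expect_equal(d$segments$segment_score,
                 mapply(segment_score, d$segments$substring,
                        d$segments$aligned_motif, USE.NAMES = FALSE))
    expect_equal(d$total_score, sum(d$segments$segment_score))
  }
})

test_that("perfect tandem repeats are recovered copy for copy", {
  set.seed(7)
  for (len in c(1, 4, 9, 20)) {
    for (k in c(1, 6, 30)) {
      m <- random_dna(len)
      d <- decompose_tr(strrep(m, k), m)
      expect_equal(nrow(d$segments), k)
      expect_true(all(d$segments$is_exact))
      expect_equal(d$total_score, 5 * k * len)
    }
  }
})

test_that("adding a motif never decreases the optimum", {
  set.seed(31)
  for (r in 1:20) {
    x <- random_dna(sample(3:14, 1))
    m1 <- random_motif_set(2, 5)
    extra <- setdiff(random_motif_set(1, 5), m1)
    if (!length(extra)) next
    expect_gte(decompose_tr(x, c(m1, extra))$total_score,
               decompose_tr(x, m1)$total_score)
  }
})

test_that("the optimum scales linearly in the match score on perfect input", {
  for (mt in c(1, 5, 9)) {
    p <- scoring_params(match = mt, mismatch = -4, indel = -4)
    d <- decompose_tr(strrep("ACGT", 6), "ACGT", p)
    expect_equal(d$total_score, mt * 24)
  }
})

test_that("ties prefer the earliest motif and runs are deterministic", {
  d <- decompose_tr("A", c("AG", "AT"))
  expect_equal(d$segments$aligned_motif, "AG")
  d2 <- decompose_tr("A", c("AT", "AG"))
  expect_equal(d2$segments$aligned_motif, "AT")
  # exact beats inexact regardless of motif order
  d3 <- decompose_tr("ACCTTG", c("ACCTTA", "ACCTTG"))
  expect_equal(d3$segments$aligned_motif, "ACCTTG")
  expect_true(d3$segments$is_exact)
  set.seed(5)
  x <- random_dna(14)
  ms <- random_motif_set(3, 4)
  expect_identical(decompose_tr(x, ms), decompose_tr(x, ms))
})

test_that("invalid decomposition inputs are rejected", {
  expect_error(decompose_tr("", "ACG"), "non-empty")
  expect_error(decompose_tr("ACG", character(0)), "at least one motif")
  expect_error(decompose_tr("ACG", c("ACG", "ACG")), "duplicate motifs")
  expect_error(decompose_tr("ACG", "ACNG"), "invalid characters")
})

test_that("batch decomposition preserves order and collects novel motifs", {
  d <- decompose_alleles(c(a = "ACGACG", b = "ACGACG"), "ACG")
  expect_named(d$decompositions, c("a", "b"))
  expect_true(all(vapply(d$decompositions,
                         function(x) nrow(x$segments) == 2L, TRUE)))

  d2 <- decompose_alleles(c(s = "ACCTTGACCTTGACCTTTG"), "ACCTTG")
  expect_equal(d2$motif_set$motif[d2$motif_set$origin == "novel"], "ACCTTTG")

  d0 <- decompose_alleles(stats::setNames(character(0), character(0)), "ACG")
  expect_length(d0$decompositions, 0L)

  expect_error(decompose_alleles(c(a = "ACG", a = "ACG"), "ACG"),
               "duplicate allele ids: a")
})
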