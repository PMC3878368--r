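test_that("the 8 presence patterns map to 8 distinct classes", {
  pats <- expand.grid(f = 0:1, m = 0:1, h = 0:1)
  cls <- classify_fragment(pats$f, pats$m, pats$h)
  expect_setequal(as.character(cls), FRAGMENT_CLASSES)
  expect_equal(length(unique(cls)), 8)
  # pinned anchor patterns
  expect_equal(as.character(classify_fragment(0, 0, 1)), "novel")
  expect_equal(as.character(classify_fragment(1, 1, 0)), "common_loss")
  expect_equal(as.character(classify_fragment(1, 0, 1)), "female_specific")
  expect_error(classify_fragment(2, 0, 1), "must be 0 or 1")
})

test_that("classification is symmetric under swapping parents and labels", {
  swap <- c(common = "common", female_specific = "male_specific",
            male_specific = "female_specific", novel = "novel",
            female_loss = "male_loss", male_loss = "female_loss",
            common_loss = "common_loss", absent_everywhere = "absent_everywhere")
  pats <- expand.grid(f = 0:1, m = 0:1, h = 0:1)
  a <- as.character(classify_fragment(pats$f, pats$m, pats$h))
  b <- as.character(classify_fragment(pats$m, pats$f, pats$h))
  expect_equal(unname(swap[a]), b)
})

test_that("trio summary reproduces the genomic cross-1 reference table", {
  m <- trio_matrix_from_counts(cross_counts("genomic", 1), default_trio)
  s <- summarize_trio(m, default_trio)
  expect_equal(s$hybrid_total, 429)
  expect_equal(s$female_total, 355)
  expect_equal(s$male_total, 321)
  expect_equal(unname(s$percentages),
               c(42.9, 34.0, 22.1, 0.9))
  expect_equal(sum(s$percentages), 100, tolerance = 0.2 / 100)
  lr <- loss_rates(s)
  expect_equal(lr$pct, c(5.1, 10.9))
  expect_equal(lr$fraction, c(18 / 355, 35 / 321))
})

test_that("partition identities hold for every reference cross", {
  for (assay in c("genomic", "cdna")) {
    for (cross in 1:2) {
      ct <- cross_counts(assay, cross)
      s <- summarize_trio_counts(ct)
      expect_equal(s$hybrid_total,
                   sum(ct[c("common", "female_specific", "male_specific", "novel")]))
      expect_equal(s$female_total,
                   sum(ct[c("common", "common_loss", "female_specific", "female_loss")]))
      expect_equal(s$male_total,
                   sum(ct[c("common", "common_loss", "male_specific", "male_loss")]))
      expect_equal(sum(s$counts), s$hybrid_total +
                     sum(ct[c("female_loss", "male_loss", "common_loss")]))
    }
  }
  # cDNA cross 2: identities give 318 / 273 / 238
  s <- summarize_trio_counts(cross_counts("cdna", 2))
  expect_equal(c(s$hybrid_total, s$female_total, s$male_total),
               c(318, 273, 238))
})

test_that("class counts are an exhaustive exclusive partition on random trios", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    calls <- matrix(rbinom(n * 3, 1, runif(1, 0.2, 0.8)), ncol = 3,
                    dimnames = list(sprintf("f%03d", 1:n),
                                    c("female", "male", "hybrid")))
    s <- summarize_trio(fragment_matrix(calls), default_trio)
    expect_equal(sum(s$counts), n)
    cls <- classify_trio(fragment_matrix(calls), default_trio)
    expect_false(anyNA(cls$class))
  }
})

test_that("degenerate summaries are handled explicitly", {
  empty <- fragment_matrix(matrix(integer(0), ncol = 3,
                                  dimnames = list(NULL, c("female", "male", "hybrid"))))
  s <- summarize_trio(empty, default_trio)
  expect_equal(sum(s$counts), 0)
  expect_null(s$percentages)
  expect_error(loss_rates(s), "parental totals")
  # zero female loss gives a 0% rate
  s2 <- summarize_trio_counts(c(common = 10, male_loss = 2))
  expect_equal(loss_rates(s2)$pct[1], 0)
})
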