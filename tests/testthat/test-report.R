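test_that("config precedence is flag over file over default", {
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("threshold: 2.58", "female: P1"), cfgfile)
  cfg <- run_config(female = "mum", config_file = cfgfile)
  expect_equal(cfg$female, "mum")      # flag wins
  expect_equal(cfg$threshold, 2.58)    # file beats default
  expect_equal(cfg$male, "male")       # default survives
  expect_error(run_config(bogus = 1), "unknown config setting")
})

test_that("run_classify writes a reference-shaped summary with provenance", {
  m <- trio_matrix_from_counts(cross_counts("genomic", 1), default_trio)
  dir <- withr::local_tempdir()
  input <- file.path(dir, "aflp.tsv")
  write_fragment_table(m, input)
  out <- run_classify(run_config(input = input, out_dir = dir))
  expect_equal(out$summary$hybrid_total, 429)
  expect_equal(unname(out$summary$percentages), c(42.9, 34.0, 22.1, 0.9))
  expect_equal(out$loss$pct, c(5.1, 10.9))
  lines <- readLines(out$files[2])
  expect_match(lines[1], "^# msaptrio ")
  expect_match(lines[2], "^# config_hash ")
  # per-fragment class file has one row per fragment
  cls <- utils::read.delim(out$files[1], comment.char = "#")
  expect_equal(nrow(cls), 429 + 18 + 35 + 7)
})

test_that("run_classify fails loudly when a role label is missing", {
  m <- trio_matrix_from_counts(cross_counts("genomic", 1), default_trio)
  dir <- withr::local_tempdir()
  input <- file.path(dir, "aflp.tsv")
  write_fragment_table(m, input)
  expect_error(run_classify(run_config(input = input, hybrid = "F1",
                                       out_dir = dir)),
               "F1")
  expect_error(run_classify(run_config(out_dir = dir)), "lacks `input`")
})

test_that("run_msap reports the three U tests of a cross-1-shaped fixture", {
  mc <- reference_methylation_counts()
  mc1 <- mc[mc$cross == 1, ]
  dir <- withr::local_tempdir()
  input <- file.path(dir, "msap.tsv")
  write_msap_table(msap_from_counts(mc1), input)
  out <- run_msap(run_config(input = input,
                             female = mc1$line[1], male = mc1$line[2],
                             hybrid = mc1$line[3], out_dir = dir))
  expect_equal(out$utests$U, c(1.36, 1.31, 0.21))
  expect_false(any(out$utests$significant))
  # degenerate all-type-I fixture reports U as undefined
  allI <- tibble::tibble(line = c("f", "m", "h"),
                         type_I = c(5L, 5L, 5L), type_II = 0L, type_III = 0L)
  input2 <- file.path(dir, "msap2.tsv")
  write_msap_table(msap_from_counts(allI), input2)
  out2 <- run_msap(run_config(input = input2, female = "f", male = "m",
                              hybrid = "h", out_dir = dir))
  expect_true(all(is.na(out2$utests$U)))
})

test_that("rerunning a driver on the same inputs is byte-identical", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  out1 <- run_simulate(run_config(out_dir = dir1, seed = 33))
  out2 <- run_simulate(run_config(out_dir = dir2, seed = 33))
  for (i in seq_along(out1$files)) {
    expect_identical(readLines(out1$files[i]), readLines(out2$files[i]))
  }
  # simulate -> classify at zero noise reproduces ground truth counts
  rec <- reconcile_replicates(out1$aflp$matrix)
  s <- summarize_trio(rec, default_trio)
  expect_equal(unname(s$counts),
               unname(table(out1$aflp$truth$class)[FRAGMENT_CLASSES]),
               ignore_attr = TRUE)
})
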