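test_that("parameter validation rejects infeasible settings", {
  expect_error(trio_sim_params(p_shared = 0.6, p_female_only = 0.3,
                               p_male_only = 0.2), "<= 1")
  expect_error(trio_sim_params(loss_paternal = 1.2), "\\[0, 1\\]")
  expect_error(trio_sim_params(msap_state_probs = c(type_I = 0.5, type_II = 0.5,
                                                    type_III = 0.1, absent = 0)),
               "sum to 1")
  expect_error(trio_sim_params(n_fragments = 0), "positive")
})

test_that("simulation is deterministic under a fixed seed", {
  p <- trio_sim_params(n_fragments = 300, seed = 99)
  a <- simulate_trio_aflp(p); b <- simulate_trio_aflp(p)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$truth, b$truth)
  c <- simulate_trio_aflp(trio_sim_params(n_fragments = 300, seed = 100))
  expect_false(identical(a$matrix$calls, c$matrix$calls))
  m1 <- simulate_trio_msap(p); m2 <- simulate_trio_msap(p)
  expect_identical(m1$matrix$h_calls, m2$matrix$h_calls)
  expect_identical(m1$matrix$m_calls, m2$matrix$m_calls)
})

test_that("a noiseless simulation classifies back to its ground truth exactly", {
  p <- trio_sim_params(n_fragments = 2000, replicate_dropout = 0, seed = 3)
  sim <- simulate_trio_aflp(p)
  rec <- reconcile_replicates(sim$matrix)
  cls <- classify_trio(rec, default_trio)
  expect_identical(as.character(cls$class), as.character(sim$truth$class))
  s <- summarize_trio(rec, default_trio)
  expect_equal(unname(s$counts), unname(table(sim$truth$class)[FRAGMENT_CLASSES]),
               ignore_attr = TRUE)
})

test_that("zero loss and novel rates leave only additive classes", {
  p <- trio_sim_params(n_fragments = 1000, loss_maternal = 0, loss_paternal = 0,
                       loss_common = 0, p_novel = 0, replicate_dropout = 0,
                       seed = 5)
  sim <- simulate_trio_aflp(p)
  s <- summarize_trio(reconcile_replicates(sim$matrix), default_trio)
  lost <- s$counts[c("female_loss", "male_loss", "common_loss", "novel")]
  expect_true(all(lost == 0))
  # hybrid carries exactly the union of transmitted parental bands
  expect_equal(s$hybrid_total,
               sum(s$counts[c("common", "female_specific", "male_specific")]))
})

test_that("replicate dropout only ever removes bands and AND-reconciliation is conservative", {
  p <- trio_sim_params(n_fragments = 800, replicate_dropout = 0.15, seed = 8)
  sim <- simulate_trio_aflp(p)
  rec <- reconcile_replicates(sim$matrix)
  truth_calls <- cbind(sim$truth$F, sim$truth$M, sim$truth$H)
  expect_true(all(rec$calls <= truth_calls))
  expect_true(any(rec$calls < truth_calls))  # at 15% dropout some band vanishes
})

test_that("estimated rates converge to the generating parameters with n", {
  p_target <- 35 / 130
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    sim <- simulate_trio_aflp(trio_sim_params(n_fragments = n, seed = 17))
    s <- summarize_trio(reconcile_replicates(sim$matrix), default_trio)
    est <- s$counts[["male_loss"]] /
      (s$counts[["male_loss"]] + s$counts[["male_specific"]])
    abs(est - p_target)
  }, 0)
  expect_true(err[3] < err[1])
  # at n = 1e5 the estimate sits within 3 binomial standard errors
  n_malonly <- 1e5 * (130 / 520)
  se <- sqrt(p_target * (1 - p_target) / n_malonly)
  expect_lt(err[3], 3 * se)
})

test_that("MSAP simulation respects its state distribution and shift", {
  # degenerate distribution: every site type I, methylation level 0
  p <- trio_sim_params(n_sites = 400,
                       msap_state_probs = c(type_I = 1, type_II = 0,
                                            type_III = 0, absent = 0),
                       demethylation_shift = 0, seed = 2)
  sim <- simulate_trio_msap(p)
  for (s in sim$matrix$samples) {
    sm <- summarize_methylation(sim$matrix, s)
    expect_equal(sm$pct_methylated, 0)
    expect_equal(sm$total_sites, 400)
  }
  # zero shift: hybrid methylation within sampling error of the parents
  p2 <- trio_sim_params(n_sites = 20000, demethylation_shift = 0, seed = 21)
  sim2 <- simulate_trio_msap(p2)
  f <- summarize_methylation(sim2$matrix, "female")
  m <- summarize_methylation(sim2$matrix, "male")
  h <- summarize_methylation(sim2$matrix, "hybrid")
  p_parent <- (f$methylated + m$methylated) / (f$total_sites + m$total_sites)
  se <- sqrt(p_parent * (1 - p_parent) / h$total_sites)
  expect_lt(abs(h$methylated / h$total_sites - p_parent), 4 * se)
})

test_that("parameter recovery flags almost nothing at the 99% level", {
  p <- trio_sim_params(seed = 0)
  n_flagged <- 0; n_checked <- 0
  for (seed in 1:60) {
    p$seed <- seed
    aflp <- simulate_trio_aflp(p)
    msap <- simulate_trio_msap(p)
    s <- summarize_trio(reconcile_replicates(aflp$matrix), default_trio)
    rep <- recover_parameters(aflp_summary = s,
                              msap = list(matrix = msap$matrix, trio = default_trio),
                              p = p)
    n_flagged <- n_flagged + sum(rep$flagged)
    n_checked <- n_checked + nrow(rep)
  }
  # 12 parameters x 60 runs at 99% coverage: expect ~ 7 flags; allow generous
  # binomial slack (5 SD above the mean)
  expect_equal(n_checked, 12 * 60)
  expect_lt(n_flagged, 0.01 * n_checked + 5 * sqrt(0.01 * 0.99 * n_checked))
})

test_that("tiny simulations give wide intervals without spurious flags", {
  p <- trio_sim_params(n_fragments = 10, n_sites = 30, seed = 4)
  aflp <- simulate_trio_aflp(p)
  s <- summarize_trio(reconcile_replicates(aflp$matrix), default_trio)
  rep <- recover_parameters(aflp_summary = s, p = p)
  expect_true(all(rep$upper - rep$lower > 0.2))
  expect_false(any(rep$flagged))
})

test_that("YAML parameter files round trip through read_sim_params", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_fragments: 50", "loss_paternal: 0.25", "seed: 12",
               "msap_state_probs:", "  type_I: 0.5", "  type_II: 0.2",
               "  type_III: 0.2", "  absent: 0.1"), path)
  p <- read_sim_params(path)
  expect_equal(p$n_fragments, 50L)
  expect_equal(p$loss_paternal, 0.25)
  expect_equal(unname(p$msap_state_probs), c(0.5, 0.2, 0.2, 0.1))
  expect_equal(p$p_shared, 191 / 520)  # defaults fill the rest
})
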