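#' Parameters for the synthetic trio generator
#'
#' Encodes the generative model the trio analysis assumes. Each marker
#' locus falls into one of four parental categories — band in both
#' parents (`p_shared`), female only (`p_female_only`), male only
#' (`p_male_only`), or neither (the remainder) — and the hybrid then
#' inherits or loses the band by an independent Bernoulli draw per
#' fragment: a shared band fails to transmit with probability
#' `loss_common`, a female-only band with `loss_maternal`, a male-only
#' band with `loss_paternal`, and a band absent from both parents
#' appears de novo with probability `p_novel`. The loss parameters are
#' *conditional* per-fragment probabilities (given the parental
#' category), the natural Bernoulli rates of the model; the familiar
#' reported loss rates (lost bands over a parent's total bands) are
#' derived quantities recovered by [loss_rates()].
#'
#' For MSAP sites, each parent's state at each of `n_sites` CCGG sites
#' is drawn from `msap_state_probs`; the hybrid inherits the state of
#' a uniformly chosen parent, and an inherited methylated state (type
#' II or III) reverts to non-methylated type I with probability
#' `demethylation_shift` — the hypomethylation pulse wide hybridization
#' is known to trigger.
#'
#' Defaults are calibrated to the genomic fingerprints of cross 1 of
#' [reference_fragment_counts()] and [reference_methylation_counts()]
#' (e.g. `loss_paternal = 35/130` of male-only bands, which yields the
#' familiar ~10.9% reported paternal loss; parental methylation near
#' 52.5% with a shift to ~48.5% in the hybrid). `replicate_dropout`
#' (probability that a true band fails to amplify in one replicate
#' lane) defaults to 0: reference matrices are already
#' reproducibility-filtered, so noisy lanes are opt-in for exercising
#' [reconcile_replicates()].
#'
#' @param n_fragments Number of marker loci to simulate.
#' @param p_shared,p_female_only,p_male_only Parental category
#'   probabilities; must sum to at most 1.
#' @param loss_maternal,loss_paternal,loss_common Conditional
#'   non-transmission probabilities.
#' @param p_novel Conditional probability a parent-absent locus bands
#'   in the hybrid.
#' @param n_sites Number of CCGG sites for MSAP simulation.
#' @param msap_state_probs Named probabilities over
#'   `c(type_I, type_II, type_III, absent)`; must sum to 1.
#' @param demethylation_shift Probability an inherited methylated site
#'   reverts to type I in the hybrid.
#' @param replicate_dropout Per-lane band dropout probability.
#' @param seed Integer RNG seed; every draw of a simulation run flows
#'   from it.
#' @return A `trio_sim_params` list.
#' @export
trio_sim_params <- function(n_fragments = 520,
                            p_shared = 191 / 520,
                            p_female_only = 164 / 520,
                            p_male_only = 130 / 520,
                            loss_maternal = 18 / 164,
                            loss_paternal = 35 / 130,
                            loss_common = 7 / 191,
                            p_novel = 4 / 35,
                            n_sites = 600,
                            msap_state_probs = c(type_I = 0.456,
                                                 type_II = 0.284,
                                                 type_III = 0.220,
                                                 absent = 0.040),
                            demethylation_shift = 0.076,
                            replicate_dropout = 0,
                            seed = 1L) {
  probs <- c(p_shared, p_female_only, p_male_only, loss_maternal,
             loss_paternal, loss_common, p_novel, demethylation_shift,
             replicate_dropout, msap_state_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_shared + p_female_only + p_male_only > 1 + 1e-12) {
    stop("p_shared + p_female_only + p_male_only must be <= 1", call. = FALSE)
  }
  if (!setequal(names(msap_state_probs),
                c("type_I", "type_II", "type_III", "absent")) ||
      abs(sum(msap_state_probs) - 1) > 1e-9) {
    stop("msap_state_probs must be named over the four site states and sum to 1",
         call. = FALSE)
  }
  if (n_fragments < 1 || n_sites < 1) {
    stop("n_fragments and n_sites must be positive", call. = FALSE)
  }
  structure(list(n_fragments = as.integer(n_fragments),
                 p_shared = p_shared, p_female_only = p_female_only,
                 p_male_only = p_male_only,
                 loss_maternal = loss_maternal,
                 loss_paternal = loss_paternal,
                 loss_common = loss_common,
                 p_novel = p_novel,
                 n_sites = as.integer(n_sites),
                 msap_state_probs = msap_state_probs[c("type_I", "type_II",
                                                       "type_III", "absent")],
                 demethylation_shift = demethylation_shift,
                 replicate_dropout = replicate_dropout,
                 seed = as.integer(seed)),
            class = "trio_sim_params")
}

#' Read generator parameters from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [trio_sim_params()]; `msap_state_probs` is a mapping over the four
#'   state names. Omitted keys take the calibrated defaults.
#' @return A `trio_sim_params`.
#' @export
read_sim_params <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$msap_state_probs)) {
    vals$msap_state_probs <- unlist(vals$msap_state_probs)
  }
  do.call(trio_sim_params, vals)
}

aflp_primer_combos <- c("E2+M5", "E2+M6", "E3+M2", "E4+M3", "E4+M8",
                        "E6+M7", "E7+M3", "E8+M3", "E8+M7")

#' Simulate AFLP fingerprints for a parent-parent-hybrid trio
#'
#' Draws parental categories and hybrid transmission per locus under
#' the model of [trio_sim_params()], then emits two replicate lanes per
#' sample with independent per-lane band dropout. Fragment sizes are
#' drawn uniformly on 100-500 bp and primer combinations uniformly
#' over nine standard pairs, so the size filter is the identity on
#' simulated data.
#'
#' @param p A `trio_sim_params`.
#' @param trio A [trio_spec] giving the sample labels.
#' @return A list with elements `matrix` (a [fragment_matrix] with
#'   lanes `<sample>__r1`, `<sample>__r2`), `truth` (tibble of
#'   per-fragment true states and class) and `params`.
#' @export
simulate_trio_aflp <- function(p, trio = trio_spec("female", "male", "hybrid")) {
  stopifnot(inherits(p, "trio_sim_params"))
  set.seed(p$seed)
  n <- p$n_fragments
  category <- sample(c("shared", "female_only", "male_only", "neither"),
                     n, replace = TRUE,
                     prob = c(p$p_shared, p$p_female_only, p$p_male_only,
                              1 - p$p_shared - p$p_female_only - p$p_male_only))
  f <- as.integer(category %in% c("shared", "female_only"))
  m <- as.integer(category %in% c("shared", "male_only"))
  keep_prob <- c(shared = 1 - p$loss_common,
                 female_only = 1 - p$loss_maternal,
                 male_only = 1 - p$loss_paternal,
                 neither = p$p_novel)
  h <- as.integer(stats::runif(n) < keep_prob[category])
  truth <- tibble::tibble(fragment_id = sprintf("frag_%05d", seq_len(n)),
                          category = category,
                          F = f, M = m, H = h,
                          class = classify_fragment(f, m, h))
  lanes <- lapply(list(f, f, m, m, h, h), function(true) {
    dropped <- stats::rbinom(n, 1, p$replicate_dropout)
    as.integer(true & !dropped)
  })
  calls <- do.call(cbind, lanes)
  lane_names <- as.vector(t(outer(c(trio$female, trio$male, trio$hybrid),
                                  c("__r1", "__r2"), paste0)))
  dimnames(calls) <- list(truth$fragment_id, lane_names)
  fragments <- tibble::tibble(
    fragment_id = truth$fragment_id,
    primer_combo = sample(aflp_primer_combos, n, replace = TRUE),
    size_bp = sample(100:500, n, replace = TRUE))
  replicate_of <- stats::setNames(
    rep(c(trio$female, trio$male, trio$hybrid), each = 2), lane_names)
  list(matrix = fragment_matrix(calls, fragments, replicate_of),
       truth = truth, params = p)
}

#' Simulate MSAP lane profiles for a trio
#'
#' Each parent's methylation state per CCGG site is an independent
#' draw from `msap_state_probs`; the hybrid inherits the state of a
#' uniformly chosen parent and reverts inherited methylated states to
#' type I with probability `demethylation_shift`. H/M lane bits follow
#' the [classify_site()] bijection.
#'
#' @inheritParams simulate_trio_aflp
#' @return A list with elements `matrix` (an [msap_matrix]), `truth`
#'   (per-site states) and `params`.
#' @export
simulate_trio_msap <- function(p, trio = trio_spec("female", "male", "hybrid")) {
  stopifnot(inherits(p, "trio_sim_params"))
  set.seed(p$seed)
  n <- p$n_sites
  states <- names(p$msap_state_probs)
  f_state <- sample(states, n, replace = TRUE, prob = p$msap_state_probs)
  m_state <- sample(states, n, replace = TRUE, prob = p$msap_state_probs)
  donor_is_f <- stats::runif(n) < 0.5
  h_state <- ifelse(donor_is_f, f_state, m_state)
  revert <- h_state %in% c("type_II", "type_III") &
    stats::runif(n) < p$demethylation_shift
  h_state[revert] <- "type_I"
  to_lanes <- function(state) {
    cbind(h = as.integer(state %in% c("type_I", "type_III")),
          m = as.integer(state %in% c("type_I", "type_II")))
  }
  fl <- to_lanes(f_state); ml <- to_lanes(m_state); hl <- to_lanes(h_state)
  ids <- sprintf("site_%05d", seq_len(n))
  samples <- c(trio$female, trio$male, trio$hybrid)
  h_calls <- cbind(fl[, "h"], ml[, "h"], hl[, "h"])
  m_calls <- cbind(fl[, "m"], ml[, "m"], hl[, "m"])
  dimnames(h_calls) <- dimnames(m_calls) <- list(ids, samples)
  truth <- tibble::tibble(site_id = ids,
                          female_state = f_state, male_state = m_state,
                          hybrid_state = h_state,
                          donor = ifelse(donor_is_f, "female", "male"),
                          demethylated = revert)
  list(matrix = msap_matrix(h_calls, m_calls), truth = truth, params = p)
}

#' Recover generator parameters from truth-free pipeline output
#'
#' Re-estimates every rate of the generative model from the analysed
#' data alone — classification counts for the AFLP layer, lane-pattern
#' tallies for the MSAP layer — and checks each estimate against its
#' exact binomial confidence interval around the true parameter. With
#' noiseless replicates the estimators are the conditional-binomial
#' MLEs, so at confidence `conf` roughly `(1 - conf)` of estimates are
#' flagged by chance alone. The `demethylation_shift` interval is
#' approximate (a transformed interval for the hybrid methylation
#' proportion, treating the parental level as known).
#'
#' @param aflp_summary A `trio_summary` from the reconciled simulated
#'   AFLP matrix (pass `NULL` to skip the AFLP layer).
#' @param msap An analysed [msap_matrix] plus its [trio_spec], as
#'   `list(matrix = , trio = )` (or `NULL` to skip).
#' @param p The `trio_sim_params` used to generate the data.
#' @param conf Confidence level for the checks (default 0.99).
#' @return A tibble with one row per parameter: `parameter`, `truth`,
#'   `estimate`, `x`, `n`, `lower`, `upper`, `flagged`.
#' @export
recover_parameters <- function(aflp_summary = NULL, msap = NULL, p, conf = 0.99) {
  stopifnot(inherits(p, "trio_sim_params"))
  rows <- list()
  ci_row <- function(parameter, truth, x, n) {
    ci <- stats::binom.test(round(x), round(n), conf.level = conf)$conf.int
    tibble::tibble(parameter = parameter, truth = truth,
                   estimate = x / n, x = x, n = n,
                   lower = ci[1], upper = ci[2],
                   flagged = truth < ci[1] | truth > ci[2])
  }
  if (!is.null(aflp_summary)) {
    stopifnot(inherits(aflp_summary, "trio_summary"))
    ct <- aflp_summary$counts
    n <- p$n_fragments
    shared <- ct[["common"]] + ct[["common_loss"]]
    f_only <- ct[["female_specific"]] + ct[["female_loss"]]
    m_only <- ct[["male_specific"]] + ct[["male_loss"]]
    neither <- n - shared - f_only - m_only
    rows <- c(rows, list(
      ci_row("p_shared", p$p_shared, shared, n),
      ci_row("p_female_only", p$p_female_only, f_only, n),
      ci_row("p_male_only", p$p_male_only, m_only, n),
      ci_row("loss_common", p$loss_common, ct[["common_loss"]], shared),
      ci_row("loss_maternal", p$loss_maternal, ct[["female_loss"]], f_only),
      ci_row("loss_paternal", p$loss_paternal, ct[["male_loss"]], m_only),
      ci_row("p_novel", p$p_novel, ct[["novel"]], neither)))
  }
  if (!is.null(msap)) {
    mm <- msap$matrix
    trio <- msap$trio
    parents <- c(trio$female, trio$male)
    pat <- unlist(lapply(parents, function(s) {
      as.character(classify_site(mm$h_calls[, s], mm$m_calls[, s]))
    }))
    n2 <- length(pat)
    for (st in names(p$msap_state_probs)) {
      rows <- c(rows, list(ci_row(paste0("msap_", st),
                                  p$msap_state_probs[[st]],
                                  sum(pat == st), n2)))
    }
    f <- summarize_methylation(mm, trio$female)
    m2 <- summarize_methylation(mm, trio$male)
    h <- summarize_methylation(mm, trio$hybrid)
    parent_meth <- (f$methylated + m2$methylated) / (f$total_sites + m2$total_sites)
    ci_h <- stats::binom.test(h$methylated, h$total_sites,
                              conf.level = conf)$conf.int
    est <- 1 - (h$methylated / h$total_sites) / parent_meth
    lo <- 1 - ci_h[2] / parent_meth
    hi <- 1 - ci_h[1] / parent_meth
    rows <- c(rows, list(tibble::tibble(
      parameter = "demethylation_shift", truth = p$demethylation_shift,
      estimate = est, x = h$methylated, n = h$total_sites,
      lower = lo, upper = hi,
      flagged = p$demethylation_shift < lo | p$demethylation_shift > hi)))
  }
  do.call(rbind, rows)
}
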