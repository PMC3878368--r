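#' Run configuration for the reporting drivers
#'
#' Collects everything a pipeline run needs: input paths, trio role
#' labels, the size window, the U-test threshold, rounding precision,
#' output directory and seed. Values given here override those read
#' from a YAML config file, which override the defaults (flag > file >
#' default). Every output file written by the `run_*` drivers carries a
#' provenance header (package version, a hash of the effective config,
#' the seed), so re-running with identical inputs is byte-identical.
#'
#' @param ... Named settings; recognised names are `input`, `female`,
#'   `male`, `hybrid`, `size_min`, `size_max`, `threshold`, `digits`,
#'   `out_dir`, `seed`, `params` (a YAML path for [run_simulate()]).
#' @param config_file Optional YAML file of the same settings.
#' @return A `run_config` list of the effective settings.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- list(input = NULL, female = "female", male = "male",
                   hybrid = "hybrid", size_min = NULL, size_max = NULL,
                   threshold = 1.96, digits = 1, out_dir = ".",
                   seed = 1L, params = NULL)
  from_file <- if (!is.null(config_file)) yaml::read_yaml(config_file) else list()
  flags <- list(...)
  unknown <- setdiff(c(names(flags), names(from_file)), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), flags)
  structure(cfg, class = "run_config")
}

provenance_header <- function(cfg, seed = NULL) {
  # out_dir is excluded: where results land must not change what they say
  keep <- cfg[!vapply(cfg, is.null, logical(1))]
  keep <- keep[setdiff(names(keep), "out_dir")]
  desc <- paste(names(keep), vapply(keep, paste, character(1), collapse = ","),
                sep = "=", collapse = ";")
  codes <- utf8ToInt(desc)
  hash <- sum(codes * (seq_along(codes) %% 97 + 1)) %% 1e9
  c(sprintf("msaptrio %s", as.character(utils::packageVersion("msaptrio"))),
    sprintf("config_hash %d", hash),
    sprintf("seed %s", if (is.null(seed)) cfg$seed else seed))
}

resolve_trio <- function(cfg, samples) {
  trio <- trio_spec(cfg$female, cfg$male, cfg$hybrid)
  check_trio_in(trio, samples)
  trio
}

#' Classify a fingerprint table and write trio reports
#'
#' Reads a band-score TSV, collapses replicates, optionally applies the
#' size window, classifies every fragment of the configured trio and
#' writes two TSVs to `out_dir`: `classes.tsv` (per-fragment F/M/H bits
#' and class) and `summary.tsv` (class counts, hybrid percentages,
#' totals and parental loss rates).
#'
#' @param cfg A [run_config] with at least `input`, `female`, `male`,
#'   `hybrid`.
#' @return Invisibly, a list with the `summary` (a `trio_summary`),
#'   `classes` tibble, `loss` tibble and output `files`.
#' @export
run_classify <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$input)) stop("config lacks `input`", call. = FALSE)
  m <- read_fragment_table(cfg$input)
  m <- reconcile_replicates(m)
  if (!is.null(cfg$size_min) || !is.null(cfg$size_max)) {
    m <- filter_by_size(m, cfg$size_min %||% 0, cfg$size_max %||% Inf)
  }
  trio <- resolve_trio(cfg, colnames(m$calls))
  classes <- classify_trio(m, trio)
  s <- summarize_trio(m, trio)
  loss <- loss_rates(s)
  hdr <- provenance_header(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  f_classes <- file.path(cfg$out_dir, "classes.tsv")
  f_summary <- file.path(cfg$out_dir, "summary.tsv")
  write_tsv_file(as.data.frame(classes), f_classes, hdr)
  summary_df <- as.data.frame(as_tibble.trio_summary(s))
  summary_df$total <- c(rep(NA, length(FRAGMENT_CLASSES)))
  totals <- data.frame(class = c("hybrid_total", "female_total", "male_total",
                                 "female_loss_pct", "male_loss_pct"),
                       count = c(s$hybrid_total, s$female_total, s$male_total,
                                 NA, NA),
                       pct_of_hybrid = NA,
                       total = c(NA, NA, NA, loss$pct))
  write_tsv_file(rbind(summary_df, totals), f_summary, hdr)
  invisible(list(summary = s, classes = classes, loss = loss,
                 files = c(f_classes, f_summary)))
}

#' Summarise an MSAP table and run the mid-parent U tests
#'
#' Reads a paired-lane MSAP TSV, types every site of each trio member,
#' builds the mid-parent expectation and writes two TSVs to `out_dir`:
#' `methylation.tsv` (the per-line methylation-level table) and
#' `utests.tsv` (total / full / hemi U tests at the configured
#' threshold). A degenerate test (pooled proportion 0 or 1) is reported
#' with an empty `U` cell and `significant = NA`.
#'
#' @param cfg A [run_config] with at least `input`, `female`, `male`,
#'   `hybrid`.
#' @return Invisibly, a list with `table` (methylation tibble),
#'   `utests` tibble and output `files`.
#' @export
run_msap <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$input)) stop("config lacks `input`", call. = FALSE)
  m <- read_msap_table(cfg$input)
  trio <- resolve_trio(cfg, m$samples)
  tab <- methylation_table(m, trio)
  mpv <- mid_parent(summarize_methylation(m, trio$female),
                    summarize_methylation(m, trio$male))
  res <- compare_hybrid_to_mpv(mpv, summarize_methylation(m, trio$hybrid),
                               threshold = cfg$threshold)
  ut <- u_test_table(res)
  hdr <- provenance_header(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  f_tab <- file.path(cfg$out_dir, "methylation.tsv")
  f_ut <- file.path(cfg$out_dir, "utests.tsv")
  write_tsv_file(as.data.frame(tab), f_tab, hdr)
  write_tsv_file(as.data.frame(ut), f_ut, hdr)
  invisible(list(table = tab, utests = ut, results = res,
                 files = c(f_tab, f_ut)))
}

#' Simulate a trio and write matrices plus ground truth
#'
#' Generates AFLP and MSAP matrices under [trio_sim_params()] (read
#' from `cfg$params` YAML when given, otherwise the calibrated
#' defaults, with `cfg$seed` overriding the parameter seed) and writes
#' `aflp.tsv`, `msap.tsv`, `aflp_truth.tsv` and `msap_truth.tsv` to
#' `out_dir`, each with the provenance header.
#'
#' @param cfg A [run_config]; relevant settings are `params`, `seed`,
#'   `out_dir`, `female`, `male`, `hybrid`.
#' @return Invisibly, a list with both simulations and output `files`.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  p <- if (!is.null(cfg$params)) read_sim_params(cfg$params) else trio_sim_params()
  if (!is.null(cfg$seed)) {
    p$seed <- as.integer(cfg$seed)
  }
  trio <- trio_spec(cfg$female, cfg$male, cfg$hybrid)
  aflp <- simulate_trio_aflp(p, trio)
  msap <- simulate_trio_msap(p, trio)
  hdr <- provenance_header(cfg, seed = p$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(cfg$out_dir,
                     c("aflp.tsv", "msap.tsv", "aflp_truth.tsv", "msap_truth.tsv"))
  write_fragment_table(aflp$matrix, files[1], hdr)
  write_msap_table(msap$matrix, files[2], hdr)
  truth_a <- aflp$truth
  truth_a$class <- as.character(truth_a$class)
  write_tsv_file(as.data.frame(truth_a), files[3], hdr)
  write_tsv_file(as.data.frame(msap$truth), files[4], hdr)
  invisible(list(aflp = aflp, msap = msap, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
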