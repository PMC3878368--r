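#' Classify the methylation state of a CCGG site
#'
#' HpaII cuts CCGG only when the site is unmethylated on both strands;
#' MspI also cuts when the internal cytosine is methylated. Comparing
#' the two lanes therefore types each site:
#'
#' | (H, M) | pattern | meaning |
#' |--------|---------|---------|
#' | 1, 1 | `type_I`   | non-methylated (band in both lanes) |
#' | 0, 1 | `type_II`  | fully methylated (M lane only) |
#' | 1, 0 | `type_III` | hemi-methylated (H lane only) |
#' | 0, 0 | `absent`   | no band in either lane |
#'
#' A double-absent site is indistinguishable from a site hypermethylated
#' beyond the reach of both enzymes; it is reported as `absent` and
#' excluded from methylation denominators.
#'
#' @param h,m HpaII-lane and MspI-lane presence bits (0/1). Vectorised.
#' @return A factor with levels `type_I`, `type_II`, `type_III`,
#'   `absent`.
#' @export
classify_site <- function(h, m) {
  bits <- c(h, m)
  if (any(!(bits %in% c(0, 1))) || anyNA(bits)) {
    stop("lane calls must be 0 or 1", call. = FALSE)
  }
  lut <- c("absent", "type_II", "type_III", "type_I")  # index H*2 + M
  factor(lut[h * 2L + m + 1L],
         levels = c("type_I", "type_II", "type_III", "absent"))
}

#' Per-sample methylation summary
#'
#' Types every site of one sample with [classify_site()] and tallies
#' the three band-producing patterns. Sites absent in this sample are
#' excluded from its denominator, so per-sample totals legitimately
#' differ across samples. `methylated = type_II + type_III`;
#' percentages are of `total_sites`, rounded half-up to one decimal.
#'
#' @param m An [msap_matrix].
#' @param sample A sample label present in `m`.
#' @return A `methylation_summary` list: `sample`, `total_sites`,
#'   `type_I`, `type_II`, `type_III`, `methylated`, and `pct_I`,
#'   `pct_II`, `pct_III`, `pct_methylated`.
#' @export
summarize_methylation <- function(m, sample) {
  stopifnot(inherits(m, "msap_matrix"))
  if (!sample %in% m$samples) {
    stop("sample `", sample, "` not found in MSAP matrix", call. = FALSE)
  }
  cls <- classify_site(m$h_calls[, sample], m$m_calls[, sample])
  counts <- table(cls)
  methylation_summary(type_I = counts[["type_I"]],
                      type_II = counts[["type_II"]],
                      type_III = counts[["type_III"]],
                      sample = sample)
}

#' Build a methylation summary directly from type counts
#'
#' @param type_I,type_II,type_III Non-negative site counts.
#' @param sample Sample label.
#' @return A `methylation_summary`; errors if all counts are zero.
#' @export
methylation_summary <- function(type_I, type_II, type_III, sample = NA_character_) {
  total <- type_I + type_II + type_III
  if (total == 0) {
    stop("sample `", sample, "` has no scorable sites (all absent)",
         call. = FALSE)
  }
  meth <- type_II + type_III
  structure(list(sample = sample,
                 total_sites = total,
                 type_I = type_I, type_II = type_II, type_III = type_III,
                 methylated = meth,
                 pct_I = round_half_up(100 * type_I / total, 1),
                 pct_II = round_half_up(100 * type_II / total, 1),
                 pct_III = round_half_up(100 * type_III / total, 1),
                 pct_methylated = round_half_up(100 * meth / total, 1)),
            class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf("<methylation_summary> %s: %d sites | I %d (%.1f%%) | methylated %d (%.1f%%) = II %d (%.1f%%) + III %d (%.1f%%)\n",
              x$sample, x$total_sites, x$type_I, x$pct_I,
              x$methylated, x$pct_methylated,
              x$type_II, x$pct_II, x$type_III, x$pct_III))
  invisible(x)
}

#' Mid-parent methylation expectation
#'
#' The null expectation for an additive hybrid is the mid-parent value
#' (MPV): the arithmetic mean of the two parents' *raw site counts*
#' (not of their percentages), taken class by class. Counts may
#' therefore be half-integral. Percentages are each mean count over the
#' mean total, half-up to one decimal.
#'
#' @param f,m `methylation_summary` objects for the female and male
#'   parent. The operation is symmetric in its arguments.
#' @return A `mid_parent_value` list: `n1` (mean total sites),
#'   `y1_total`, `y1_full`, `y1_hemi`, `y1_I` (mean counts) and the
#'   corresponding `pct_*` fields.
#' @export
mid_parent <- function(f, m) {
  stopifnot(inherits(f, "methylation_summary"),
            inherits(m, "methylation_summary"))
  n1 <- (f$total_sites + m$total_sites) / 2
  y1_total <- (f$methylated + m$methylated) / 2
  y1_full <- (f$type_II + m$type_II) / 2
  y1_hemi <- (f$type_III + m$type_III) / 2
  y1_I <- (f$type_I + m$type_I) / 2
  structure(list(n1 = n1,
                 y1_total = y1_total, y1_full = y1_full,
                 y1_hemi = y1_hemi, y1_I = y1_I,
                 pct_I = round_half_up(100 * y1_I / n1, 1),
                 pct_methylated = round_half_up(100 * y1_total / n1, 1),
                 pct_full = round_half_up(100 * y1_full / n1, 1),
                 pct_hemi = round_half_up(100 * y1_hemi / n1, 1),
                 parents = c(f$sample, m$sample)),
            class = "mid_parent_value")
}

#' @export
print.mid_parent_value <- function(x, ...) {
  cat(sprintf("<mid_parent_value> of %s + %s: n1 %.1f | I %.1f%% | methylated %.1f%% = full %.1f%% + hemi %.1f%%\n",
              x$parents[1], x$parents[2], x$n1, x$pct_I,
              x$pct_methylated, x$pct_full, x$pct_hemi))
  invisible(x)
}

#' Tabulate methylation summaries of a trio
#'
#' Produces the standard per-line methylation-level table: one row per
#' parent, the mid-parent expectation, then the hybrid, each with total
#' sites, non-methylated and methylated counts and percentages.
#'
#' @param m An [msap_matrix].
#' @param trio A [trio_spec].
#' @return A tibble with columns `line`, `total_sites`, `type_I`,
#'   `pct_I`, `methylated`, `pct_methylated`, `type_II`, `pct_II`,
#'   `type_III`, `pct_III`.
#' @export
methylation_table <- function(m, trio) {
  stopifnot(inherits(trio, "trio_spec"))
  check_trio_in(trio, m$samples)
  f <- summarize_methylation(m, trio$female)
  ma <- summarize_methylation(m, trio$male)
  h <- summarize_methylation(m, trio$hybrid)
  mpv <- mid_parent(f, ma)
  row <- function(s, line) {
    tibble::tibble(line = line, total_sites = s$total_sites,
                   type_I = s$type_I, pct_I = s$pct_I,
                   methylated = s$methylated, pct_methylated = s$pct_methylated,
                   type_II = s$type_II, pct_II = s$pct_II,
                   type_III = s$type_III, pct_III = s$pct_III)
  }
  mpv_row <- tibble::tibble(line = "mid-parent", total_sites = mpv$n1,
                            type_I = mpv$y1_I, pct_I = mpv$pct_I,
                            methylated = mpv$y1_total,
                            pct_methylated = mpv$pct_methylated,
                            type_II = mpv$y1_full, pct_II = mpv$pct_full,
                            type_III = mpv$y1_hemi, pct_III = mpv$pct_hemi)
  out <- rbind(row(f, trio$female), row(ma, trio$male), mpv_row,
               row(h, trio$hybrid))
  tibble::as_tibble(out)
}
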