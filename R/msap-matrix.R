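#' Construct an MSAP lane-pair matrix
#'
#' MSAP (methylation-sensitive amplification polymorphism) profiles each
#' CCGG site twice: once after an EcoRI + HpaII digest (the H lane) and
#' once after EcoRI + MspI (the M lane). HpaII and MspI are
#' isoschizomers that cut the same CCGG target but differ in
#' methylation sensitivity, so the pair of band calls per site encodes
#' its cytosine-methylation state (see [classify_site()]).
#'
#' @param h_calls,m_calls Integer matrices over \{0, 1\} of identical
#'   shape: sites x samples, with matching dimnames. `h_calls` holds
#'   the HpaII-lane scores, `m_calls` the MspI-lane scores.
#' @param sites Optional data frame of site metadata
#'   (`fragment_id`, `primer_combo`, `size_bp`), as in
#'   [fragment_matrix()].
#' @return An object of class `msap_matrix`.
#' @export
msap_matrix <- function(h_calls, m_calls, sites = NULL) {
  h <- fragment_matrix(h_calls, sites)
  m <- fragment_matrix(m_calls, sites)
  if (!identical(dim(h$calls), dim(m$calls)) ||
      !identical(dimnames(h$calls), dimnames(m$calls))) {
    stop("h_calls and m_calls must have identical shape and dimnames",
         call. = FALSE)
  }
  structure(
    list(h_calls = h$calls, m_calls = m$calls,
         sites = h$fragments, samples = colnames(h$calls)),
    class = "msap_matrix")
}

#' @export
print.msap_matrix <- function(x, ...) {
  cat(sprintf("<msap_matrix> %d CCGG sites x %d samples (H + M lanes)\n",
              nrow(x$h_calls), length(x$samples)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Read an MSAP table from TSV
#'
#' Dialect as in [read_fragment_table()], except that every sample
#' contributes a pair of call columns named `"<sample>__H"` and
#' `"<sample>__M"` for its HpaII and MspI lanes. An H column without an
#' M partner (or vice versa) is an error.
#'
#' @inheritParams read_fragment_table
#' @return An [msap_matrix].
#' @export
read_msap_table <- function(path, missing_code = NULL) {
  raw <- read_tsv_chr(path)
  if (names(raw)[1] != "fragment_id") {
    stop("first column must be `fragment_id`, got `", names(raw)[1], "`",
         call. = FALSE)
  }
  lane_cols <- setdiff(names(raw), meta_cols)
  paired <- grepl("__[HM]$", lane_cols)
  lane <- ifelse(paired, sub("^.*__", "", lane_cols), "")
  sample <- sub("__[HM]$", "", lane_cols)
  if (!all(lane %in% c("H", "M"))) {
    stop("lane columns must end in `__H` or `__M`; offending column: ",
         lane_cols[!lane %in% c("H", "M")][1], call. = FALSE)
  }
  samples <- unique(sample)
  for (s in samples) {
    have <- lane[sample == s]
    if (!setequal(have, c("H", "M"))) {
      stop("sample `", s, "` lacks its ",
           if ("H" %in% have) "M" else "H", " lane partner column",
           call. = FALSE)
    }
  }
  calls <- parse_calls(raw, lane_cols, missing_code, path)
  rownames(calls) <- raw$fragment_id
  sites <- tibble::tibble(
    fragment_id = raw$fragment_id,
    primer_combo = if ("primer_combo" %in% names(raw)) raw$primer_combo else NA_character_,
    size_bp = if ("size_bp" %in% names(raw))
      as.integer(replace(raw$size_bp, raw$size_bp == "", NA)) else NA_integer_)
  h <- calls[, paste0(samples, "__H"), drop = FALSE]
  m <- calls[, paste0(samples, "__M"), drop = FALSE]
  colnames(h) <- colnames(m) <- samples
  msap_matrix(h, m, sites)
}

#' Write an MSAP table to TSV
#'
#' Inverse of [read_msap_table()]; round trips preserve both lane
#' matrices bit-exactly.
#'
#' @param m An [msap_matrix].
#' @inheritParams write_fragment_table
#' @return `path`, invisibly.
#' @export
write_msap_table <- function(m, path, header = NULL) {
  df <- data.frame(fragment_id = m$sites$fragment_id,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (any(!is.na(m$sites$primer_combo))) df$primer_combo <- m$sites$primer_combo
  if (any(!is.na(m$sites$size_bp))) df$size_bp <- m$sites$size_bp
  for (s in m$samples) {
    df[[paste0(s, "__H")]] <- m$h_calls[, s]
    df[[paste0(s, "__M")]] <- m$m_calls[, s]
  }
  write_tsv_file(df, path, header)
  invisible(path)
}
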