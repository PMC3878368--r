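#' Construct a fragment presence/absence matrix
#'
#' A `fragment_matrix` holds dominant-marker band scores: one row per
#' fragment (an AFLP, cDNA-AFLP or MSAP-derived band, identified by its
#' primer combination and, optionally, its size in base pairs) and one
#' column per sample lane, with cells coded 1 (band present) and 0
#' (band absent). Columns may be technical replicates of the same
#' biological sample; the `replicate_of` map records which.
#'
#' @param calls Integer matrix over \{0, 1\}; rows are fragments, columns
#'   are sample lanes. Row and column names are required.
#' @param fragments Data frame of fragment metadata with columns
#'   `fragment_id` (matching `rownames(calls)`), and optionally
#'   `primer_combo` and `size_bp`.
#' @param replicate_of Named character vector mapping each column label
#'   to its biological sample. Defaults to the identity map (every
#'   column its own sample).
#'
#' @return An object of class `fragment_matrix`.
#' @export
fragment_matrix <- function(calls, fragments = NULL, replicate_of = NULL) {
  calls <- as.matrix(calls)
  rn <- rownames(calls)
  if (is.null(rn) && nrow(calls) == 0) rn <- character(0)
  if (is.null(rn) || is.null(colnames(calls))) {
    stop("`calls` must have row names (fragment ids) and column names (lanes)",
         call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  bad <- which(!(calls %in% c(0L, 1L)), arr.ind = FALSE)
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(calls))
    stop(sprintf("call matrix cell [%s, %s] is not 0/1",
                 rownames(calls)[ij[1]], colnames(calls)[ij[2]]),
         call. = FALSE)
  }
  if (anyDuplicated(rn)) {
    stop("duplicate fragment_id: ", rn[duplicated(rn)][1], call. = FALSE)
  }
  if (is.null(fragments)) {
    fragments <- tibble::tibble(fragment_id = rn,
                                primer_combo = NA_character_,
                                size_bp = NA_integer_)
  }
  fragments <- tibble::as_tibble(fragments)
  if (!"primer_combo" %in% names(fragments)) fragments$primer_combo <- NA_character_
  if (!"size_bp" %in% names(fragments)) fragments$size_bp <- NA_integer_
  fragments$size_bp <- as.integer(fragments$size_bp)
  if (!identical(fragments$fragment_id, rn)) {
    stop("`fragments$fragment_id` must match rownames(calls) in order",
         call. = FALSE)
  }
  if (any(!is.na(fragments$size_bp) & fragments$size_bp <= 0)) {
    stop("size_bp must be positive where present", call. = FALSE)
  }
  if (is.null(replicate_of)) {
    replicate_of <- stats::setNames(colnames(calls), colnames(calls))
  }
  if (!identical(sort(names(replicate_of)), sort(colnames(calls)))) {
    stop("`replicate_of` must name every column of `calls`", call. = FALSE)
  }
  replicate_of <- replicate_of[colnames(calls)]
  structure(
    list(calls = calls,
         fragments = fragments,
         replicate_of = replicate_of,
         samples = unique(unname(replicate_of))),
    class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf("<fragment_matrix> %d fragments x %d lanes (%d samples)\n",
              nrow(x$calls), ncol(x$calls), length(x$samples)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fragment_matrix <- function(x) dim(x$calls)

#' Declare the three roles of a parent-parent-hybrid trio
#'
#' @param female,male,hybrid Sample labels for the maternal parent, the
#'   paternal parent and their F1 hybrid. Must be three distinct labels.
#' @return An object of class `trio_spec`.
#' @export
trio_spec <- function(female, male, hybrid) {
  roles <- c(female = female, male = male, hybrid = hybrid)
  if (anyDuplicated(roles)) {
    stop("female, male and hybrid must be three distinct sample labels",
         call. = FALSE)
  }
  structure(as.list(roles), class = "trio_spec")
}

check_trio_in <- function(trio, samples) {
  missing <- setdiff(unlist(trio), samples)
  if (length(missing) > 0) {
    stop("trio role label(s) not found in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

meta_cols <- c("fragment_id", "primer_combo", "size_bp")

#' Read a band-score table from TSV
#'
#' Expected dialect: UTF-8, tab-separated, first column `fragment_id`,
#' optional metadata columns `primer_combo` and `size_bp`, then one
#' column of 0/1 calls per sample lane. Replicate lanes are declared in
#' the header by a `"<sample>__<replicate>"` naming convention (e.g.
#' `HybA__r1`, `HybA__r2`); columns without the separator stand for a
#' single-lane sample.
#'
#' @param path Path to a TSV file.
#' @param replicate_sep Separator splitting sample from replicate tag in
#'   column names; set to `NULL` to disable replicate detection.
#' @param missing_code Optional string to accept as a missing call,
#'   read as 0 with a warning. By default missing calls are an error.
#' @return A [fragment_matrix].
#' @export
read_fragment_table <- function(path, replicate_sep = "__",
                                missing_code = NULL) {
  raw <- read_tsv_chr(path)
  if (names(raw)[1] != "fragment_id") {
    stop("first column must be `fragment_id`, got `", names(raw)[1], "`",
         call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), meta_cols)
  if (length(sample_cols) == 0) stop("no sample columns found", call. = FALSE)
  calls <- parse_calls(raw, sample_cols, missing_code, path)
  rownames(calls) <- raw$fragment_id
  fragments <- tibble::tibble(
    fragment_id = raw$fragment_id,
    primer_combo = if ("primer_combo" %in% names(raw)) raw$primer_combo else NA_character_,
    size_bp = if ("size_bp" %in% names(raw))
      as.integer(replace(raw$size_bp, raw$size_bp == "", NA)) else NA_integer_)
  replicate_of <- split_replicates(sample_cols, replicate_sep)
  fragment_matrix(calls, fragments, replicate_of)
}

read_tsv_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    comment.char = "#", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

parse_calls <- function(raw, sample_cols, missing_code, path) {
  calls <- matrix(NA_integer_, nrow(raw), length(sample_cols),
                  dimnames = list(NULL, sample_cols))
  for (col in sample_cols) {
    v <- raw[[col]]
    if (!is.null(missing_code)) {
      n_miss <- sum(v == missing_code)
      if (n_miss > 0) {
        warning(sprintf("%d missing call(s) in column `%s` read as 0",
                        n_miss, col), call. = FALSE)
        v[v == missing_code] <- "0"
      }
    }
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("%s: cell (fragment `%s`, column `%s`) is `%s`, expected 0/1",
                   basename(path), raw$fragment_id[i], col, v[i]),
           call. = FALSE)
    }
    calls[, col] <- as.integer(v)
  }
  calls
}

split_replicates <- function(cols, sep) {
  if (is.null(sep)) return(stats::setNames(cols, cols))
  stats::setNames(sub(paste0(sep, "[^_]*$"), "", cols), cols)
}

#' Write a band-score table to TSV
#'
#' Inverse of [read_fragment_table()]: round trips are bit-exact.
#' Metadata columns are written only when any value is non-missing.
#'
#' @param m A [fragment_matrix].
#' @param path Output path.
#' @param header Optional character vector of provenance comment lines,
#'   written as `# `-prefixed lines before the table.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(m, path, header = NULL) {
  df <- data.frame(fragment_id = m$fragments$fragment_id,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (any(!is.na(m$fragments$primer_combo))) df$primer_combo <- m$fragments$primer_combo
  if (any(!is.na(m$fragments$size_bp))) df$size_bp <- m$fragments$size_bp
  df <- cbind(df, as.data.frame(m$calls, check.names = FALSE))
  write_tsv_file(df, path, header)
  invisible(path)
}

write_tsv_file <- function(df, path, header = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Collapse replicate lanes by requiring reproducibility
#'
#' A band is scored present for a biological sample only when every
#' replicate lane of that sample shows it (logical AND). This is the
#' standard conservative rule for dominant markers: a band that fails
#' to amplify in any replicate is treated as unreliable and dropped.
#'
#' @param m A [fragment_matrix], possibly with several lanes per sample.
#' @return A [fragment_matrix] with exactly one column per biological
#'   sample, in first-appearance order.
#' @export
reconcile_replicates <- function(m) {
  stopifnot(inherits(m, "fragment_matrix"))
  out <- vapply(m$samples, function(s) {
    cols <- names(m$replicate_of)[m$replicate_of == s]
    as.integer(rowSums(m$calls[, cols, drop = FALSE]) == length(cols))
  }, integer(nrow(m$calls)))
  if (nrow(m$calls) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, m$samples))
  rownames(out) <- rownames(m$calls)
  fragment_matrix(out, m$fragments)
}

#' Keep fragments inside a size window
#'
#' Retains fragments whose `size_bp` lies in `[lo, hi]` (inclusive on
#' both ends). Fragments without size metadata are kept, with a
#' warning, since they cannot be judged.
#'
#' @param m A [fragment_matrix].
#' @param lo,hi Window bounds in base pairs; `lo <= hi`.
#' @return A filtered [fragment_matrix].
#' @export
filter_by_size <- function(m, lo = 100, hi = 500) {
  stopifnot(inherits(m, "fragment_matrix"))
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  size <- m$fragments$size_bp
  keep <- is.na(size) | (size >= lo & size <= hi)
  n_nosize <- sum(is.na(size))
  if (n_nosize > 0) {
    warning(sprintf("%d fragment(s) lack size_bp and were kept", n_nosize),
            call. = FALSE)
  }
  fragment_matrix(m$calls[keep, , drop = FALSE],
                  m$fragments[keep, , drop = FALSE],
                  m$replicate_of)
}
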