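#' The eight fragment inheritance classes
#'
#' For a dominant marker scored in a female parent, a male parent and
#' their hybrid, the 2^3 = 8 possible presence patterns partition into
#' eight classes: four in which the hybrid carries the band (`common`,
#' `female_specific`, `male_specific`, `novel`) and four in which it
#' does not (`female_loss`, `male_loss`, `common_loss`,
#' `absent_everywhere`).
#'
#' @format Character vector of the eight class labels, in reporting
#'   order.
#' @export
FRAGMENT_CLASSES <- c("common", "female_specific", "male_specific", "novel",
                      "female_loss", "male_loss", "common_loss",
                      "absent_everywhere")

#' Classify a fragment's inheritance pattern in a trio
#'
#' Maps the (female, male, hybrid) presence bits of a fragment to its
#' inheritance class:
#'
#' | (F, M, H) | class |
#' |-----------|-------|
#' | 1, 1, 1 | `common` |
#' | 1, 0, 1 | `female_specific` |
#' | 0, 1, 1 | `male_specific` |
#' | 0, 0, 1 | `novel` |
#' | 1, 0, 0 | `female_loss` |
#' | 0, 1, 0 | `male_loss` |
#' | 1, 1, 0 | `common_loss` |
#' | 0, 0, 0 | `absent_everywhere` |
#'
#' Loss classes are parent-exclusive: `female_loss` means the band was
#' present *only* in the female parent and failed to transmit; a band
#' present in both parents and missing from the hybrid is
#' `common_loss`, not counted as a loss from either single parent.
#'
#' @param f,m,h Presence bits (0/1) for female parent, male parent and
#'   hybrid. Vectorised.
#' @return A factor with levels [FRAGMENT_CLASSES].
#' @export
classify_fragment <- function(f, m, h) {
  bits <- c(f, m, h)
  if (any(!(bits %in% c(0, 1))) || anyNA(bits)) {
    stop("presence calls must be 0 or 1", call. = FALSE)
  }
  key <- f * 4L + m * 2L + h
  # index by F*4 + M*2 + H, i.e. patterns 000, 001, ..., 111
  lut <- c("absent_everywhere", "novel", "male_loss", "male_specific",
           "female_loss", "female_specific", "common_loss", "common")
  factor(lut[key + 1L], levels = FRAGMENT_CLASSES)
}

#' Per-fragment inheritance classes for a trio
#'
#' @param m A reconciled [fragment_matrix] (one column per sample).
#' @param trio A [trio_spec] naming the female, male and hybrid columns.
#' @return A tibble with columns `fragment_id`, `F`, `M`, `H` (presence
#'   bits) and `class`.
#' @export
classify_trio <- function(m, trio) {
  stopifnot(inherits(m, "fragment_matrix"), inherits(trio, "trio_spec"))
  check_trio_in(trio, colnames(m$calls))
  f <- m$calls[, trio$female]
  mm <- m$calls[, trio$male]
  h <- m$calls[, trio$hybrid]
  tibble::tibble(fragment_id = m$fragments$fragment_id,
                 F = f, M = mm, H = h,
                 class = classify_fragment(f, mm, h))
}

#' Count and summarise the inheritance classes of a trio
#'
#' Aggregates [classify_fragment()] over all fragments and derives the
#' totals each fingerprint would show on a gel:
#' `hybrid_total = common + female_specific + male_specific + novel`,
#' `female_total = common + common_loss + female_specific + female_loss`,
#' `male_total = common + common_loss + male_specific + male_loss`.
#' Percentages of the four hybrid-present classes are reported relative
#' to `hybrid_total`, rounded half-up to one decimal.
#' `absent_everywhere` fragments are counted but enter no denominator:
#' a locus with no band anywhere is unobservable on a real gel and can
#' only arise from synthetic data.
#'
#' @inheritParams classify_trio
#' @return A `trio_summary` list with elements `counts` (named integer
#'   vector over [FRAGMENT_CLASSES]), `hybrid_total`, `female_total`,
#'   `male_total`, `percentages` (named, hybrid-present classes) and
#'   `trio`.
#' @export
summarize_trio <- function(m, trio) {
  cls <- classify_trio(m, trio)
  counts <- table(cls$class)
  counts <- stats::setNames(as.integer(counts[FRAGMENT_CLASSES]), FRAGMENT_CLASSES)
  summarize_trio_counts(counts, trio)
}

#' Build a trio summary directly from class counts
#'
#' Useful when only the class tallies are available (e.g. published
#' count tables) rather than the underlying band matrix.
#'
#' @param counts Named non-negative integer vector; names must be a
#'   subset of [FRAGMENT_CLASSES]; omitted classes count 0.
#' @param trio Optional [trio_spec] carried along for labelling.
#' @return A `trio_summary`, as for [summarize_trio()].
#' @export
summarize_trio_counts <- function(counts, trio = NULL) {
  stopifnot(all(names(counts) %in% FRAGMENT_CLASSES))
  full <- stats::setNames(integer(length(FRAGMENT_CLASSES)), FRAGMENT_CLASSES)
  full[names(counts)] <- as.integer(counts)
  counts <- full
  hybrid_total <- sum(counts[c("common", "female_specific", "male_specific", "novel")])
  female_total <- sum(counts[c("common", "common_loss", "female_specific", "female_loss")])
  male_total <- sum(counts[c("common", "common_loss", "male_specific", "male_loss")])
  if (hybrid_total == 0) {
    percentages <- NULL
  } else {
    hyb_classes <- c("common", "female_specific", "male_specific", "novel")
    percentages <- round_half_up(100 * counts[hyb_classes] / hybrid_total, 1)
  }
  structure(list(counts = counts,
                 hybrid_total = hybrid_total,
                 female_total = female_total,
                 male_total = male_total,
                 percentages = percentages,
                 trio = trio),
            class = "trio_summary")
}

#' @export
print.trio_summary <- function(x, ...) {
  cat("<trio_summary>\n")
  print(as_tibble.trio_summary(x))
  cat(sprintf("totals: hybrid %d, female %d, male %d\n",
              x$hybrid_total, x$female_total, x$male_total))
  invisible(x)
}

#' @rdname summarize_trio
#' @param x A `trio_summary`.
#' @param ... Unused.
#' @method as_tibble trio_summary
#' @export
as_tibble.trio_summary <- function(x, ...) {
  pct <- rep(NA_real_, length(FRAGMENT_CLASSES))
  names(pct) <- FRAGMENT_CLASSES
  if (!is.null(x$percentages)) pct[names(x$percentages)] <- x$percentages
  tibble::tibble(class = FRAGMENT_CLASSES,
                 count = unname(x$counts),
                 pct_of_hybrid = unname(pct))
}

#' Maternal and paternal fragment-loss rates
#'
#' The reported loss rate for each parent is the number of bands
#' present only in that parent and absent from the hybrid, divided by
#' that parent's total band count (shared bands, and their joint
#' losses, are excluded from the numerator — they cannot be attributed
#' to one parent).
#'
#' @param s A `trio_summary`.
#' @return A tibble with one row per parent: `parent`, `lost`, `total`,
#'   `fraction` and `pct` (half-up, 1 decimal).
#' @export
loss_rates <- function(s) {
  stopifnot(inherits(s, "trio_summary"))
  if (s$female_total == 0 || s$male_total == 0) {
    stop("parental totals must be positive to compute loss rates",
         call. = FALSE)
  }
  lost <- c(s$counts[["female_loss"]], s$counts[["male_loss"]])
  total <- c(s$female_total, s$male_total)
  tibble::tibble(parent = c("female", "male"),
                 lost = lost, total = total,
                 fraction = lost / total,
                 pct = round_half_up(100 * lost / total, 1))
}

# Half-up decimal rounding (R's round() is round-half-even); internal
# arithmetic stays at full precision, only reported percentages pass
# through here.
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}
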