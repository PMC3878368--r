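#' Fragment-class counts from two intergeneric chrysanthemum crosses
#'
#' Inheritance-class tallies observed in two wide crosses within the
#' Asteraceae — *Chrysanthemum nankingense* x *Tanacetum vulgare*
#' (cross 1) and *Crossostephium chinense* crossed with the decaploid
#' *Chrysanthemum crassum* (cross 2) — scored both on genomic DNA
#' (AFLP, nine primer combinations, reproducible 100-500 bp bands) and
#' on cDNA (cDNA-AFLP). These serve as reference inputs for the trio
#' summaries and as calibration anchors for the synthetic generator.
#'
#' @param assay `"genomic"` (AFLP) or `"cdna"` (cDNA-AFLP).
#' @return A tibble with columns `cross` (1 or 2), `class` (a
#'   [FRAGMENT_CLASSES] label) and `count`.
#' @export
reference_fragment_counts <- function(assay = c("genomic", "cdna")) {
  assay <- match.arg(assay)
  counts <- switch(assay,
    genomic = list(
      `1` = c(common = 184, female_specific = 146, male_specific = 95,
              novel = 4, female_loss = 18, male_loss = 35, common_loss = 7),
      `2` = c(common = 180, female_specific = 162, male_specific = 103,
              novel = 4, female_loss = 16, male_loss = 33, common_loss = 9)),
    cdna = list(
      `1` = c(common = 155, female_specific = 91, male_specific = 52,
              novel = 9, female_loss = 8, male_loss = 22, common_loss = 5),
      `2` = c(common = 166, female_specific = 91, male_specific = 46,
              novel = 15, female_loss = 9, male_loss = 19, common_loss = 7)))
  do.call(rbind, lapply(names(counts), function(cr) {
    tibble::tibble(cross = as.integer(cr),
                   class = names(counts[[cr]]),
                   count = as.integer(counts[[cr]]))
  }))
}

#' Methylation-type counts from the same two crosses
#'
#' Per-line MSAP site tallies (type I non-methylated, type II fully
#' methylated, type III hemi-methylated) for the parents and F1 hybrid
#' of each cross. Per-line totals differ because double-absent sites
#' are dropped per sample.
#'
#' @return A tibble with columns `cross`, `role` (`female`, `male`,
#'   `hybrid`), `line` (taxon label), `type_I`, `type_II`, `type_III`.
#' @export
reference_methylation_counts <- function() {
  tibble::tribble(
    ~cross, ~role, ~line, ~type_I, ~type_II, ~type_III,
    1L, "female", "C.nankingense", 274L, 178L, 132L,
    1L, "male", "T.vulgare", 275L, 164L, 133L,
    1L, "hybrid", "F1.nankingense.vulgare", 292L, 148L, 127L,
    2L, "female", "C.crassum", 261L, 171L, 153L,
    2L, "male", "Cr.chinense", 268L, 162L, 142L,
    2L, "hybrid", "F1.crassum.chinense", 284L, 149L, 140L)
}

#' Materialise a band matrix realising given class counts
#'
#' Builds a three-column (female, male, hybrid) [fragment_matrix] whose
#' per-fragment presence patterns reproduce the supplied class tallies
#' exactly — the classification pipeline applied to the result recovers
#' `counts`. Fragment order is by class, which is immaterial to every
#' downstream summary.
#'
#' @param counts Named integer vector over (a subset of)
#'   [FRAGMENT_CLASSES].
#' @param trio A [trio_spec] providing the column labels.
#' @return A [fragment_matrix] with one column per trio role.
#' @export
trio_matrix_from_counts <- function(counts,
                                    trio = trio_spec("female", "male", "hybrid")) {
  stopifnot(all(names(counts) %in% FRAGMENT_CLASSES))
  pattern <- list(common = c(1, 1, 1), female_specific = c(1, 0, 1),
                  male_specific = c(0, 1, 1), novel = c(0, 0, 1),
                  female_loss = c(1, 0, 0), male_loss = c(0, 1, 0),
                  common_loss = c(1, 1, 0), absent_everywhere = c(0, 0, 0))
  rows <- do.call(rbind, lapply(names(counts), function(cl) {
    matrix(rep(pattern[[cl]], counts[[cl]]), ncol = 3, byrow = TRUE)
  }))
  if (is.null(rows)) rows <- matrix(integer(0), ncol = 3)
  dimnames(rows) <- list(sprintf("frag_%04d", seq_len(nrow(rows))),
                         c(trio$female, trio$male, trio$hybrid))
  fragment_matrix(rows)
}

#' Materialise an MSAP matrix realising given per-sample type counts
#'
#' Builds an [msap_matrix] whose per-sample site typing reproduces the
#' supplied tallies exactly. Samples are filled independently: site
#' identity across samples is arbitrary, which is harmless because all
#' downstream methylation summaries are per-sample marginals.
#'
#' @param counts A data frame with columns `line` (sample label),
#'   `type_I`, `type_II`, `type_III` — e.g. one cross's rows of
#'   [reference_methylation_counts()].
#' @return An [msap_matrix] with one column per row of `counts`.
#' @export
msap_from_counts <- function(counts) {
  stopifnot(all(c("line", "type_I", "type_II", "type_III") %in% names(counts)))
  totals <- counts$type_I + counts$type_II + counts$type_III
  n_sites <- max(totals)
  h <- m <- matrix(0L, nrow = n_sites, ncol = nrow(counts),
                   dimnames = list(sprintf("site_%04d", seq_len(n_sites)),
                                   counts$line))
  for (j in seq_len(nrow(counts))) {
    iI <- seq_len(counts$type_I[j])
    iII <- seq_len(counts$type_II[j]) + counts$type_I[j]
    iIII <- seq_len(counts$type_III[j]) + counts$type_I[j] + counts$type_II[j]
    h[c(iI, iIII), j] <- 1L   # H lane: types I and III
    m[c(iI, iII), j] <- 1L    # M lane: types I and II
  }
  msap_matrix(h, m)
}
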