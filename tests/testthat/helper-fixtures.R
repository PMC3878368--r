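# Small in-code fixtures shared across test files.

# 4-fragment trio matrix with two replicate lanes per sample.
make_replicated_matrix <- function() {
  calls <- rbind(
    frag_a = c(1, 1, 1, 1, 1, 1),
    frag_b = c(1, 0, 1, 1, 0, 0),  # female replicates disagree
    frag_c = c(0, 0, 1, 1, 1, 1),
    frag_d = c(1, 1, 0, 0, 0, 0))
  colnames(calls) <- c("F__r1", "F__r2", "M__r1", "M__r2", "H__r1", "H__r2")
  fragment_matrix(calls,
                  tibble::tibble(fragment_id = rownames(calls),
                                 primer_combo = "E2+M5",
                                 size_bp = c(99L, 100L, 500L, 501L)),
                  replicate_of = setNames(rep(c("F", "M", "H"), each = 2),
                                          colnames(calls)))
}

# Write a minimal fragment TSV and return its path.
write_tmp_fragment_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

cross_counts <- function(assay, cross) {
  tab <- reference_fragment_counts(assay)
  tab <- tab[tab$cross == cross, ]
  setNames(tab$count, tab$class)
}

default_trio <- trio_spec("female", "male", "hybrid")
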