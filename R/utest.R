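#' Pooled two-proportion U test of hybrid versus mid-parent
#'
#' Compares the hybrid's proportion of methylated (or fully / hemi
#' methylated) sites with the mid-parent expectation using the pooled
#' two-sample proportion statistic
#' \deqn{p = \frac{y_1 + y_2}{n_1 + n_2},\quad q = 1 - p,\quad
#'   \delta = \sqrt{pq\left(\frac{1}{n_1} + \frac{1}{n_2}\right)},\quad
#'   U = \frac{p_1 - p_2}{\delta}}
#' where \eqn{(y_1, n_1)} are the mid-parent count and total (means of
#' the two parents' raw counts, possibly half-integral) and
#' \eqn{(y_2, n_2)} the hybrid's. Under the additive null \eqn{U} is
#' asymptotically standard normal; the two-sided 5% decision compares
#' \eqn{|U|} with 1.96. No continuity correction is applied.
#'
#' When the pooled proportion is degenerate (`p` is 0 or 1) the
#' standard error is zero and `U` is undefined; the result is returned
#' with `degenerate = TRUE` and `U = NA` rather than dividing by zero.
#'
#' @param y1,n1 Mid-parent count of the class of interest and
#'   mid-parent total sites (half-integers allowed).
#' @param y2,n2 Hybrid count and total sites (integers).
#' @param threshold Critical value for the two-sided decision
#'   (default 1.96, the 5% normal quantile).
#' @return A `u_test_result` list: `y1`, `n1`, `y2`, `n2`, `p1`, `p2`,
#'   `p`, `q`, `delta`, `U` (full precision; `NA` if degenerate),
#'   `threshold`, `significant`, `degenerate`.
#' @export
u_test <- function(y1, n1, y2, n2, threshold = 1.96) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive", call. = FALSE)
  if (y1 < 0 || y1 > n1 || y2 < 0 || y2 > n2) {
    stop("counts must satisfy 0 <= y <= n", call. = FALSE)
  }
  p1 <- y1 / n1
  p2 <- y2 / n2
  p <- (y1 + y2) / (n1 + n2)
  q <- 1 - p
  if (p <= 0 || p >= 1) {
    return(structure(list(y1 = y1, n1 = n1, y2 = y2, n2 = n2,
                          p1 = p1, p2 = p2, p = p, q = q,
                          delta = 0, U = NA_real_,
                          threshold = threshold, significant = NA,
                          degenerate = TRUE),
                     class = "u_test_result"))
  }
  delta <- sqrt(p * q * (1 / n1 + 1 / n2))
  U <- (p1 - p2) / delta
  structure(list(y1 = y1, n1 = n1, y2 = y2, n2 = n2,
                 p1 = p1, p2 = p2, p = p, q = q,
                 delta = delta, U = U,
                 threshold = threshold,
                 significant = abs(U) >= threshold,
                 degenerate = FALSE),
            class = "u_test_result")
}

#' @export
print.u_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<u_test> p1 %.4f vs p2 %.4f: pooled p = %g, U undefined (degenerate)\n",
                x$p1, x$p2, x$p))
  } else {
    cat(sprintf("<u_test> p1 %.4f vs p2 %.4f: U = %.2f (threshold %.2f, %s)\n",
                x$p1, x$p2, x$U, x$threshold,
                if (x$significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' U tests of a hybrid against its mid-parent value
#'
#' Runs [u_test()] three times — for total methylated sites, fully
#' methylated (type II) sites and hemi-methylated (type III) sites —
#' taking \eqn{(y_1, n_1)} from the mid-parent value and
#' \eqn{(y_2, n_2)} from the hybrid summary.
#'
#' @param mpv A `mid_parent_value` (see [mid_parent()]).
#' @param hyb A `methylation_summary` for the hybrid.
#' @param threshold Critical value, as in [u_test()].
#' @return Named list of three `u_test_result`s: `total`, `full`,
#'   `hemi`.
#' @export
compare_hybrid_to_mpv <- function(mpv, hyb, threshold = 1.96) {
  stopifnot(inherits(mpv, "mid_parent_value"),
            inherits(hyb, "methylation_summary"))
  list(
    total = u_test(mpv$y1_total, mpv$n1, hyb$methylated, hyb$total_sites, threshold),
    full = u_test(mpv$y1_full, mpv$n1, hyb$type_II, hyb$total_sites, threshold),
    hemi = u_test(mpv$y1_hemi, mpv$n1, hyb$type_III, hyb$total_sites, threshold))
}

#' Tabulate a list of U-test results
#'
#' @param results Named list of `u_test_result`s (e.g. from
#'   [compare_hybrid_to_mpv()]).
#' @return A tibble with one row per test: `test`, `y1`, `n1`, `y2`,
#'   `n2`, `p1`, `p2`, `U` (rounded to 2 decimals for reporting),
#'   `significant`.
#' @export
u_test_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    tibble::tibble(test = nm, y1 = r$y1, n1 = r$n1, y2 = r$y2, n2 = r$n2,
                   p1 = r$p1, p2 = r$p2,
                   U = if (r$degenerate) NA_real_ else round_half_up(r$U, 2),
                   significant = r$significant)
  })
  do.call(rbind, rows)
}
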