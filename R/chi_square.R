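#' Pearson chi-square test for a 2x2 trial table
#'
#' Standard Pearson statistic on the four cells with expected counts
#' `row_total * col_total / N`, 1 degree of freedom, p-value from the
#' upper tail. No continuity correction by default; Yates' correction is
#' available via the flag.
#'
#' @param table A [trial_table].
#' @param continuity_correction Apply Yates' continuity correction.
#' @return An object of class `chi_square_result`: list with `statistic`,
#'   `df` (always 1) and `p_value`.
#' @examples
#' chi_square_2x2(empa_reg_table())
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  stopifnot(inherits(table, "trial_table"))
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square undefined: a row or column margin is zero",
         call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(m, correct = continuity_correction)
  )
  structure(list(statistic = unname(ht$statistic),
                 df = 1L,
                 p_value = unname(ht$p.value)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
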