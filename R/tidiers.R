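# broom-style accessors for test results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chi-square comparison
#'
#' @param x A `meth_chisq` object from [pairwise_chisq()].
#' @param ... Unused.
#' @return A tibble with one row per comparison.
#' @method tidy meth_chisq
#' @export
tidy.meth_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 significant = x$significant, computable = x$computable)
}

#' Summarise a chi-square comparison set
#'
#' @param x A `meth_chisq` object from [pairwise_chisq()].
#' @param ... Unused.
#' @return A one-row tibble: number of comparisons, number significant, and
#'   the critical value used.
#' @method glance meth_chisq
#' @export
glance.meth_chisq <- function(x, ...) {
  tibble::tibble(n_comparisons = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 critical = attr(x, "critical") %||% stats::qchisq(0.99, 1))
}
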