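#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x A `circ_de` from [differential()].
#' @param ... Ignored.
#' @return A plain tibble (one row per feature).
#' @export
tidy.circ_de <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a differential-expression result
#'
#' @param x A `circ_de`.
#' @param ... Ignored.
#' @return Tibble with tissue, feature/significance counts and the fitted
#'   thresholds.
#' @export
glance.circ_de <- function(x, ...) {
  tibble(tissue = attr(x, "tissue"), n_features = nrow(x),
         n_up = sum(x$status == "up"), n_down = sum(x$status == "down"),
         fc_cutoff = attr(x, "fc_cutoff"), alpha = attr(x, "alpha"),
         correct = attr(x, "correct"))
}

#' Tidy / summarize a global shift test
#'
#' @param x A `circ_shift_test` from [global_shift()].
#' @param ... Ignored.
#' @return One-row tibble with U, z, P and group sizes.
#' @export
tidy.circ_shift_test <- function(x, ...) {
  tibble(tissue = x$tissue, U = x$U, z = x$z, p_value = x$p_value,
         n_old = x$n_old, n_young = x$n_young)
}

#' @rdname tidy.circ_shift_test
#' @export
glance.circ_shift_test <- tidy.circ_shift_test
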