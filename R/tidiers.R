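#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a marker-set comparison
#'
#' @param x A `cq_marker_comparison` from [compare_marker_sets()].
#' @param ... Unused.
#' @return The per-panel test tibble.
#' @exportS3Method generics::tidy
tidy.cq_marker_comparison <- function(x, ...) x$tests

#' One-row summary of a marker-set comparison
#'
#' @param x A `cq_marker_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with cell counts and the test used.
#' @exportS3Method generics::glance
glance.cq_marker_comparison <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$groups),
    n_positive = sum(x$groups$group == "positive"),
    n_negative = sum(x$groups$group == "negative"),
    split_gene = x$split_gene,
    test = x$test
  )
}
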