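#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Monte Carlo proximity test
#'
#' @param x A [proximity_test()] result.
#' @param ... Unused.
#' @return The per-pair significance tibble (one row per analysed pair).
#' @export
tidy.proxseq_proximity <- function(x, ...) {
  x$results
}

#' One-row summary of a Monte Carlo proximity test
#'
#' @param x A [proximity_test()] result.
#' @param ... Unused.
#' @return A one-row tibble: dataset dimensions, randomization count and
#'   discovery counts at the configured thresholds.
#' @export
glance.proxseq_proximity <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$skeleton$features),
    n_groups = length(x$skeleton$group_sizes),
    n_proxy_reads = sum(x$skeleton$group_sizes),
    n_randomizations = x$n_randomizations,
    n_pairs_analysed = nrow(x$results),
    n_pairs_tested = sum(x$results$observed_count >=
                           x$config$min_observed_for_significance),
    n_significant_local = sum(x$results$significant_local),
    n_significant_corrected = sum(x$results$significant_corrected)
  )
}
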