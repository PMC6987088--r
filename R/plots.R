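#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a proximity test as count-ratio clouds
#'
#' Reproduces the standard diagnostic view of the Monte Carlo analysis: the
#' log2 observed/randomized co-barcoding ratio (y) against the observed
#' co-barcoding count (x), with the background cloud (a randomized dataset
#' against its own randomizations) in one panel and the observed data in
#' the other. Observed pairs are coloured by significance call.
#'
#' @param object A [proximity_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proxseq_proximity <- function(object, ...) {
  bg <- tibble::tibble(x = object$background$x, y = object$background$y,
                       panel = "background (random vs its randomizations)",
                       call = "background")
  res <- object$results
  obs <- tibble::tibble(
    x = res$observed_count, y = res$log2_ratio,
    panel = "observed vs randomizations",
    call = dplyr::case_when(
      res$significant_corrected ~ "q <= cutoff",
      res$significant_local ~ "local p <= cutoff",
      TRUE ~ "not significant"))
  dat <- dplyr::bind_rows(bg, obs)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      "background" = "grey60", "not significant" = "grey30",
      "local p <= cutoff" = "goldenrod2", "q <= cutoff" = "red2")) +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = "observed co-barcoding count",
                  y = "log2 observed / mean randomized",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot valency classifications
#'
#' Scatter of the valency-1 z-score against the mean of the valency-2 and
#' valency-3 z-scores, coloured by class: high-valency transcripts (dense
#' RNA neighbourhoods) sit in the upper-left quadrant, low-valency ones in
#' the lower-right.
#'
#' @param classification A [classify_valency()] table.
#' @return A ggplot object.
#' @export
plot_valency_classes <- function(classification) {
  dat <- classification[classification$class != "unassigned", ]
  dat$z23 <- (dat$z2 + dat$z3) / 2
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$z1, y = .data$z23,
                                    colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(high = "purple3",
                                            low = "springgreen4",
                                            middle = "grey20")) +
    ggplot2::labs(x = "valency 1 z-score",
                  y = "mean of valency 2 and 3 z-scores",
                  colour = "valency class") +
    ggplot2::theme_bw()
}

#' Plot the barcode-group size distribution against its Poisson fit
#'
#' @param group_sizes Integer vector of barcode group sizes.
#' @param model Optional [fit_group_size_threshold()] model (fitted from
#'   `group_sizes` when omitted).
#' @return A ggplot object.
#' @export
plot_group_sizes <- function(group_sizes, model = NULL) {
  if (is.null(model)) model <- fit_group_size_threshold(group_sizes)
  tab <- dplyr::count(tibble::tibble(size = group_sizes), .data$size)
  tab$expected <- length(group_sizes) *
    stats::dpois(tab$size, model$lambda_hat) /
    (1 - stats::dpois(0, model$lambda_hat))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "steelblue",
                      alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "red2") +
    ggplot2::geom_vline(xintercept = model$max_allowed_size + 0.5,
                        linetype = 2) +
    ggplot2::labs(x = "barcode group size", y = "groups",
                  subtitle = paste0("Poisson lambda = ",
                                    signif(model$lambda_hat, 3),
                                    "; sizes beyond the dashed line removed")) +
    ggplot2::theme_bw()
}
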