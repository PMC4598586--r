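# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sliding-window methylation profile
#'
#' @param object A `meth_windows` table from [window_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_windows
#' @export
autoplot.meth_windows <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$n_sites > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$mean_level,
                                   colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "mean methylation level",
                  colour = "context") +
    ggplot2::ylim(0, 1)
}

#' Plot a metagene methylation profile
#'
#' @param object A `meth_metagene` table from [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_metagene
#' @export
autoplot.meth_metagene <- function(object, ...) {
  df <- tibble::as_tibble(object)
  offs <- c(upstream = 0, body = 10, downstream = 20)
  df$x <- offs[as.character(df$region)] + df$bin
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean_level,
                                   colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(10.5, 20.5), linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "bin (upstream | body deciles | downstream)",
                  y = "mean methylation level", colour = "context")
}

#' Plot a per-context methylation level histogram
#'
#' @param object A `meth_histogram` table from [level_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_histogram
#' @export
autoplot.meth_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$context)) +
    ggplot2::labs(x = "methylation level bin (%)", y = "fraction of sites") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot stratum methylation means
#'
#' @param object A `stratum_summary` table from [stratum_means()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stratum_summary
#' @export
autoplot.stratum_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$component, y = .data$mean,
                               fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$context), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "pooled methylation level",
                  fill = "stratum")
}
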