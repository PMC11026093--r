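#' @export
tidy.cluster_match <- function(x, ...) {
  x$matches
}

#' @export
glance.cluster_match <- function(x, ...) {
  tibble::tibble(n_shared_pairs = nrow(x$matches),
                 n_unique_a = nrow(x$unique_a),
                 n_unique_b = nrow(x$unique_b),
                 d_max = x$d_max)
}

#' @export
glance.consistency_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
autoplot.feature_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      cols = c("mean_shared", "mean_unique"),
      names_to = "class", values_to = "mean", names_prefix = "mean_") |>
    dplyr::mutate(sd = ifelse(.data$class == "shared", .data$sd_shared,
                              .data$sd_unique))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$mean,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "subject-level mean ± SD",
                  title = "Shared vs unique peak features")
}

#' Scatter plot of cross-species shared-cluster consistency
#'
#' @param pairs tibble with `consistency_m` and `consistency_h` columns (the
#'   `pairs` element of the pipeline's consistency stage).
#' @return a ggplot.
#' @export
plot_consistency_pairs <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$consistency_m,
                                      y = .data$consistency_h)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "macaque consistency (peaks/subject)",
                  y = "human consistency (peaks/subject)",
                  title = "Inter-species consistency of shared clusters")
}

#' Bar plot of per-network shared/unique proportions
#'
#' @param tally a [network_tally()] result.
#' @return a ggplot.
#' @export
plot_network_tally <- function(tally) {
  df <- tally$by_network |>
    tidyr::pivot_longer(c("prop_shared", "prop_unique"),
                        names_to = "class", values_to = "proportion",
                        names_prefix = "prop_")
  df$network <- factor(df$network, levels = tally$by_network$network)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$proportion,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "within-class proportion",
                  title = "Cluster centers per network")
}
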