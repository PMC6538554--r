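#' Plot corpus statistics
#'
#' Bar panels of the four per-domain statistics plus the domains-per-resource
#' histogram.
#'
#' @param object A `corpus_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corpus_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(object$domains,
                              c("coverage", "volume", "diversity", "isolation"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$domain, y = .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Per-domain annotation statistics (m = %d)",
                                  object$m)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.corpus_stats
#' @export
plot_domain_histogram <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = factor(.data$n_domains),
                               y = .data$n_resources)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "distinct annotation domains per resource",
                  y = "resources") +
    ggplot2::theme_minimal()
}

#' Plot a similarity matrix as a heatmap
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  m <- object$scores
  df <- tibble::tibble(
    r1 = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    r2 = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    score = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$r1, .data$r2, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s / %s", setting_label(object$setting),
                                  object$measure$groupwise)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot an evaluation report: metric against k per setting
#'
#' One panel per metric, one line per setting — multi-domain settings solid,
#' baselines dotted.
#'
#' @param object An `evaluation_report`.
#' @param measure Restrict to one groupwise measure (default: first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object,
                                       measure = unique(object$measure)[[1]],
                                       ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$measure == !!measure) |>
    tidyr::pivot_longer(dplyr::all_of(names(metric_directions)),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(kind = ifelse(startsWith(.data$setting, "baseline"),
                                "single-domain baseline", "multi-domain"))
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$value,
                                   colour = .data$setting,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_linetype_manual(values = c("multi-domain" = "solid",
                                              "single-domain baseline" = "dotted")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(y = NULL, title = paste("ML-KNN performance,", measure)) +
    ggplot2::theme_minimal()
}
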