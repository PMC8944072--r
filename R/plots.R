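#' Plot a threshold-vs-z sweep
#'
#' The diagnostic plot used to pick a module: the induced-LCC z-score at
#' each p-value threshold, sized by component size, with the selection band
#' drawn at `z_min` and the selected module (if any) highlighted.
#'
#' @param object A `module_fit` (from [detect_module()]) or `module_sweep`
#'   (from [run_sweep()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_fit <- function(object, ...) {
  p <- autoplot.module_sweep(object$sweep, ...)
  if (is_module(object$module)) {
    m <- object$module
    p <- p + ggplot2::annotate("point", x = m$threshold, y = m$z_score,
                               shape = 1, size = 5, colour = "red") +
      ggplot2::labs(subtitle = sprintf("selected: %d genes at t = %.4g",
                                       m$lcc_size, m$threshold))
  }
  p
}

#' @rdname autoplot.module_fit
#' @export
autoplot.module_sweep <- function(object, ...) {
  rule <- attr(object, "rule") %||% selection_rule()
  df <- as_tibble(object) |> select(-"lcc_members")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$z_score)) +
    ggplot2::geom_hline(yintercept = rule$z_min, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$lcc_size), colour = "red3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value threshold", y = "LCC z-score",
                  size = "LCC size",
                  title = attr(object, "dataset") %||% "sweep") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the null statistic (cross-edge count or within-set
#' connectivity) with the observed value marked.
#'
#' @param object A `connectivity_test` from [inter_module_significance()] or
#'   [gene_set_connectivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_test <- function(object, ...) {
  nulls <- attr(object, "null_values")
  observed <- if ("total" %in% names(object)) object$total else object$observed
  ggplot2::ggplot(tibble(null = nulls), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = observed, colour = "red3",
                        linewidth = 1) +
    ggplot2::labs(x = "null statistic", y = "count",
                  title = sprintf("observed = %d, z = %.2f, p = %.3g",
                                  observed, object$z_score,
                                  object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Bar chart of `-log10` adjusted p-values for the top enriched sets.
#'
#' @param object An `enrichment_result` from [enrich_collection()].
#' @param top Number of sets to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- as_tibble(object) |>
    head(top) |>
    mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$adj_p_value),
                                   y = .data$set_name,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha") %||% 0.05),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "red3", `FALSE` = "grey70"),
                               name = "adj. p < 0.05") +
    ggplot2::labs(x = expression(-log[10]~adjusted~p), y = NULL) +
    ggplot2::theme_minimal()
}
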