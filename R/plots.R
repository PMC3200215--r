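# ggplot2 displays for the main result types.

#' Volcano plot of per-protein differential expression
#'
#' @param results A `protein_stats` tibble from [quantify_proteins()].
#' @param q_max,min_abs_fc Thresholds drawn as guide lines (matching the
#'   significance gate).
#' @return A ggplot.
#' @export
plot_volcano <- function(results, q_max = 0.05, min_abs_fc = 1.3) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(
      x = .data$diff_log2, y = -log10(.data$q_value),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(q_max), linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = c(-log2(min_abs_fc), log2(min_abs_fc)),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "log2 group difference (case - control)",
      y = "-log10 q-value", colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `protein_stats` tibble.
#' @param ... Passed on to [plot_volcano()].
#' @export
autoplot.protein_stats <- function(object, ...) {
  plot_volcano(object, ...)
}

#' Per-sample discriminant scores of a fitted panel
#'
#' @param object A `panel_model`.
#' @param ... Unused.
#' @return A ggplot showing each sample's projection and the decision
#'   threshold.
#' @export
autoplot.panel_model <- function(object, ...) {
  df <- tibble::tibble(
    sample = names(object$scores) %||% as.character(seq_along(object$scores)),
    score = unname(object$scores),
    class = object$labels
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score, y = stats::reorder(.data$sample, .data$score),
    colour = .data$class
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "discriminant score", y = NULL, colour = NULL,
      title = paste("Panel:", paste(object$proteins, collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}

#' Injection intensity distributions before/after normalization
#'
#' @param raw,normalized Long peptide tibbles on the raw and normalized
#'   scales (columns `injection` and `intensity`/`log2_intensity`).
#' @return A ggplot of per-injection boxplots faceted by stage.
#' @export
plot_normalization <- function(raw, normalized) {
  df <- dplyr::bind_rows(
    dplyr::transmute(raw,
      injection = .data$injection,
      value = log2(.data$intensity), stage = "log2 raw"
    ),
    dplyr::transmute(normalized,
      injection = .data$injection,
      value = .data$log2_intensity, stage = "quantile normalized"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$injection, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~stage, ncol = 1) +
    ggplot2::labs(x = NULL, y = "log2 intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
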