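#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   labs theme_minimal scale_fill_brewer facet_wrap
NULL

#' Stacked ancestry bar plot
#'
#' The customary display of admixture results: one vertical bar per
#' individual partitioned into its K ancestry proportions, individuals
#' ordered by dominant cluster and membership.
#'
#' @param object A `qmatrix` from [align_runs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qmatrix <- function(object, ...) {
  Q <- object$Q
  ord <- order(apply(Q, 1, which.max), -apply(Q, 1, max))
  df <- as_tibble(Q[ord, , drop = FALSE]) %>%
    mutate(individual = factor(seq_len(nrow(Q)))) %>%
    tidyr::pivot_longer(-"individual", names_to = "cluster",
                        values_to = "ancestry")
  ggplot(df, aes(x = .data$individual, y = .data$ancestry,
                 fill = .data$cluster)) +
    geom_col(width = 1) +
    labs(x = "individual", y = "ancestry proportion (qI)", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Delta-K profile plot
#'
#' @param object A `delta_k_tbl` from [delta_k()].
#' @param ... Unused.
#' @return A ggplot of delta-K against K with the selected K marked.
#' @export
autoplot.delta_k_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  sel <- attr(object, "selected_k")
  ggplot(df, aes(x = .data$k, y = .data$delta_k)) +
    geom_line() + geom_point() +
    geom_point(data = df[df$k == sel, , drop = FALSE], colour = "red", size = 3) +
    labs(x = "K", y = expression(Delta * K)) +
    theme_minimal()
}

#' PCoA scatter plot
#'
#' @param object A `pcoa_result`.
#' @param colour_by Optional tibble with `accession_id` and `group`
#'   (e.g. from [assign_groups()]) to colour the points.
#' @param axes Which two axes to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_result <- function(object, colour_by = NULL, axes = c(1, 2), ...) {
  df <- object$points
  ax <- paste0("axis", axes)
  if (!all(ax %in% names(df))) abort("requested axes not available")
  if (!is.null(colour_by)) {
    df <- left_join(df, dplyr::select(colour_by, "accession_id", "group"),
                    by = "accession_id")
  } else {
    df$group <- "all"
  }
  pv <- 100 * object$prop_var[axes]
  ggplot(df, aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                 colour = .data$group)) +
    geom_point(alpha = 0.8) +
    labs(x = sprintf("Axis %d (%.1f%%)", axes[1], pv[1]),
         y = sprintf("Axis %d (%.1f%%)", axes[2], pv[2]),
         colour = NULL) +
    theme_minimal()
}
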