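# ggplot2 displays for the main result types.

#' Plot a social network as a weight heatmap
#'
#' @param object A [social_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot social_network
#' @export
autoplot.social_network <- function(object, ...) {
  df <- tidyr::expand_grid(from = object$labels, to = object$labels) |>
    dplyr::mutate(weight = as.numeric(t(object$W)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(object$labels)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = object$behaviour,
                  x = "receiver / observed", y = "actor / observer") +
    ggplot2::theme_minimal()
}

#' Plot a centrality table
#'
#' Dot plot of group-relative ranks per measure (rank 1, the most central,
#' at the top).
#'
#' @param object A `centrality_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot centrality_table
#' @export
autoplot.centrality_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::ends_with("_rank"),
                              names_to = "measure", values_to = "rank") |>
    dplyr::mutate(measure = sub("_rank$", "", .data$measure))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$id,
                                     colour = .data$measure)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_reverse(breaks = scales_int_breaks(max(long$rank))) +
    ggplot2::labs(title = attr(object, "behaviour"),
                  x = "rank (1 = most central)", y = NULL) +
    ggplot2::theme_minimal()
}

scales_int_breaks <- function(mx) seq_len(ceiling(mx))

#' Plot an OADA model set
#'
#' Akaike weights per model, coloured by network, weighted models hatched
#' apart by the weight flag.
#'
#' @param object An `oada_model_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oada_model_set
#' @export
autoplot.oada_model_set <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(model = paste0(.data$network,
                                 ifelse(.data$use_weights, " (w)", ""),
                                 ifelse(.data$ilvs == "", "", paste0(" + ", .data$ilvs))),
                  model = stats::reorder(.data$model, -.data$AICc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$akaike_weight, y = .data$model,
                                   fill = .data$network)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}
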