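#' Map a field variable over its grid
#'
#' Tile map of one column of a field dataset against its coordinates; the
#' quickest way to eyeball gradients, edge effects and correlated patches.
#'
#' @param data A field dataset with columns `x`, `y`.
#' @param var Column to display (tidy-eval); defaults to `A`.
#' @return A ggplot object.
#' @examples
#' d <- simulate_observational(p = 1, outcome_spec = "gaussCor", seed = 1)
#' plot_field(d)
#' @export
plot_field <- function(data, var = NULL) {
  var <- rlang::enquo(var)
  if (rlang::quo_is_null(var)) var <- rlang::sym("A")
  ggplot2::ggplot(data, ggplot2::aes(.data$x, .data$y, fill = !!var)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @method autoplot fieldsim
#' @export
autoplot.fieldsim <- function(object, ...) plot_field(object, ...)

#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object, metric = NULL, ...) {
  df <- summarize_study(object)
  if (!is.null(metric)) df <- dplyr::filter(df, .data$metric %in% !!metric)
  facet_vars <- intersect(c("scenario_outcome", "scenario_regressor"), names(df))
  pl <- ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$mean,
                                         colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$mc_se,
                                          ymax = .data$mean + .data$mc_se),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(facet_vars) > 0) {
    pl <- pl + ggplot2::facet_grid(stats::reformulate(facet_vars[1],
                                                      facet_vars[length(facet_vars)]))
  }
  pl
}
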