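#' Plot group metric trajectories over timepoints
#'
#' Mean and 95% confidence interval of a metric per group and timepoint,
#' faceted by network — the standard longitudinal trajectory figure for
#' resting-state network metrics.
#'
#' @param metrics long metric table from [metric_table()].
#' @param metric column to plot (`"amplitude"` or `"shape"`).
#' @return A ggplot object.
#' @export
plot_metric_trajectories <- function(metrics, metric = "amplitude") {
  stopifnot(metric %in% names(metrics))
  summ <- metrics |>
    dplyr::group_by(.data$network, .data$timepoint, .data$group) |>
    dplyr::summarise(
      mean = mean(.data[[metric]], na.rm = TRUE),
      se = sd(.data[[metric]], na.rm = TRUE) /
        sqrt(sum(is.finite(.data[[metric]]))),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = factor(.data$group, levels = c(0, 1),
                                 labels = c("control", "transgenic")))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                        ymax = .data$mean + 1.96 * .data$se),
                           width = 0.15) +
    ggplot2::facet_wrap(~network, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(control = "#2166ac",
                                            transgenic = "#b2182b")) +
    ggplot2::labs(y = metric, x = "timepoint", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metric_trajectories
#' @param object an `rsn_pipeline_result`.
#' @param ... passed on (e.g. `metric`).
#' @export
autoplot.rsn_pipeline_result <- function(object, ...) {
  plot_metric_trajectories(object$metrics, ...)
}

#' Plot a fitted longitudinal mixed model over its data
#'
#' Scatter of the response against age coloured by group, with the
#' fixed-effect regression lines of the fitted model.
#'
#' @param object an `rsn_lme` from [fit_rsn_lme()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rsn_lme <- function(object, ...) {
  fr <- object$model@frame
  b <- setNames(object$fixed$estimate, object$fixed$term)
  ages <- range(fr$age)
  lines <- tidyr::expand_grid(group = c(0, 1), age = ages) |>
    dplyr::mutate(y = b[["(Intercept)"]] + b[["group"]] * .data$group +
                    b[["age"]] * .data$age +
                    b[["group:age"]] * .data$group * .data$age)
  df <- tibble::tibble(y = fr$y, age = fr$age, group = fr$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$y,
                                   colour = factor(.data$group))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(group = factor(.data$group))) +
    ggplot2::scale_colour_manual(values = c(`0` = "#2166ac",
                                            `1` = "#b2182b"),
                                 labels = c("control", "transgenic")) +
    ggplot2::labs(x = "age (months)", y = object$response, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot axial slices of a component z-map
#'
#' @param cs a `component_set` with a mask.
#' @param component component index or name.
#' @param slices z-slice indices (default: 4 evenly spaced).
#' @param z_thresh values with `|z|` below this are blanked.
#' @return A ggplot object.
#' @export
plot_component_map <- function(cs, component = 1, slices = NULL,
                               z_thresh = 2.3) {
  stopifnot(inherits(cs, "component_set"), !is.null(cs$mask))
  if (is.character(component)) {
    component <- match(component, rownames(cs$maps_z))
  }
  d <- dim(cs$mask)
  vol <- array(NA_real_, d)
  vol[cs$mask] <- cs$maps_z[component, ]
  slices <- slices %||% unique(round(seq(2, d[3] - 1, length.out = 4)))
  df <- purrr::map_dfr(slices, function(zi) {
    vals <- as.vector(vol[, , zi])
    tibble::tibble(
      x = rep(seq_len(d[1]), d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      z = zi,
      value = vals
    )
  })
  df$value[!is.na(df$value) & abs(df$value) < z_thresh] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "z") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
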