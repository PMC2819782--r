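#' Trace and density plots for a fitted model
#'
#' @param object A `prev_fit` object.
#' @param parameters Parameters to show (default: the cause coefficients,
#'   spatial correlation, variances and indicator loadings).
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object, faceted by parameter.
#' @export
autoplot.prev_fit <- function(object, parameters = NULL,
                              type = c("trace", "density"), ...) {
  type <- match.arg(type)
  d <- object$dims
  if (is.null(parameters))
    parameters <- c(if (d$L > 0) paste0("beta[", seq_len(d$L), "]"),
                    "kappa", "sigma2_f", "sigma2_u",
                    paste0("lambda_y[", seq_len(d$P), "]"))
  dr <- tidy_draws(object, parameters)
  dr$chain <- factor(dr$chain)
  if (type == "trace") {
    ggplot2::ggplot(dr, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "retained iteration", y = NULL, colour = "chain")
  } else {
    ggplot2::ggplot(dr, ggplot2::aes(x = .data$value, colour = .data$chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = NULL, colour = "chain")
  }
}

#' Hotspot plot of standardised relative risks
#'
#' Areas ordered by posterior mean SRR, coloured by the three-way
#' classification, with the threshold lines shown. For lattice geographies
#' from [make_grid_geography()] a tile map can be drawn instead by passing
#' the geography.
#'
#' @param object A `prev_area_summary` from [area_summary()].
#' @param thresholds The classification thresholds drawn as reference lines.
#' @param geography Optional geography list (with `areas$row`, `areas$col`)
#'   to draw a lattice tile map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prev_area_summary <- function(object, thresholds = c(-1, 1),
                                       geography = NULL, ...) {
  if (!is.null(geography)) {
    df <- left_join(tibble::as_tibble(object),
                    geography$areas[c("area_id", "row", "col")],
                    by = "area_id")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$label)) +
        ggplot2::geom_tile(colour = "grey40") +
        ggplot2::scale_fill_manual(
          values = c(low = "#2166ac", middle = "grey85", high = "#b2182b"),
          drop = FALSE) +
        ggplot2::coord_equal() +
        ggplot2::labs(fill = "SRR class"))
  }
  df <- tibble::as_tibble(object)
  df <- df[order(df$srr), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$srr,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(low = "#2166ac", middle = "grey50", high = "#b2182b"),
      drop = FALSE) +
    ggplot2::labs(x = "area (ordered)", y = "standardised relative risk",
                  colour = "class")
}
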