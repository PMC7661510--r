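## ggplot2 views of the main result types.

#' Map a per-cell indicator on the reef grid
#'
#' @param grid reef grid tibble
#' @param values tibble `cell_id` plus the column named in `fill`
#' @param fill name of the column to map to fill
#' @return a ggplot
#' @export
plot_reef_map <- function(grid, values, fill) {
  df <- grid |>
    filter(.data$is_reef) |>
    inner_join(values, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_genotype_logistic logistic presence-vs-BAF curve
#' @param object a `gea_fit`
#' @export
autoplot.gea_fit <- function(object, ...) {
  baf <- seq(0, 0.35, length.out = 200)
  df <- tibble(baf = baf,
               freq = predict_genotype_frequency(object, baf))
  ggplot2::ggplot(df, ggplot2::aes(.data$baf, .data$freq)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "BAF_overall", y = "expected genotype frequency",
                  title = object$genotype_id) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pooled_glmm PA_HEAT as a function of BAF
#' @param object a `pa_model`
#' @export
autoplot.pa_model <- function(object, ...) {
  baf <- seq(0, 0.35, length.out = 200)
  df <- tibble(baf = baf, pa_heat = predict_pa_heat(object, baf))
  ggplot2::ggplot(df, ggplot2::aes(.data$baf, .data$pa_heat)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "BAF_overall", y = "PA_HEAT") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_beta_glmm fixed effects with 95% Wald intervals
#' @param object a `cover_fit`
#' @export
autoplot.cover_fit <- function(object, ...) {
  df <- object$terms |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.15
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimate (logit scale, standardized covariates)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn rda_anova sites on the first two canonical axes
#' @param object an `rda_result`
#' @export
autoplot.rda_result <- function(object, ...) {
  sc <- object$site_scores
  df <- tibble(
    RDA1 = sc[, 1],
    RDA2 = if (ncol(sc) >= 2) sc[, 2] else 0
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$RDA1, .data$RDA2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("RDA: adj R2 = %.2f, p = %.3g",
                      object$adj_r2, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
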