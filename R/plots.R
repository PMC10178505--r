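# ggplot2 graphics for fitted surfaces and optimizer runs.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Convergence plot of an optimizer run
#'
#' For a genetic-algorithm result, plots best and population-mean fitness
#' against generation; for a grid-based response-surface optimum (no
#' history) a single-point summary is drawn.
#'
#' @param object An `opt_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' fits <- lapply(garlic_responses(), function(r) fit_rsm(garlic_runs(), r))
#' autoplot(ga_optimize(fits, seed = 1, max_generations = 30))
#' @export
autoplot.opt_result <- function(object, ...) {
  if (is.null(object$history)) {
    df <- tibble::tibble(generation = 1, kind = "best",
                         fitness = object$fitness)
  } else {
    df <- tidyr::pivot_longer(object$history, c("best", "mean"),
                              names_to = "kind", values_to = "fitness")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Generation", y = "Fitness (negated response sum)",
                  colour = NULL,
                  title = "Optimizer convergence") +
    ggplot2::theme_minimal()
}

#' Response-surface contour plot for two factors
#'
#' Evaluates a fitted quadratic over a grid of two factors (actual units),
#' holding the remaining factors at their centers (or at values supplied
#' via `at`), and draws a filled contour map — the familiar way of
#' inspecting interaction structure in extraction optimization.
#'
#' @param fit An `rsm_fit`.
#' @param x,y Factor names for the axes; default the first two factors.
#' @param at Named list/vector of actual values for the held factors;
#'   default their centers.
#' @param n Grid resolution per axis (default 101).
#' @return A ggplot object.
#' @examples
#' plot_rsm_surface(fit_rsm(garlic_runs(), "yield"), "amplitude", "time")
#' @export
plot_rsm_surface <- function(fit, x = NULL, y = NULL, at = NULL, n = 101) {
  stopifnot(inherits(fit, "rsm_fit"))
  factors <- fit$factors
  if (is.null(x)) x <- factors$name[1]
  if (is.null(y)) y <- factors$name[2]
  stopifnot(x %in% factors$name, y %in% factors$name, x != y)
  held <- setdiff(factors$name, c(x, y))
  at_vals <- stats::setNames(
    factors$center[match(held, factors$name)], held)
  if (!is.null(at)) at_vals[names(at)] <- unlist(at)

  fx <- factors[factors$name == x, ]
  fy <- factors[factors$name == y, ]
  grid <- expand.grid(
    seq(fx$low, fx$high, length.out = n),
    seq(fy$low, fy$high, length.out = n))
  names(grid) <- c(x, y)
  for (h in held) grid[[h]] <- at_vals[[h]]
  grid$response <- predict(fit, grid)

  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                     z = .data$response)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::labs(title = paste("Predicted", fit$response),
                  fill = fit$response) +
    ggplot2::theme_minimal()
}
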