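# Model-comparison statistics between predicted and experimental vectors.

#' Error statistics comparing predictions with experimental values
#'
#' Computes the seven comparison statistics used to rank surrogate models:
#' MSE, its root RMSE, the mean-normalized NMSE = MSE / mean(obs) and
#' NRMSE = RMSE / mean(obs), the average absolute deviation AAD, the mean
#' percentage error MPE = 100/n * sum(|pred - obs| / denominator), and
#' R-squared = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2).
#'
#' By default MPE is taken relative to the experimental values, the
#' convention that reproduces the published comparison table of the
#' bundled study to 4 decimals; `mpe_denominator = "predicted"` gives the
#' variant with the prediction in the denominator. Likewise the
#' occasionally seen R-squared variant that centers the *predictions*
#' around the experimental mean is available via
#' `r2_denominator = "predicted"`; the default is the standard form.
#'
#' @param predicted,experimental Numeric vectors of equal length >= 2.
#' @param mpe_denominator `"experimental"` (default) or `"predicted"`.
#' @param r2_denominator `"experimental"` (default) or `"predicted"`.
#' @return A one-row tibble: `n`, `mean_obs`, `mse`, `nmse`, `aad`, `mpe`,
#'   `rmse`, `nrmse`, `r2`. `mpe` is `NA` (with a warning) if any
#'   denominator value is zero.
#' @examples
#' model_metrics(c(2, 4), c(1, 5))
#' @export
model_metrics <- function(predicted, experimental,
                          mpe_denominator = c("experimental", "predicted"),
                          r2_denominator = c("experimental", "predicted")) {
  mpe_denominator <- match.arg(mpe_denominator)
  r2_denominator <- match.arg(r2_denominator)
  xp <- as.numeric(predicted)
  xa <- as.numeric(experimental)
  if (length(xp) != length(xa)) {
    stop("`predicted` and `experimental` must have the same length.",
         call. = FALSE)
  }
  n <- length(xp)
  if (n < 2) stop("Need at least 2 observations.", call. = FALSE)
  if (any(!is.finite(xp)) || any(!is.finite(xa))) {
    stop("Inputs must be finite.", call. = FALSE)
  }
  err <- xp - xa
  xm <- mean(xa)
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  aad <- mean(abs(err))
  den <- if (mpe_denominator == "predicted") xp else xa
  if (any(den == 0)) {
    warning("Zero value in the MPE denominator; MPE reported as NA.",
            call. = FALSE)
    mpe <- NA_real_
  } else {
    mpe <- 100 * mean(abs(err / den))
  }
  ss_den <- if (r2_denominator == "predicted") sum((xp - xm)^2)
            else sum((xa - xm)^2)
  r2 <- if (ss_den > 0) 1 - sum(err^2) / ss_den else NA_real_
  tibble::tibble(
    n = n, mean_obs = xm,
    mse = mse, nmse = mse / xm,
    aad = aad, mpe = mpe,
    rmse = rmse, nrmse = rmse / xm,
    r2 = r2
  )
}

#' Comparison-statistics grid for a run table with predicted columns
#'
#' For every response with a `<response>_<method>` predicted column,
#' computes [model_metrics()] against the experimental column, yielding
#' the response-by-method grid of the study's comparison table.
#'
#' @param run_table Run table holding experimental columns and
#'   `_rsm` / `_ann` predicted columns.
#' @param responses Response names; default [garlic_responses()] filtered
#'   to the columns present.
#' @param methods Method suffixes to look for (default `c("rsm", "ann")`).
#' @param ... Passed to [model_metrics()].
#' @return A long tibble with `response`, `method` and the metric columns.
#'   Missing method columns are skipped with a warning.
#' @examples
#' metric_table(garlic_runs())
#' @export
metric_table <- function(run_table, responses = NULL,
                         methods = c("rsm", "ann"), ...) {
  if (is.null(responses)) {
    responses <- intersect(garlic_responses(), names(run_table))
    if (!length(responses)) {
      pred_cols <- grep("_(rsm|ann)$", names(run_table), value = TRUE)
      responses <- unique(sub("_(rsm|ann)$", "", pred_cols))
    }
  }
  rows <- list()
  for (resp in responses) {
    for (m in methods) {
      col <- paste0(resp, "_", m)
      if (!col %in% names(run_table)) {
        warning("No predicted column '", col, "'; skipping.", call. = FALSE)
        next
      }
      met <- model_metrics(run_table[[col]], run_table[[resp]], ...)
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(tibble::tibble(response = resp, method = m), met)
    }
  }
  if (!length(rows)) {
    stop("No predicted columns found for any requested response.",
         call. = FALSE)
  }
  dplyr::bind_rows(rows)
}
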