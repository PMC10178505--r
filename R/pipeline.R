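# File-level pipeline steps: each takes CSV paths in, writes CSV reports
# out, and returns the result invisibly. A thin command-line dispatcher
# over these functions ships in inst/cli/uaeopt.R.

#' Generate a rotatable central composite design and write it to CSV
#'
#' @param factors Factor table, or path to a key-value factor config (see
#'   [read_factor_config()]).
#' @param n_center Center replicates (default 6).
#' @param out Output CSV path (`NULL` to skip writing).
#' @return The design tibble, invisibly.
#' @export
run_design <- function(factors = garlic_factors(), n_center = 6, out = NULL) {
  if (is.character(factors)) factors <- read_factor_config(factors)
  des <- ccd_design(factors, n_center = n_center)
  if (!is.null(out)) write_run_table(des, out)
  invisible(des)
}

#' Fit response-surface models for every response of a run table
#'
#' Writes a coefficient report (term x response estimates with p-values)
#' and one ANOVA report per response, mirroring the standard
#' coefficient-table layout.
#'
#' @param runs Run table tibble or CSV path.
#' @param factors Factor table (or config path); default resolved from the
#'   data.
#' @param responses Response columns; default auto-detected.
#' @param out_dir Directory for `coefficients.csv` and
#'   `anova_<response>.csv` (`NULL` to skip writing).
#' @return Named list of `rsm_fit` objects, invisibly.
#' @export
run_fit <- function(runs, factors = NULL, responses = NULL, out_dir = NULL) {
  if (is.character(factors)) factors <- read_factor_config(factors)
  if (is.character(runs)) {
    if (is.null(factors)) factors <- garlic_factors()
    runs <- read_run_table(runs, factors, responses)
  }
  factors <- resolve_factors(runs, factors)
  if (is.null(responses)) {
    skip <- c("run_id", "space_type", factors$name,
              "applied_energy", "calorimetric_energy")
    responses <- setdiff(names(runs)[vapply(runs, is.numeric, logical(1))],
                         skip)
    responses <- responses[!grepl("_(rsm|ann)$", responses)]
  }
  fits <- lapply(responses, function(r) fit_rsm(runs, r, factors))
  names(fits) <- responses

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    coef_tab <- quad_terms(factors$name)[, c("term", "label")]
    for (r in responses) {
      td <- tidy(fits[[r]])
      coef_tab[[r]] <- td$estimate
      coef_tab[[paste0(r, "_p")]] <- td$p.value
      readr::write_csv(rsm_anova(fits[[r]]),
                       file.path(out_dir, paste0("anova_", r, ".csv")),
                       progress = FALSE)
    }
    readr::write_csv(coef_tab, file.path(out_dir, "coefficients.csv"),
                     progress = FALSE)
  }
  invisible(fits)
}

#' Optimize a run table by response-surface or neural-surrogate route
#'
#' `method = "rsm"` fits quadratic models and optimizes their sum by grid
#' scan + polish; `method = "ann_ga"` trains one surrogate network per
#' response and runs the genetic algorithm on the negated response sum.
#'
#' @param runs Run table tibble or CSV path.
#' @param method `"rsm"` or `"ann_ga"`.
#' @param factors Factor table or config path.
#' @param responses Response columns; default auto-detected.
#' @param seed Seed for the neural/GA route.
#' @param bounds Optional bounds: coded box for `"rsm"`, actual box for
#'   `"ann_ga"` (defaults: coded/actual factorial region).
#' @param out_dir If given, writes `optimum.csv` and (for the GA) a
#'   `convergence.csv` generation log.
#' @param ... Further arguments to [train_mlp()] / [ga_optimize()].
#' @return An `opt_result`, invisibly.
#' @export
run_optimize <- function(runs, method = c("rsm", "ann_ga"), factors = NULL,
                         responses = NULL, seed = 1925, bounds = NULL,
                         out_dir = NULL, ...) {
  method <- match.arg(method)
  if (is.character(factors)) factors <- read_factor_config(factors)
  if (is.character(runs)) {
    if (is.null(factors)) factors <- garlic_factors()
    runs <- read_run_table(runs, factors, responses)
  }
  factors <- resolve_factors(runs, factors)
  fits <- run_fit(runs, factors, responses)
  responses <- names(fits)

  if (method == "rsm") {
    res <- optimize_rsm(unname(fits), bounds = bounds)
  } else {
    dots <- list(...)
    mlp_args <- dots[intersect(names(dots),
                               names(formals(train_mlp)))]
    ga_args <- dots[intersect(names(dots), names(formals(ga_optimize)))]
    nets <- lapply(responses, function(r) {
      do.call(train_mlp, c(list(runs, r, factors, seed = seed), mlp_args))
    })
    res <- do.call(ga_optimize,
                   c(list(nets, bounds = bounds, factors = factors,
                          seed = seed), ga_args))
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    opt_row <- dplyr::bind_cols(
      tibble::tibble(method = method, seed = seed,
                     fitness = res$fitness),
      res$best_actual,
      tibble::as_tibble(as.list(res$predictions)))
    readr::write_csv(opt_row, file.path(out_dir, "optimum.csv"),
                     progress = FALSE)
    if (!is.null(res$history)) {
      readr::write_csv(res$history, file.path(out_dir, "convergence.csv"),
                       progress = FALSE)
    }
  }
  invisible(res)
}

#' Compute the model-comparison report for a run table with predictions
#'
#' @param runs Run table tibble or CSV path (must hold `_rsm`/`_ann`
#'   predicted columns).
#' @param factors Factor table or config path.
#' @param out Output CSV path (`NULL` to skip writing).
#' @param ... Passed to [metric_table()].
#' @return The metric tibble, invisibly.
#' @export
run_compare <- function(runs, factors = NULL, out = NULL, ...) {
  if (is.character(factors)) factors <- read_factor_config(factors)
  if (is.character(runs)) {
    if (is.null(factors)) factors <- garlic_factors()
    runs <- read_run_table(runs, factors)
  }
  tab <- metric_table(runs, ...)
  if (!is.null(out)) readr::write_csv(tab, out, progress = FALSE)
  invisible(tab)
}

#' Simulate a synthetic run table and write it to CSV
#'
#' Uses the garlic-study scenario (published coefficients as ground truth)
#' unless surfaces are supplied.
#'
#' @param surfaces List of `true_surface` (default: [garlic_scenario()]).
#' @param design Design tibble (default: the scenario's design).
#' @param seed Master seed (default 1925).
#' @param out Output CSV path (`NULL` to skip writing).
#' @return The simulated run table, invisibly.
#' @export
run_simulate <- function(surfaces = NULL, design = NULL, seed = 1925,
                         out = NULL) {
  if (is.null(surfaces) || is.null(design)) {
    sc <- garlic_scenario()
    if (is.null(surfaces)) surfaces <- sc$surfaces
    if (is.null(design)) design <- sc$design
  }
  rt <- simulate_runs(design, surfaces, seed = seed)
  if (!is.null(out)) write_run_table(rt, out)
  invisible(rt)
}
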