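# Synthetic response surfaces: known-coefficient quadratics with Gaussian
# replicate noise over a CCD, closing the loop for property-based testing
# of the whole pipeline.

#' Define a ground-truth quadratic response surface
#'
#' A surface is the full second-order polynomial in coded factors with
#' known coefficients plus homoscedastic Gaussian noise. Coefficients are
#' named in b-notation matching [tidy()] output: `b0`, `b1`..`bk`,
#' interactions `bij` (i < j), quadratics `bii`; omitted terms default
#' to 0.
#'
#' @param response Response name.
#' @param coefficients Named numeric vector of coefficients in coded space.
#' @param factor_names Factor names, fixing k and the term order.
#' @param noise_sd Non-negative replicate noise standard deviation
#'   (response units).
#' @return An object of class `true_surface`.
#' @examples
#' s <- true_surface("y", c(b0 = 2, b1 = 1.5, b22 = -0.5),
#'                   factor_names = c("x1", "x2"))
#' @export
true_surface <- function(response, coefficients, factor_names,
                         noise_sd = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            noise_sd >= 0)
  terms <- quad_terms(factor_names)
  unknown <- setdiff(names(coefficients), terms$term)
  if (length(unknown)) {
    stop("Unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         "; expected ", paste(terms$term, collapse = ", "), ".",
         call. = FALSE)
  }
  full <- stats::setNames(rep(0, nrow(terms)), terms$term)
  full[names(coefficients)] <- coefficients
  structure(
    list(response = response, coefficients = full,
         factor_names = factor_names, noise_sd = noise_sd),
    class = "true_surface")
}

#' Evaluate a ground-truth surface (noise-free)
#'
#' @param surface A `true_surface`.
#' @param coded Data frame or matrix of coded points.
#' @return Numeric vector of exact polynomial values.
#' @export
surface_values <- function(surface, coded) {
  stopifnot(inherits(surface, "true_surface"))
  cm <- as.data.frame(coded)
  if (is.null(colnames(cm)) ||
      !all(surface$factor_names %in% colnames(cm))) {
    colnames(cm) <- surface$factor_names
  }
  as.vector(quad_model_matrix(cm[surface$factor_names]) %*%
              surface$coefficients)
}

#' Simulate a run table from ground-truth surfaces over a design
#'
#' Each response is its surface polynomial evaluated at the design's coded
#' points plus independent Gaussian noise (`sd = noise_sd`). One master
#' seed spawns a per-response substream derived from the response name, so
#' adding or reordering responses does not perturb the draws of the
#' others. Deterministic given `seed`.
#'
#' @param design A [ccd_design()] (or any run table with factor columns
#'   and a factor table attribute).
#' @param surfaces A `true_surface` or list of them sharing the design's
#'   factors.
#' @param seed Integer master seed.
#' @return A run table tibble: `run_id`, `space_type`, factor columns, one
#'   response column per surface; factor table attached as attribute.
#' @examples
#' des <- ccd_design(garlic_factors(), n_center = 6)
#' s <- true_surface("y", c(b0 = 10, b1 = 1), garlic_factors()$name,
#'                   noise_sd = 0.1)
#' simulate_runs(des, s, seed = 1)
#' @export
simulate_runs <- function(design, surfaces, seed = 1) {
  if (inherits(surfaces, "true_surface")) surfaces <- list(surfaces)
  factors <- attr(design, "factors")
  if (is.null(factors)) factors <- resolve_factors(design, NULL)
  coded <- code_values(design, factors, snap = TRUE)
  out <- design[intersect(c("run_id", "space_type", factors$name),
                          names(design))]
  if (!"run_id" %in% names(out)) out$run_id <- seq_len(nrow(out))
  for (s in surfaces) {
    if (!setequal(s$factor_names, factors$name)) {
      stop("Surface '", s$response, "' does not share the design's factors.",
           call. = FALSE)
    }
    mu <- surface_values(s, coded)
    sub_seed <- (seed + sum(utf8ToInt(s$response)) * 131L) %% .Machine$integer.max
    noise <- if (s$noise_sd > 0) {
      withr::with_seed(sub_seed, stats::rnorm(length(mu), 0, s$noise_sd))
    } else {
      rep(0, length(mu))
    }
    out[[s$response]] <- mu + noise
  }
  out <- tibble::as_tibble(out)
  attr(out, "factors") <- factors
  out
}

#' The garlic-study scenario as a synthetic ground truth
#'
#' The study's 3-factor rotatable design with 6 center replicates, and
#' four ground-truth surfaces whose coefficients are the published fitted
#' coefficients of the garlic-leaf study (see
#' `uae_fixture("rsm_coefficients")`). Default noise levels are the
#' residual RMSE of the published response-surface models (0.163 % yield,
#' 0.0353 mg GAE/g TPC, 0.1442 mg QE/g TFC, 0.5298 % antioxidant), i.e.
#' the replicate scatter the study itself exhibits.
#'
#' @param noise_sd Named vector overriding the per-response noise, or a
#'   single value recycled; `NULL` keeps the defaults above.
#' @return List with elements `design`, `surfaces` (list of four
#'   `true_surface`), and `factors`.
#' @examples
#' sc <- garlic_scenario()
#' rt <- simulate_runs(sc$design, sc$surfaces, seed = 1)
#' @export
garlic_scenario <- function(noise_sd = NULL) {
  factors <- garlic_factors()
  design <- ccd_design(factors, n_center = 6)
  coefs <- uae_fixture("rsm_coefficients")
  coef_rows <- coefs[grepl("^b", coefs$term), ]
  defaults <- c(yield = 0.1630, tpc = 0.0353, tfc = 0.1442,
                antioxidant = 0.5298)
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd))) {
      defaults[] <- noise_sd
    } else {
      defaults[names(noise_sd)] <- noise_sd
    }
  }
  surfaces <- lapply(names(defaults), function(r) {
    true_surface(r,
                 stats::setNames(coef_rows[[r]], coef_rows$term),
                 factor_names = factors$name,
                 noise_sd = unname(defaults[r]))
  })
  names(surfaces) <- names(defaults)
  list(design = design, surfaces = surfaces, factors = factors)
}
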