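# Real-coded genetic algorithm over surrogate models.

predict_surrogate <- function(s, data) {
  if (is.function(s)) s(data) else stats::predict(s, data)
}

#' Composite extraction fitness over a set of surrogates
#'
#' The optimization objective used throughout: the *negated* (weighted)
#' sum of the surrogate predictions, `f = -(Y1 + Y2 + ... )`, so that
#' minimizing `f` maximizes the combined extraction performance. The
#' canonical study form has exactly four surrogates (extraction yield,
#' total phenol content, total flavonoid content, antioxidant activity);
#' pass `weights` for the generalized variant.
#'
#' @param surrogates List of fitted predictors (`rsm_fit`, `mlp_fit`, or a
#'   function of a data frame) — exactly 4 unless `weights` is given.
#' @param data Data frame of points in actual factor units.
#' @param weights Optional objective weights, one per surrogate.
#' @return Numeric vector of fitness values (one per row of `data`).
#' @examples
#' fits <- lapply(garlic_responses(), function(r) fit_rsm(garlic_runs(), r))
#' composite_fitness(fits, data.frame(amplitude = 45, time = 10, ethanol = 50))
#' @export
composite_fitness <- function(surrogates, data, weights = NULL) {
  if (is.null(weights)) {
    if (length(surrogates) != 4) {
      stop("The default composite fitness expects exactly 4 surrogates ",
           "(one per response); pass `weights` for other counts.",
           call. = FALSE)
    }
    weights <- rep(1, 4)
  }
  stopifnot(length(weights) == length(surrogates))
  total <- 0
  for (i in seq_along(surrogates)) {
    total <- total + weights[i] * predict_surrogate(surrogates[[i]], data)
  }
  -total
}

#' Optimize surrogate models with a real-coded genetic algorithm
#'
#' Minimizes the composite fitness (see [composite_fitness()]) over a box
#' of actual factor values. Individuals are real vectors; each generation
#' applies rank-scaled roulette selection (rank r weighted 1/sqrt(r)),
#' scattered (uniform-mask) crossover on a `crossover_fraction` share of
#' the non-elite offspring, Gaussian mutation with a linearly decaying
#' standard deviation clipped to the bounds on the remainder, and elitism
#' on the `elite` best individuals, which makes the best fitness
#' non-increasing across generations. Stops at `max_generations` or when
#' the best fitness has improved by less than `stall_tol` over
#' `stall_generations` generations. Deterministic given `seed`.
#'
#' @param surrogates List of fitted predictors (see [composite_fitness()]).
#' @param bounds Actual-unit box: k x 2 matrix or list of `c(lo, hi)`,
#'   one per factor. Defaults to the factorial region of the factor table
#'   found on the first surrogate (e.g. amplitude 30-60 %, time 5-15 min,
#'   ethanol 40-60 % for the garlic study).
#' @param factors Factor table (for naming and coded reporting); default
#'   taken from the first surrogate that carries one.
#' @param pop_size Population size (default 50).
#' @param max_generations Generation budget (default 100).
#' @param crossover_fraction Share of non-elite offspring produced by
#'   crossover (default 0.8).
#' @param elite Number of elite individuals copied unchanged (default 2).
#' @param mutation_sd Initial mutation standard deviation in coded units
#'   (default 0.1); decays linearly to 0 over the generation budget.
#' @param seed Integer seed.
#' @param stall_generations,stall_tol Stall stopping rule (defaults 50,
#'   1e-6).
#' @param weights Optional fitness weights (see [composite_fitness()]).
#' @return An `opt_result`: `best_actual`, `best_coded` (when a factor
#'   table is available), `predictions` at the optimum, best `fitness`,
#'   population `mean_fitness` at the final generation, and a `history`
#'   tibble (generation, best, mean).
#' @examples
#' fits <- lapply(garlic_responses(), function(r) fit_rsm(garlic_runs(), r))
#' res <- ga_optimize(fits, seed = 1, max_generations = 30)
#' res$best_actual
#' @export
ga_optimize <- function(surrogates, bounds = NULL, factors = NULL,
                        pop_size = 50, max_generations = 100,
                        crossover_fraction = 0.8, elite = 2,
                        mutation_sd = 0.1, seed = 1,
                        stall_generations = 50, stall_tol = 1e-6,
                        weights = NULL) {
  if (is.null(factors)) {
    for (s in surrogates) {
      if (!is.function(s) && !is.null(s$factors)) { factors <- s$factors; break }
    }
  }
  if (is.null(factors)) {
    stop("Supply `factors` (none of the surrogates carries a factor table).",
         call. = FALSE)
  }
  check_factors(factors)
  k <- nrow(factors)
  default_bounds <- cbind(factors$center - factors$step,
                          factors$center + factors$step)
  bm <- normalize_bounds(bounds, k, default = default_bounds)
  stopifnot(pop_size > elite, elite >= 0, max_generations >= 1,
            crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_sd >= 0)

  lo <- bm[, 1]; hi <- bm[, 2]
  as_df <- function(P) {
    d <- as.data.frame(P)
    names(d) <- factors$name
    d
  }
  fit_of <- function(P) composite_fitness(surrogates, as_df(P), weights)

  run <- function() {
    P <- matrix(stats::runif(pop_size * k, rep(lo, each = pop_size),
                             rep(hi, each = pop_size)), pop_size, k)
    f <- fit_of(P)
    hist_best <- numeric(0)
    hist_mean <- numeric(0)
    n_off <- pop_size - elite
    n_x <- round(crossover_fraction * n_off)
    n_m <- n_off - n_x

    for (gen in seq_len(max_generations)) {
      ord <- order(f)
      P <- P[ord, , drop = FALSE]
      f <- f[ord]
      hist_best <- c(hist_best, f[1])
      hist_mean <- c(hist_mean, mean(f))
      if (gen >= stall_generations &&
          hist_best[gen - stall_generations + 1] - f[1] < stall_tol) {
        break
      }
      if (gen == max_generations) break

      w <- 1 / sqrt(seq_len(pop_size))   # rank scaling
      w <- w / sum(w)
      pick <- function(m) sample.int(pop_size, m, replace = TRUE, prob = w)

      children <- matrix(NA_real_, n_off, k)
      if (n_x > 0) {
        p1 <- P[pick(n_x), , drop = FALSE]
        p2 <- P[pick(n_x), , drop = FALSE]
        mask <- matrix(stats::runif(n_x * k) < 0.5, n_x, k)
        children[seq_len(n_x), ] <- ifelse(mask, p1, p2)
      }
      if (n_m > 0) {
        sd_gen <- mutation_sd * (1 - (gen - 1) / max_generations)
        sd_dim <- sd_gen * factors$step
        par <- P[pick(n_m), , drop = FALSE]
        noise <- matrix(stats::rnorm(n_m * k, 0, rep(sd_dim, each = n_m)),
                        n_m, k)
        children[n_x + seq_len(n_m), ] <- par + noise
      }
      children <- pmin(pmax(children, rep(lo, each = n_off)),
                       rep(hi, each = n_off))
      P <- rbind(P[seq_len(elite), , drop = FALSE], children)
      f <- c(f[seq_len(elite)], fit_of(children))
    }
    ord <- order(f)
    list(best = P[ord[1], ], best_f = f[ord[1]],
         mean_f = mean(f),
         history = tibble::tibble(generation = seq_along(hist_best),
                                  best = hist_best, mean = hist_mean))
  }
  res <- withr::with_seed(seed, run())

  best_actual <- tibble::as_tibble(as.list(stats::setNames(res$best,
                                                           factors$name)))
  best_coded <- code_values(best_actual, factors, snap = FALSE)
  preds <- vapply(surrogates, predict_surrogate, numeric(1),
                  data = best_actual)
  names(preds) <- vapply(seq_along(surrogates), function(i) {
    s <- surrogates[[i]]
    if (!is.function(s) && !is.null(s$response)) s$response
    else paste0("response", i)
  }, character(1))

  structure(
    list(method = "ga",
         best_actual = best_actual, best_coded = best_coded,
         predictions = preds,
         objective = -res$best_f,
         fitness = res$best_f,
         mean_fitness = res$mean_f,
         history = res$history,
         seed = seed),
    class = "opt_result")
}
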