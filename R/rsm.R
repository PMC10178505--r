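# Second-order response-surface modeling in coded variables.

# Term bookkeeping for the full quadratic in k coded variables, in the
# conventional reporting order: b0, linear b1..bk, interactions bij (i<j),
# quadratics bii.
quad_terms <- function(factor_names) {
  k <- length(factor_names)
  idx <- seq_len(k)
  pairs <- if (k > 1) utils::combn(idx, 2) else matrix(numeric(0), 2, 0)
  tibble::tibble(
    term = c("b0",
             paste0("b", idx),
             paste0("b", pairs[1, ], pairs[2, ]),
             paste0("b", idx, idx)),
    label = c("(Intercept)",
              factor_names,
              paste(factor_names[pairs[1, ]], factor_names[pairs[2, ]],
                    sep = ":"),
              paste0(factor_names, "^2")),
    kind = c("intercept",
             rep("linear", k),
             rep("interaction", ncol(pairs)),
             rep("quadratic", k))
  )
}

# Full quadratic model matrix from a matrix/data frame of coded values.
quad_model_matrix <- function(coded) {
  m <- as.matrix(as.data.frame(coded))
  k <- ncol(m)
  idx <- seq_len(k)
  cols <- list(rep(1, nrow(m)))
  for (i in idx) cols <- c(cols, list(m[, i]))
  if (k > 1) {
    pairs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(pairs))) {
      cols <- c(cols, list(m[, pairs[1, j]] * m[, pairs[2, j]]))
    }
  }
  for (i in idx) cols <- c(cols, list(m[, i]^2))
  X <- do.call(cbind, cols)
  colnames(X) <- quad_terms(colnames(m))$term
  X
}

#' Fit a second-order response-surface model in coded variables
#'
#' Ordinary least squares of one response on the full quadratic model in
#' coded factors: intercept, k linear, k(k-1)/2 interaction and k squared
#' terms (10 terms for k = 3). Factor columns are coded with
#' [code_values()] (snapping printed axial values to `-+alpha`) before the
#' model matrix is built, so coefficients are in response units per coded
#' unit. Per-term p-values are partial F tests of each single-df term in
#' the full model (equivalently the squared coefficient t tests).
#'
#' @param data Run table (data frame) holding the factor columns in actual
#'   units and the response column.
#' @param response Response column name.
#' @param factors Factor table (see [factor_spec()]); defaults to the
#'   attribute attached by [read_run_table()], else [garlic_factors()] when
#'   those columns are present.
#' @param snap_tol Snap tolerance for coding; see [snap_to_levels()].
#' @return An object of class `rsm_fit`: coefficients, fit statistics and
#'   the coded design, with [generics::tidy()] / [generics::glance()] /
#'   [stats::predict()] methods.
#' @examples
#' fit <- fit_rsm(garlic_runs(), "yield")
#' tidy(fit)
#' glance(fit)
#' @export
fit_rsm <- function(data, response, factors = NULL, snap_tol = 0.1) {
  factors <- resolve_factors(data, factors)
  if (!response %in% names(data)) {
    stop("Response column '", response, "' not found.", call. = FALSE)
  }
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("Response '", response, "' must be numeric and complete.",
         call. = FALSE)
  }
  k <- nrow(factors)
  n <- length(y)
  coded <- code_values(data, factors, snap = TRUE, tol = snap_tol)
  X <- quad_model_matrix(coded)
  p <- ncol(X)
  if (n < p) {
    stop("Need at least ", p, " runs to fit the full quadratic in ", k,
         " factors; got ", n, ".", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("Design is singular for the full quadratic; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  fitted <- as.vector(X %*% b)
  resid <- y - fitted
  sse <- sum(resid^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sse / sstot else NA_real_
  adj_r2 <- if (!is.na(r2) && n > p) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  sigma2 <- sse / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtX_inv) * sigma2, 0))
  tstat <- b / se
  pval <- 2 * stats::pt(abs(tstat), df = n - p, lower.tail = FALSE)

  terms <- quad_terms(factors$name)
  terms$estimate <- unname(b)
  terms$std.error <- unname(se)
  terms$statistic <- unname(tstat)
  terms$p.value <- unname(pval)

  structure(
    list(response = response, factors = factors, terms = terms,
         coefficients = stats::setNames(unname(b), terms$term),
         coded = coded, y = y, fitted = fitted, residuals = resid,
         n = n, p = p, r2 = r2, adj_r2 = adj_r2,
         sigma = sqrt(sigma2), snap_tol = snap_tol),
    class = "rsm_fit")
}

resolve_factors <- function(data, factors) {
  if (!is.null(factors)) return(check_factors(factors))
  att <- attr(data, "factors")
  if (!is.null(att)) return(check_factors(att))
  gf <- garlic_factors()
  if (all(gf$name %in% names(data))) return(gf)
  stop("Supply a factor table via `factors` (see factor_spec()).",
       call. = FALSE)
}

#' Predict from a fitted response-surface model
#'
#' Evaluates the full second-order polynomial at new points. Points are
#' given in actual factor units (default) and coded internally without
#' snapping, or directly in coded units with `coded = TRUE`.
#'
#' @param object An `rsm_fit`.
#' @param newdata Data frame with one column per factor; default: the
#'   training runs.
#' @param coded Is `newdata` already in coded units?
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @examples
#' fit <- fit_rsm(garlic_runs(), "yield")
#' predict(fit, data.frame(amplitude = 53, time = 13, ethanol = 50))
#' @export
predict.rsm_fit <- function(object, newdata = NULL, coded = FALSE, ...) {
  if (is.null(newdata)) {
    return(object$fitted)
  }
  cm <- if (coded) {
    m <- as.data.frame(newdata)
    if (is.null(colnames(m)) || !all(object$factors$name %in% colnames(m))) {
      colnames(m) <- object$factors$name
    }
    m[object$factors$name]
  } else {
    code_values(newdata, object$factors, snap = FALSE)
  }
  as.vector(quad_model_matrix(cm) %*% object$coefficients)
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf(
    "Second-order response-surface model for '%s' (%d runs, %d terms)\n",
    x$response, x$n, x$p))
  est <- x$terms$estimate
  names(est) <- x$terms$term
  print(round(est, 4))
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term` (b-notation),
#'   `label` (factor names), `kind`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.rsm_fit <- function(x, ...) {
  x$terms
}

#' One-row summary of a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return Tibble with `response`, `r.squared`, `adj.r.squared`, `sigma`,
#'   `lack.of.fit.p` (NA when the design has no replicates), `nobs`.
#' @export
glance.rsm_fit <- function(x, ...) {
  an <- rsm_anova(x)
  lof <- an$p.value[an$source == "lack_of_fit"]
  tibble::tibble(
    response = x$response,
    r.squared = x$r2,
    adj.r.squared = x$adj_r2,
    sigma = x$sigma,
    lack.of.fit.p = if (length(lof)) lof else NA_real_,
    nobs = x$n
  )
}

#' ANOVA with lack-of-fit decomposition for a response-surface fit
#'
#' Decomposes the total (mean-corrected) sum of squares into the model and
#' residual parts, and the residual further into lack of fit and pure
#' error. Pure error is the within-group sum of squares over groups of runs
#' with identical coded coordinates (the center replicates in a standard
#' rotatable design); lack of fit is the remainder, tested against pure
#' error with an F statistic. Per-term rows carry partial (type III) sums
#' of squares for each single-df term, tested against the residual mean
#' square. Without any replicated design point, the lack-of-fit rows are
#' reported as `NA` rather than raising an error.
#'
#' @param fit An `rsm_fit`.
#' @return A tibble with columns `source`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`. Sources: `model`, one row per non-intercept
#'   term, `residual`, `lack_of_fit`, `pure_error`, `total`.
#' @examples
#' rsm_anova(fit_rsm(garlic_runs(), "yield"))
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  y <- fit$y
  n <- fit$n
  p <- fit$p
  sse <- sum(fit$residuals^2)
  sstot <- sum((y - mean(y))^2)
  ssmod <- sstot - sse
  df_mod <- p - 1
  df_res <- n - p
  msres <- sse / df_res

  # partial SS for single-df terms: t^2 * MS_resid
  tt <- fit$terms[fit$terms$term != "b0", ]
  term_ss <- tt$statistic^2 * msres

  grp <- apply(as.matrix(fit$coded), 1, paste, collapse = "\r")
  counts <- table(grp)
  has_reps <- any(counts > 1)
  if (has_reps) {
    means <- tapply(y, grp, mean)
    sspe <- sum((y - means[grp])^2)
    df_pe <- n - length(counts)
    sslof <- max(sse - sspe, 0)
    df_lof <- df_res - df_pe
    if (df_lof > 0 && df_pe > 0 && sspe > 0) {
      f_lof <- (sslof / df_lof) / (sspe / df_pe)
      p_lof <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    } else {
      f_lof <- NA_real_
      p_lof <- NA_real_
    }
  } else {
    sspe <- NA_real_; df_pe <- NA_real_
    sslof <- NA_real_; df_lof <- NA_real_
    f_lof <- NA_real_; p_lof <- NA_real_
  }

  f_mod <- (ssmod / df_mod) / msres
  tibble::tibble(
    source = c("model", tt$term, "residual", "lack_of_fit", "pure_error",
               "total"),
    df = c(df_mod, rep(1, nrow(tt)), df_res, df_lof, df_pe, n - 1),
    sumsq = c(ssmod, term_ss, sse, sslof, sspe, sstot),
    meansq = c(ssmod / df_mod, term_ss, msres,
               if (is.na(df_lof) || df_lof == 0) NA_real_ else sslof / df_lof,
               if (is.na(df_pe) || df_pe == 0) NA_real_ else sspe / df_pe,
               NA_real_),
    statistic = c(f_mod, tt$statistic^2, NA_real_, f_lof, NA_real_, NA_real_),
    p.value = c(stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE),
                tt$p.value, NA_real_, p_lof, NA_real_, NA_real_)
  )
}

#' Locate the optimum of one or more response-surface models
#'
#' Maximizes a composite objective (by default the unweighted sum of all
#' model predictions, the same composite the genetic-algorithm route uses)
#' over a coded box by a dense grid scan followed by a local quadratic
#' polish with `L-BFGS-B`. With a single model this is ordinary
#' single-response optimization.
#'
#' @param fits An `rsm_fit` or list of them sharing one factor space.
#' @param bounds Coded box as a 2 x k matrix / list of `c(lo, hi)` per
#'   factor; default the factorial box `[-1, 1]^k`.
#' @param weights Objective weights, one per model; default all 1.
#' @param grid_n Grid points per axis for the scan (default 101).
#' @return An `opt_result` list: `best_coded`, `best_actual` (tibbles),
#'   `predictions` (named vector of per-response predictions at the
#'   optimum), `objective` (weighted sum), `fitness` (its negative),
#'   `method = "rsm"`.
#' @examples
#' fits <- lapply(garlic_responses(), function(r) fit_rsm(garlic_runs(), r))
#' optimize_rsm(fits)
#' @export
optimize_rsm <- function(fits, bounds = NULL, weights = NULL, grid_n = 101) {
  if (inherits(fits, "rsm_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "rsm_fit")))
  factors <- fits[[1]]$factors
  k <- nrow(factors)
  if (is.null(weights)) weights <- rep(1, length(fits))
  stopifnot(length(weights) == length(fits))
  bm <- normalize_bounds(bounds, k, default = cbind(rep(-1, k), rep(1, k)))

  obj <- function(cm) {
    # cm: matrix of coded points, one row per point
    vals <- 0
    X <- quad_model_matrix(cm)
    for (i in seq_along(fits)) {
      vals <- vals + weights[i] * as.vector(X %*% fits[[i]]$coefficients)
    }
    vals
  }

  axes <- lapply(seq_len(k), function(i) seq(bm[i, 1], bm[i, 2],
                                             length.out = grid_n))
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- factors$name
  vals <- obj(grid)
  start <- grid[which.max(vals), ]

  polish <- stats::optim(
    start,
    fn = function(x) -obj(matrix(x, 1, dimnames = list(NULL, factors$name))),
    method = "L-BFGS-B",
    lower = bm[, 1], upper = bm[, 2],
    control = list(factr = 1e1)
  )
  best <- polish$par
  best_coded <- tibble::as_tibble(as.list(stats::setNames(best, factors$name)))
  best_actual <- decode_values(best_coded, factors)
  preds <- vapply(fits, function(f) predict(f, best_coded, coded = TRUE),
                  numeric(1))
  names(preds) <- vapply(fits, `[[`, "", "response")
  structure(
    list(method = "rsm",
         best_coded = best_coded, best_actual = best_actual,
         predictions = preds,
         objective = sum(weights * preds),
         fitness = -sum(weights * preds),
         history = NULL),
    class = "opt_result")
}

normalize_bounds <- function(bounds, k, default) {
  if (is.null(bounds)) {
    bm <- default
  } else if (is.matrix(bounds)) {
    bm <- if (nrow(bounds) == 2 && ncol(bounds) == k) t(bounds) else bounds
  } else if (is.list(bounds)) {
    bm <- do.call(rbind, bounds)
  } else {
    stop("`bounds` must be a k x 2 matrix or a list of c(lo, hi).",
         call. = FALSE)
  }
  if (!is.matrix(bm) || nrow(bm) != k || ncol(bm) != 2) {
    stop("`bounds` must give one (lo, hi) pair per factor.", call. = FALSE)
  }
  if (any(bm[, 2] <= bm[, 1])) {
    stop("Each bound must satisfy lo < hi.", call. = FALSE)
  }
  bm
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("Optimum (%s):\n", x$method))
  print(as.data.frame(x$best_actual), row.names = FALSE)
  cat("Predicted responses:\n")
  print(round(x$predictions, 4))
  cat(sprintf("Composite objective = %.4f (fitness %.4f)\n",
              x$objective, x$fitness))
  invisible(x)
}
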