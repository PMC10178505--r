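# Feed-forward surrogate (k inputs, one tansig hidden layer, linear output)
# trained by Levenberg-Marquardt with validation-based early stopping.

#' Hyperbolic tangent sigmoid transfer function
#'
#' `tansig(n) = 2 / (1 + exp(-2 n)) - 1`, the hidden-layer transfer
#' function of the surrogate network (mathematically identical to
#' `tanh(n)`, written in its classic neural-toolbox form).
#'
#' @param n Numeric vector or matrix.
#' @return Same shape as `n`, values in (-1, 1).
#' @examples
#' tansig(c(-Inf, 0, 0.5, Inf))
#' @export
tansig <- function(n) {
  2 / (1 + exp(-2 * n)) - 1
}

#' Randomly partition runs into training / validation / test subsets
#'
#' Subset sizes are `round(n * fraction)`, adjusted by largest remainder so
#' they sum to `n` (for 20 runs and the 70/15/15 split: 14/3/3). The
#' partition is deterministic given `seed`.
#'
#' @param n Number of runs.
#' @param fractions Length-3 vector `(train, validation, test)` summing
#'   to 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List of disjoint index vectors `train`, `validation`, `test`
#'   covering `1:n` exactly once.
#' @examples
#' split_data(20, seed = 1)
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = NULL) {
  stopifnot(n >= 3)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three non-negative values summing to 1.",
         call. = FALSE)
  }
  draw <- function() sample.int(n)
  perm <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  base <- floor(n * fractions)
  rem <- n * fractions - base
  left <- n - sum(base)
  if (left > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  list(train = sort(perm[seq_len(base[1])]),
       validation = sort(perm[base[1] + seq_len(base[2])]),
       test = sort(perm[base[1] + base[2] + seq_len(base[3])]))
}

# parameter packing -----------------------------------------------------

mlp_pack <- function(U, th, w, to) c(as.vector(U), th, w, to)

mlp_unpack <- function(theta, H, k) {
  U <- matrix(theta[seq_len(H * k)], H, k)
  th <- theta[H * k + seq_len(H)]
  w <- theta[H * k + H + seq_len(H)]
  to <- theta[H * k + 2 * H + 1]
  list(U = U, th = th, w = w, to = to)
}

# forward pass on normalized inputs (rows of Xn); returns normalized outputs
mlp_forward_norm <- function(par, Xn) {
  Z <- tansig(Xn %*% t(par$U) + matrix(par$th, nrow(Xn), length(par$th),
                                       byrow = TRUE))
  as.vector(Z %*% par$w + par$to)
}

# min-max scaling to [-1, 1]
norm_to_pm1 <- function(x, lo, hi) {
  span <- hi - lo
  span[span == 0] <- 1
  sweep(sweep(x, 2, lo, `-`), 2, span / 2, `/`) - 1
}
denorm_from_pm1 <- function(xn, lo, hi) {
  if (is.matrix(xn)) {
    sweep(sweep((xn + 1) / 2, 2, hi - lo, `*`), 2, lo, `+`)
  } else {
    (xn + 1) * (hi - lo) / 2 + lo
  }
}

#' Train a tansig/linear feed-forward surrogate by Levenberg-Marquardt
#'
#' Fits a k-H-1 network (tansig hidden layer, linear output) to one
#' response. Inputs and target are min-max normalized to `[-1, 1]` over the
#' full dataset; the runs are split 70/15/15 into training, validation and
#' test subsets; and the training-subset squared error is minimized by
#' Levenberg-Marquardt: the damped normal equations
#' `(J'J + mu I) delta = -J'r` (on the mean-square scale, so `mu` keeps its
#' conventional magnitude for any training-set size) are solved each step,
#' with `mu` shrunk by `mu_decrease` on an accepted step and grown by
#' `mu_increase` until a step reduces the error. Weights start from the
#' Nguyen-Widrow rule (hidden units of magnitude `0.7 H^(1/k)` spread
#' across the normalized input cube). Training stops at `max_epochs`, when
#' the gradient norm falls below `gradient_floor`, when `mu` exceeds 1e10,
#' or after `max_val_failures` consecutive epochs of rising validation
#' error; the returned weights are those of the best validation epoch. A
#' split without validation points (e.g. `fractions = c(1, 0, 0)`) disables
#' early stopping and returns the final weights.
#'
#' @param data Run table with factor and response columns.
#' @param response Response column name.
#' @param factors Factor table; resolved as in [fit_rsm()].
#' @param hidden Hidden-layer size H (default 10).
#' @param seed Integer seed controlling the split and weight init.
#' @param fractions Train/validation/test fractions (default 0.70/0.15/0.15).
#' @param max_epochs Maximum LM epochs (default 1000); 0 returns the
#'   initial weights untouched.
#' @param mu_init,mu_increase,mu_decrease LM damping controls (defaults
#'   1e-3, 10, 0.1).
#' @param max_val_failures Consecutive validation failures tolerated
#'   (default 6).
#' @param gradient_floor Stop when the error-gradient norm falls below this
#'   (default 1e-7).
#' @return An object of class `mlp_fit` holding the weights (`U`, `th`,
#'   `w`, `to`), normalization ranges, the split, and a `report` tibble
#'   with per-subset MSE and R-squared (original response units),
#'   `best_epoch` and `stop_reason`.
#' @examples
#' fit <- train_mlp(garlic_runs(), "tpc", seed = 1)
#' fit$report
#' predict(fit, data.frame(amplitude = 45, time = 10, ethanol = 50))
#' @export
train_mlp <- function(data, response, factors = NULL, hidden = 10, seed = 1,
                      fractions = c(0.70, 0.15, 0.15), max_epochs = 1000,
                      mu_init = 1e-3, mu_increase = 10, mu_decrease = 0.1,
                      max_val_failures = 6, gradient_floor = 1e-7) {
  factors <- resolve_factors(data, factors)
  stopifnot(hidden >= 1, max_epochs >= 0, mu_init > 0,
            mu_increase > 1, mu_decrease > 0, mu_decrease < 1)
  y <- data[[response]]
  if (is.null(y)) stop("Response column '", response, "' not found.",
                       call. = FALSE)
  X <- as.matrix(data[factors$name])
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("Inputs and response must be finite.", call. = FALSE)
  }
  n <- nrow(X); k <- ncol(X); H <- hidden

  in_lo <- apply(X, 2, min); in_hi <- apply(X, 2, max)
  t_lo <- min(y); t_hi <- max(y)
  Xn <- norm_to_pm1(X, in_lo, in_hi)
  yn <- as.vector(norm_to_pm1(matrix(y), t_lo, t_hi))

  init <- withr::with_seed(seed, {
    idx <- split_data(n, fractions, seed = NULL)
    # Nguyen-Widrow initialization: hidden units with fixed magnitude
    # 0.7 H^(1/k) spread across the normalized input cube, so the active
    # regions of the tansig units tile the data instead of piling up at
    # the origin.
    mag <- 0.7 * H^(1 / k)
    U <- matrix(stats::runif(H * k, -1, 1), H, k)
    U <- U / sqrt(rowSums(U^2)) * mag
    th <- mag * seq(-1, 1, length.out = H) * sign(U[, 1])
    w <- stats::runif(H, -0.5, 0.5) / sqrt(H)
    to <- stats::runif(1, -0.5, 0.5)
    list(idx = idx, theta = mlp_pack(U, th, w, to))
  })
  idx <- init$idx
  theta <- init$theta
  tr <- idx$train; va <- idx$validation

  sse_of <- function(theta, rows) {
    par <- mlp_unpack(theta, H, k)
    r <- mlp_forward_norm(par, Xn[rows, , drop = FALSE]) - yn[rows]
    sum(r^2)
  }

  jac_resid <- function(theta) {
    par <- mlp_unpack(theta, H, k)
    Xt <- Xn[tr, , drop = FALSE]
    A <- Xt %*% t(par$U) + matrix(par$th, length(tr), H, byrow = TRUE)
    Z <- tansig(A)                       # n_tr x H
    yhat <- as.vector(Z %*% par$w + par$to)
    r <- yhat - yn[tr]
    D <- (1 - Z^2) * matrix(par$w, length(tr), H, byrow = TRUE)  # dy/dA
    JU <- matrix(0, length(tr), H * k)
    for (j in seq_len(k)) {
      JU[, (j - 1) * H + seq_len(H)] <- D * Xt[, j]
    }
    J <- cbind(JU, D, Z, 1)
    list(J = J, r = r)
  }

  mu <- mu_init
  val_fail <- 0
  best_theta <- theta
  # no validation subset -> early stopping disabled, final weights kept
  use_val <- length(va) > 0
  best_val <- if (use_val) sse_of(theta, va) / length(va) else Inf
  val_prev <- best_val
  best_epoch <- 0
  stop_reason <- "max_epochs"
  epoch <- 0
  sse_tr <- sse_of(theta, tr)

  while (epoch < max_epochs) {
    epoch <- epoch + 1
    jr <- jac_resid(theta)
    if (any(!is.finite(jr$r))) {
      cond <- structure(
        class = c("uaeopt_training_diverged", "error", "condition"),
        list(message = "Training diverged: non-finite residuals.",
             call = sys.call(-1), last_weights = best_theta))
      stop(cond)
    }
    # damped normal equations on the mean-square scale, so `mu` has the
    # conventional magnitude regardless of the training-set size
    n_tr <- length(tr)
    g <- crossprod(jr$J, jr$r) / n_tr
    if (sqrt(sum(g^2)) < gradient_floor) {
      stop_reason <- "gradient_floor"
      epoch <- epoch - 1
      break
    }
    JtJ <- crossprod(jr$J) / n_tr
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + mu * diag(ncol(JtJ)), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        sse_new <- sse_of(cand, tr)
        if (is.finite(sse_new) && sse_new < sse_tr) {
          theta <- cand
          sse_tr <- sse_new
          mu <- mu * mu_decrease
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * mu_increase
        if (mu > 1e10) break
      }
    }
    if (!accepted) {
      stop_reason <- "mu_max"
      break
    }
    if (use_val) {
      val_mse <- sse_of(theta, va) / length(va)
      if (val_mse < best_val) {
        best_val <- val_mse
        best_theta <- theta
        best_epoch <- epoch
      }
      # a failure is a validation epoch that did not improve on the
      # previous one; only an unbroken run of them stops training
      if (val_mse > val_prev) {
        val_fail <- val_fail + 1
        if (val_fail >= max_val_failures) {
          stop_reason <- "val_failures"
          break
        }
      } else {
        val_fail <- 0
      }
      val_prev <- val_mse
    }
  }

  final_theta <- if (use_val) best_theta else theta
  if (!use_val) best_epoch <- epoch
  par <- mlp_unpack(final_theta, H, k)
  model <- structure(
    list(U = par$U, th = par$th, w = par$w, to = par$to,
         in_lo = stats::setNames(in_lo, factors$name),
         in_hi = stats::setNames(in_hi, factors$name),
         t_lo = t_lo, t_hi = t_hi,
         hidden = H, response = response, factors = factors,
         split = idx, seed = seed),
    class = "mlp_fit")

  report <- dplyr::bind_rows(lapply(
    c(train = "train", validation = "validation", test = "test"),
    function(s) {
      rows <- idx[[s]]
      if (!length(rows)) {
        return(tibble::tibble(subset = s, n = 0L, mse = NA_real_,
                              r.squared = NA_real_))
      }
      pred <- predict(model, data[rows, , drop = FALSE])
      obs <- y[rows]
      sst <- sum((obs - mean(obs))^2)
      tibble::tibble(
        subset = s, n = length(rows),
        mse = mean((pred - obs)^2),
        r.squared = if (sst > 0) 1 - sum((pred - obs)^2) / sst else NA_real_)
    }))
  model$report <- report
  model$best_epoch <- best_epoch
  model$stop_reason <- stop_reason
  model$val_mse_norm <- if (use_val) sse_of(final_theta, va) / length(va)
                        else NA_real_
  model$train_mse_norm <- sse_of(final_theta, tr) / length(tr)
  model
}

#' Predict from a trained surrogate network
#'
#' Normalizes the inputs, applies the tansig hidden layer and linear
#' output, and maps the result back to response units:
#' `y = purelin(w %*% tansig(U x + th) + to)` on the `[-1, 1]` scale.
#'
#' @param object An `mlp_fit`.
#' @param newdata Data frame with the factor columns in actual units.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[names(object$in_lo)])
  Xn <- norm_to_pm1(X, object$in_lo, object$in_hi)
  yn <- mlp_forward_norm(object, Xn)
  denorm_from_pm1(yn, object$t_lo, object$t_hi)
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf(
    "Feed-forward surrogate for '%s': %d-%d-1 (tansig/linear), seed %s\n",
    x$response, ncol(x$U), x$hidden, format(x$seed)))
  cat(sprintf("best epoch %d, stopped on %s\n", x$best_epoch, x$stop_reason))
  print(x$report)
  invisible(x)
}

#' Tidy per-subset training report of a surrogate network
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return The `report` tibble (subset, n, mse, r.squared).
#' @export
tidy.mlp_fit <- function(x, ...) x$report

#' One-row summary of a surrogate network fit
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return Tibble with response, hidden size, all-data r.squared and mse,
#'   best epoch and stop reason.
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    hidden = x$hidden,
    best_epoch = x$best_epoch,
    stop_reason = x$stop_reason,
    train.mse = x$report$mse[x$report$subset == "train"],
    validation.mse = x$report$mse[x$report$subset == "validation"],
    test.mse = x$report$mse[x$report$subset == "test"]
  )
}

#' Save / load a surrogate network as a flat text file
#'
#' Plain-text serialization: dimensions, normalization ranges, then the
#' row-major weights at full double precision, so a reloaded network
#' reproduces `predict()` outputs exactly.
#'
#' @param fit An `mlp_fit`.
#' @param path File path.
#' @return `read_mlp()` returns the restored `mlp_fit` (without the
#'   training report); `write_mlp()` returns `fit` invisibly.
#' @examples
#' fit <- train_mlp(garlic_runs(), "tpc", seed = 1, max_epochs = 5)
#' tmp <- tempfile(fileext = ".txt")
#' write_mlp(fit, tmp)
#' fit2 <- read_mlp(tmp)
#' @export
write_mlp <- function(fit, path) {
  stopifnot(inherits(fit, "mlp_fit"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "uaeopt-mlp 1",
    paste("response", fit$response),
    paste("dims", ncol(fit$U), fit$hidden),
    paste("factors", paste(names(fit$in_lo), collapse = " ")),
    paste("in_lo", num(fit$in_lo)),
    paste("in_hi", num(fit$in_hi)),
    paste("t_range", num(c(fit$t_lo, fit$t_hi))),
    paste("U", num(t(fit$U))),
    paste("th", num(fit$th)),
    paste("w", num(fit$w)),
    paste("to", num(fit$to))
  )
  writeLines(lines, path)
  invisible(fit)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "uaeopt-mlp")) {
    stop("Not a uaeopt surrogate file.", call. = FALSE)
  }
  fields <- list()
  for (ln in lines[-1]) {
    sp <- strsplit(ln, " ", fixed = TRUE)[[1]]
    fields[[sp[1]]] <- sp[-1]
  }
  dims <- as.integer(fields$dims)
  k <- dims[1]; H <- dims[2]
  fnames <- fields$factors
  U <- matrix(as.numeric(fields$U), H, k, byrow = TRUE)
  tr <- as.numeric(fields$t_range)
  structure(
    list(U = U, th = as.numeric(fields$th), w = as.numeric(fields$w),
         to = as.numeric(fields$to),
         in_lo = stats::setNames(as.numeric(fields$in_lo), fnames),
         in_hi = stats::setNames(as.numeric(fields$in_hi), fnames),
         t_lo = tr[1], t_hi = tr[2],
         hidden = H, response = fields$response[1],
         factors = NULL, split = NULL, seed = NA),
    class = "mlp_fit")
}
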