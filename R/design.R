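#' Define an experimental factor by its center and step
#'
#' A factor is coded as `x = (actual - center) / step`, so the factorial
#' levels sit at coded -1/+1 (`center -+ step`) and the axial levels of a
#' rotatable design at `-+alpha`. All design and model functions in uaeopt
#' work on a *factor table* built by row-binding `factor_spec()` calls.
#'
#' @param name Factor name, used as a column name in design tables.
#' @param center Actual value at coded 0.
#' @param step Actual change per coded unit; must be positive.
#' @param units Unit label (documentation only).
#' @return A one-row tibble with columns `name`, `units`, `center`, `step`,
#'   `low`, `high` (`low`/`high` are the actual values at coded -+1).
#' @examples
#' factor_spec("amplitude", center = 45, step = 15, units = "%")
#' @export
factor_spec <- function(name, center, step, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0) {
    stop("`step` must be a single positive number (zero step makes coding undefined).",
         call. = FALSE)
  }
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  tibble::tibble(
    name = name, units = units,
    center = center, step = step,
    low = center - step, high = center + step
  )
}

#' Factor table of the garlic-leaf ultrasound extraction study
#'
#' Ultrasound amplitude (center 45 %, step 15 %), treatment time (center
#' 10 min, step 5 min) and ethanol concentration (center 50 %, step 10 %),
#' the three process factors of the bundled 20-run dataset (see
#' [garlic_runs()]).
#'
#' @return A three-row factor table (see [factor_spec()]).
#' @examples
#' garlic_factors()
#' @export
garlic_factors <- function() {
  dplyr::bind_rows(
    factor_spec("amplitude", center = 45, step = 15, units = "%"),
    factor_spec("time",      center = 10, step = 5,  units = "min"),
    factor_spec("ethanol",   center = 50, step = 10, units = "%")
  )
}

#' Axial distance of a rotatable central composite design
#'
#' Rotatability (constant prediction variance on spheres around the center)
#' requires the axial points at distance `alpha = (2^k)^(1/4)` from the
#' center, where `k` is the number of factors.
#'
#' @param k Number of factors.
#' @return The axial distance in coded units.
#' @examples
#' ccd_alpha(3) # 1.6818
#' @export
ccd_alpha <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  (2^k)^(1 / 4)
}

check_factors <- function(factors) {
  req <- c("name", "center", "step")
  if (!is.data.frame(factors) || !all(req %in% names(factors))) {
    stop("`factors` must be a factor table with columns name, center, step; ",
         "build it with factor_spec().", call. = FALSE)
  }
  if (anyDuplicated(factors$name)) {
    stop("Factor names must be unique.", call. = FALSE)
  }
  if (any(!is.finite(factors$step)) || any(factors$step <= 0)) {
    stop("All factor steps must be positive and finite.", call. = FALSE)
  }
  invisible(factors)
}

#' Build a rotatable central composite design
#'
#' Generates the 2^k factorial points (coded -+1), 2k axial points at coded
#' `-+alpha` with `alpha = (2^k)^(1/4)`, and `n_center` replicated center
#' points, in standard order: factorial block first (binary order), then
#' axial per factor (minus before plus), then the center replicates.
#' For the three-factor study design with six center replicates this yields
#' the canonical 20-run layout (8 factorial + 6 axial + 6 center).
#'
#' @param factors Factor table (see [factor_spec()]); 2 to 6 rows.
#' @param n_center Number of center replicates (>= 1).
#' @return A tibble of class `ccd_design` with columns `run_id`,
#'   `space_type` (`"factorial"`, `"axial"`, `"center"`) and one column per
#'   factor in actual units. The factor table and `alpha` are attached as
#'   attributes `"factors"` and `"alpha"`.
#' @examples
#' ccd_design(garlic_factors(), n_center = 6)
#' @export
ccd_design <- function(factors, n_center = 6) {
  check_factors(factors)
  k <- nrow(factors)
  if (k < 2 || k > 6) {
    stop("ccd_design() supports 2 to 6 factors, got ", k, ".", call. = FALSE)
  }
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 1) {
    stop("`n_center` must be a positive count.", call. = FALSE)
  }
  alpha <- ccd_alpha(k)

  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k))[, k:1, drop = FALSE])
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, center)
  colnames(coded) <- factors$name

  actual <- sweep(sweep(coded, 2, factors$step, `*`), 2, factors$center, `+`)
  out <- tibble::as_tibble(as.data.frame(actual))
  out <- dplyr::bind_cols(
    tibble::tibble(
      run_id = seq_len(nrow(coded)),
      space_type = rep(c("factorial", "axial", "center"),
                       c(2^k, 2 * k, n_center))
    ),
    out
  )
  structure(out,
            factors = factors, alpha = alpha, n_center = n_center,
            class = c("ccd_design", class(out)))
}

#' Convert actual factor values to coded units
#'
#' Applies `x = (actual - center) / step` per factor, optionally snapping
#' each coded value to the nearest nominal design level (see
#' [snap_to_levels()]). Snapping is on by default because published run
#' tables usually print rounded actual values at the axial runs (e.g. an
#' amplitude of 70 % for a true axial level of 70.23 %).
#'
#' @param data Data frame holding one column per factor, in actual units.
#' @param factors Factor table.
#' @param snap Snap coded values to nominal levels? Default `TRUE`.
#' @param tol Snap tolerance in coded units (see [snap_to_levels()]).
#' @return A tibble of coded values, one column per factor.
#' @examples
#' code_values(ccd_design(garlic_factors()), garlic_factors())
#' @export
code_values <- function(data, factors, snap = TRUE, tol = 0.1) {
  check_factors(factors)
  miss <- setdiff(factors$name, names(data))
  if (length(miss)) {
    stop("Factor column(s) missing from `data`: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(data[factors$name])
  coded <- sweep(sweep(m, 2, factors$center, `-`), 2, factors$step, `/`)
  if (snap) {
    alpha <- ccd_alpha(nrow(factors))
    coded[] <- apply(coded, 2, snap_to_levels, alpha = alpha, tol = tol)
  }
  tibble::as_tibble(as.data.frame(coded))
}

#' Convert coded factor values back to actual units
#'
#' Exact inverse of [code_values()] (without snapping):
#' `actual = center + step * coded`.
#'
#' @param coded Data frame or matrix of coded values, one column per factor.
#' @param factors Factor table.
#' @return A tibble of actual values.
#' @examples
#' decode_values(data.frame(amplitude = 0, time = 0, ethanol = -ccd_alpha(3)),
#'               garlic_factors())
#' @export
decode_values <- function(coded, factors) {
  check_factors(factors)
  m <- as.matrix(as.data.frame(coded))
  if (is.null(colnames(m))) colnames(m) <- factors$name
  m <- m[, factors$name, drop = FALSE]
  actual <- sweep(sweep(m, 2, factors$step, `*`), 2, factors$center, `+`)
  tibble::as_tibble(as.data.frame(actual))
}

#' Snap coded values to nominal design levels
#'
#' Any value within `tol` of a nominal level in `{-alpha, -1, 0, +1, +alpha}`
#' is replaced by that level; everything else is left unchanged. This
#' recovers exact axial coordinates from run tables whose actual values were
#' printed rounded: e.g. a printed treatment time of 18 min codes to 1.6
#' while the true axial level is 1.682. The default `tol = 0.1` covers the
#' worst such rounding in the bundled dataset (0.082 coded units on the time
#' axis) while staying well clear of genuine off-design points such as the
#' coded 0.533 of a 53 % amplitude.
#'
#' @param x Numeric vector of coded values.
#' @param alpha Axial distance; default the rotatable value for `k = 3`.
#' @param tol Non-negative snap tolerance in coded units.
#' @return Numeric vector with near-nominal values replaced.
#' @examples
#' snap_to_levels(c(1.6667, 0.5333, -1)) # 1.6818, 0.5333, -1
#' @export
snap_to_levels <- function(x, alpha = ccd_alpha(3), tol = 0.1) {
  stopifnot(is.numeric(x), tol >= 0)
  levels <- c(-alpha, -1, 0, 1, alpha)
  vapply(x, function(v) {
    if (!is.finite(v)) return(v)
    d <- abs(v - levels)
    if (min(d) <= tol) levels[which.min(d)] else v
  }, numeric(1))
}

#' @export
print.ccd_design <- function(x, ...) {
  k <- nrow(attr(x, "factors"))
  cat(sprintf(
    "Rotatable central composite design: %d factors, %d runs (alpha = %.4f)\n",
    k, nrow(x), attr(x, "alpha")))
  NextMethod()
}
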