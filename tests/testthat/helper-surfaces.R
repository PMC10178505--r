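# Shared fixtures built in code.

toy_factors <- function() {
  dplyr::bind_rows(
    factor_spec("x1", center = 0, step = 1),
    factor_spec("x2", center = 0, step = 1),
    factor_spec("x3", center = 0, step = 1)
  )
}

# Independent oracle for quadratic least squares: direct normal-equations
# solve on an explicitly constructed model matrix (no shared code with
# fit_rsm beyond base R).
normal_equations_fit <- function(coded, y) {
  m <- as.matrix(coded)
  X <- cbind(1, m[, 1], m[, 2], m[, 3],
             m[, 1] * m[, 2], m[, 1] * m[, 3], m[, 2] * m[, 3],
             m[, 1]^2, m[, 2]^2, m[, 3]^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

garlic_rsm_fits <- function() {
  rt <- garlic_runs()
  fits <- lapply(garlic_responses(), function(r) fit_rsm(rt, r))
  names(fits) <- garlic_responses()
  fits
}
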