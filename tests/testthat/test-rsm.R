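test_that("refitting the 20-run table reproduces the published coefficients", {
  fits <- garlic_rsm_fits()
  cf <- uae_fixture("rsm_coefficients")
  terms <- cf$term[grepl("^b", cf$term)]
  for (resp in garlic_responses()) {
    est <- fits[[resp]]$coefficients
    expect_equal(unname(est[terms]), cf[[resp]][match(terms, cf$term)],
                 tolerance = 0.011 / max(abs(est)), ignore_attr = TRUE)
    for (tm in terms) {
      expect_lt(abs(est[[tm]] - cf[[resp]][cf$term == tm]), 0.01)
    }
    expect_lt(abs(fits[[resp]]$r2 - cf[[resp]][cf$term == "r2"]), 0.005)
    expect_lt(abs(fits[[resp]]$adj_r2 - cf[[resp]][cf$term == "adj_r2"]),
              0.005)
  }
})

test_that("noiseless synthetic quadratics are recovered to 1e-8", {
  gf <- garlic_factors()
  des <- ccd_design(gf, n_center = 6)
  truth <- c(b0 = 2, b1 = 1.5, b2 = 0, b3 = 0, b12 = 0, b13 = -0.7,
             b23 = 0, b11 = 0, b22 = -0.5, b33 = 0.25)
  s <- true_surface("y", truth, gf$name, noise_sd = 0)
  rt <- simulate_runs(des, s, seed = 1)
  fit <- fit_rsm(rt, "y", gf)
  expect_equal(unname(fit$coefficients), unname(truth), tolerance = 1e-8)

  # independent oracle: direct normal-equations solve of the same system
  oracle <- normal_equations_fit(code_values(rt, gf), rt$y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-10)
})

test_that("degenerate and singular designs are handled explicitly", {
  gf <- garlic_factors()
  des <- ccd_design(gf, n_center = 6)
  rt <- des
  rt$y <- rep(7.5, nrow(des))
  fit <- fit_rsm(rt, "y", gf)
  expect_equal(unname(fit$coefficients[1]), 7.5, tolerance = 1e-10)
  expect_equal(max(abs(fit$coefficients[-1])), 0, tolerance = 1e-10)
  expect_true(is.na(fit$r2))

  # a factor duplicating another makes the quadratic singular
  dup <- dplyr::bind_rows(gf, factor_spec("amplitude2", center = 45, step = 15))
  bad <- des
  bad$amplitude2 <- bad$amplitude
  bad$y <- rnorm(nrow(bad))
  expect_error(fit_rsm(bad, "y", dup), "[Ss]ingular|collinear")
})

test_that("model predictions reproduce the published predicted column", {
  rt <- garlic_runs()
  fits <- garlic_rsm_fits()
  for (resp in garlic_responses()) {
    pred <- predict(fits[[resp]]) # fitted values, axial runs at +-alpha
    expect_lt(max(abs(pred - rt[[paste0(resp, "_rsm")]])), 0.02)
  }
  # intercept at the coded origin
  expect_equal(predict(fits$yield, data.frame(amplitude = 0, time = 0,
                                              ethanol = 0), coded = TRUE),
               unname(fits$yield$coefficients[["b0"]]))
  # axial run prediction (printed 31.68 at coded +alpha on amplitude)
  expect_equal(round(predict(fits$yield,
                             data.frame(amplitude = 2^(3 / 4), time = 0,
                                        ethanol = 0), coded = TRUE), 2),
               31.68)
  expect_equal(round(predict(fits$yield,
                             data.frame(amplitude = -1, time = -1,
                                        ethanol = -1), coded = TRUE), 2),
               28.84)
})

test_that("ANOVA decomposes sums of squares with lack of fit vs pure error", {
  fits <- garlic_rsm_fits()
  an <- rsm_anova(fits$yield)
  get <- function(src, col) an[[col]][an$source == src]

  # exact SS identity
  expect_equal(get("total", "sumsq"),
               get("model", "sumsq") + get("lack_of_fit", "sumsq") +
                 get("pure_error", "sumsq"),
               tolerance = 1e-8)
  expect_equal(get("residual", "sumsq"),
               get("lack_of_fit", "sumsq") + get("pure_error", "sumsq"),
               tolerance = 1e-12)
  expect_equal(get("residual", "df"),
               get("lack_of_fit", "df") + get("pure_error", "df"))
  expect_true(all(stats::na.omit(an$sumsq) >= 0))

  # pure error against a direct replicate-deviation oracle
  centers <- garlic_runs()$yield[garlic_runs()$space_type == "center"]
  expect_equal(get("pure_error", "sumsq"),
               sum((centers - mean(centers))^2), tolerance = 1e-12)
  expect_equal(get("pure_error", "df"), 5)
  expect_equal(get("lack_of_fit", "df"), 5)

  # published lack-of-fit p-values for all four responses
  lof_printed <- c(yield = 0.660, tpc = 0.336, tfc = 0.051,
                   antioxidant = 0.109)
  for (resp in names(lof_printed)) {
    an_r <- rsm_anova(fits[[resp]])
    p <- an_r$p.value[an_r$source == "lack_of_fit"]
    expect_lt(abs(p - lof_printed[[resp]]), 0.05)
  }
})

test_that("ANOVA handles replicate-free and perfect-fit designs gracefully", {
  gf <- garlic_factors()
  des <- ccd_design(gf, n_center = 1) # 15 runs, no replicates
  s <- true_surface("y", c(b0 = 5, b1 = 1, b22 = -2), gf$name,
                    noise_sd = 0.3)
  rt <- simulate_runs(des, s, seed = 2)
  an <- rsm_anova(fit_rsm(rt, "y", gf))
  expect_true(is.na(an$p.value[an$source == "lack_of_fit"]))

  # zero noise: SSE ~ 0, lack-of-fit statistic not applicable
  des6 <- ccd_design(gf, n_center = 6)
  rt0 <- simulate_runs(des6, true_surface("y", c(b0 = 5, b1 = 1), gf$name),
                       seed = 1)
  fit0 <- fit_rsm(rt0, "y", gf)
  expect_lt(sum(fit0$residuals^2), 1e-16)
  an0 <- rsm_anova(fit0)
  expect_true(is.na(an0$statistic[an0$source == "lack_of_fit"]))
})

test_that("adjusted R2 never exceeds R2 on noisy refits", {
  gf <- garlic_factors()
  des <- ccd_design(gf, n_center = 6)
  s <- true_surface("y", c(b0 = 10, b1 = 1, b23 = 0.5, b33 = -1), gf$name,
                    noise_sd = 0.5)
  for (seed in 1:10) {
    fit <- fit_rsm(simulate_runs(des, s, seed = seed), "y", gf)
    expect_lte(fit$adj_r2, fit$r2)
  }
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- garlic_rsm_fits()$tpc
  td <- tidy(fit)
  expect_equal(nrow(td), 10)
  expect_named(td, c("term", "label", "kind", "estimate", "std.error",
                     "statistic", "p.value"))
  expect_true(all(td$p.value[td$kind == "linear"] < 0.01))
  gl <- glance(fit)
  expect_equal(gl$nobs, 20)
  expect_equal(gl$r.squared, fit$r2)
})

test_that("grid-and-polish optimization finds quadratic optima", {
  gf <- garlic_factors()
  # single concave model with a known argmax at the coded origin on x1
  des <- ccd_design(gf, n_center = 6)
  rt <- simulate_runs(des, true_surface("y", c(b0 = 1, b11 = -1), gf$name),
                      seed = 1)
  res <- optimize_rsm(fit_rsm(rt, "y", gf))
  expect_equal(res$best_coded$amplitude, 0, tolerance = 1e-4)

  # composite optimum of the garlic fits: finer grid agrees within a step
  fits <- garlic_rsm_fits()
  r101 <- optimize_rsm(unname(fits), grid_n = 101)
  r201 <- optimize_rsm(unname(fits), grid_n = 201)
  expect_lt(max(abs(unlist(r101$best_coded) - unlist(r201$best_coded))),
            2 / 100)
  expect_equal(r101$objective, r201$objective, tolerance = 1e-6)
  expect_equal(r101$fitness, -sum(r101$predictions), tolerance = 1e-12)

  expect_error(optimize_rsm(unname(fits), bounds = list(c(1, -1), c(-1, 1),
                                                        c(-1, 1))),
               "lo < hi")
})

test_that("predictions at the stated process optimum match the study scale", {
  fits <- garlic_rsm_fits()
  opt_point <- data.frame(amplitude = 53, time = 13, ethanol = 50)
  expect_equal(predict(fits$yield, opt_point), 32.25, tolerance = 1e-3)
  expect_equal(predict(fits$tpc, opt_point), 9.94, tolerance = 1e-3)
})
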