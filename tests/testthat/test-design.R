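test_that("three-factor rotatable CCD has the canonical 20-run structure", {
  des <- ccd_design(garlic_factors(), n_center = 6)
  expect_equal(nrow(des), 20)
  expect_equal(as.vector(table(des$space_type)[c("factorial", "axial", "center")]),
               c(8, 6, 6))
  expect_equal(attr(des, "alpha"), 2^(3 / 4))
  expect_equal(des$run_id, 1:20)

  # axial actual values match the published design levels within 0.01
  # (the published time axials 1.60/18.40 were printed from alpha rounded
  # to 1.68; the exact alpha gives 1.591/18.409)
  ax <- des[des$space_type == "axial", ]
  expect_equal(sort(ax$amplitude[ax$time == 10 & ax$ethanol == 50]),
               c(19.77, 70.23), tolerance = 0.011 / 45)
  expect_equal(sort(ax$time[ax$amplitude == 45 & ax$ethanol == 50]),
               c(1.60, 18.40), tolerance = 0.011 / 1.6)
  expect_equal(sort(ax$ethanol[ax$amplitude == 45 & ax$time == 10]),
               c(33.18, 66.82), tolerance = 0.011 / 33.18)
})

test_that("CCD generalizes across k and degenerates correctly", {
  f2 <- dplyr::bind_rows(factor_spec("a", center = 0, step = 1),
                         factor_spec("b", center = 0, step = 1))
  des2 <- ccd_design(f2, n_center = 1)
  expect_equal(nrow(des2), 9)
  expect_equal(attr(des2, "alpha"), sqrt(2), tolerance = 1e-12)

  des1c <- ccd_design(garlic_factors(), n_center = 1)
  center <- des1c[des1c$space_type == "center", ]
  expect_equal(nrow(center), 1)
  expect_equal(unlist(code_values(center, garlic_factors())),
               c(amplitude = 0, time = 0, ethanol = 0))

  expect_error(ccd_design(factor_spec("a", center = 0, step = 1)),
               "2 to 6")
  f7 <- dplyr::bind_rows(lapply(letters[1:7], factor_spec,
                                center = 0, step = 1))
  expect_error(ccd_design(f7), "2 to 6")
})

test_that("coded columns of a full RCCD are symmetric and orthogonal", {
  for (k in 2:4) {
    fs <- dplyr::bind_rows(lapply(letters[seq_len(k)], factor_spec,
                                  center = 10, step = 2))
    des <- ccd_design(fs, n_center = 3)
    cm <- as.matrix(code_values(des, fs))
    expect_equal(colSums(cm), rep(0, k), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(crossprod(cm) - diag(diag(crossprod(cm))),
                 matrix(0, k, k), ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("coding maps actual values to coded units and back", {
  gf <- garlic_factors()
  expect_equal(code_values(data.frame(amplitude = 45, time = 10, ethanol = 50),
                           gf, snap = FALSE)$amplitude, 0)
  # the published rounded axial value codes to alpha after snapping
  expect_equal(code_values(data.frame(amplitude = 70.23, time = 10,
                                      ethanol = 50), gf)$amplitude,
               2^(3 / 4), tolerance = 1e-4)
  expect_equal(code_values(data.frame(amplitude = 53, time = 10, ethanol = 50),
                           gf)$amplitude, 8 / 15, tolerance = 1e-12)
  expect_equal(decode_values(data.frame(amplitude = 0, time = 0, ethanol = 0),
                             gf)$time, 10)
  expect_equal(decode_values(
    data.frame(amplitude = 0, time = 0, ethanol = -2^(3 / 4)), gf)$ethanol,
    33.18, tolerance = 5e-3)

  expect_error(factor_spec("bad", center = 1, step = 0), "positive")
})

test_that("decode is the exact inverse of code on random vectors", {
  gf <- garlic_factors()
  withr::with_seed(42, {
    for (i in 1:20) {
      actual <- tibble::tibble(amplitude = runif(5, 10, 80),
                               time = runif(5, 1, 20),
                               ethanol = runif(5, 20, 80))
      back <- decode_values(code_values(actual, gf, snap = FALSE), gf)
      expect_equal(as.data.frame(back), as.data.frame(actual),
                   tolerance = 1e-12)
    }
  })
})

test_that("snap_to_levels replaces only near-nominal coordinates", {
  a <- 2^(3 / 4)
  expect_equal(snap_to_levels(1.6667, tol = 0.05), a, tolerance = 1e-10)
  expect_equal(snap_to_levels(0.5333, tol = 0.05), 0.5333)
  expect_equal(snap_to_levels(-1), -1)
  # the published time axials print as 2/18 min (coded -+1.6), which only
  # the default tolerance recovers
  expect_equal(snap_to_levels(1.6, tol = 0.05), 1.6)
  expect_equal(snap_to_levels(1.6, tol = 0.1), a)
  expect_equal(snap_to_levels(c(0.2, -0.04), tol = 0.05), c(0.2, 0))
})
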