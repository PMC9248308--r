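test_that("model covariance matches direct membership summation", {
  d <- mpm_design()
  # pure common factor and pure noise
  expect_equal(unname(model_covariance(variance_components(1,0,0,0), d)),
               matrix(1, 4, 4))
  expect_equal(unname(model_covariance(variance_components(0,0,0,1), d)),
               diag(4))
  vc <- variance_components(0.6, 0.1, 0.1, 0.2)
  Sigma <- model_covariance(vc, d)
  expect_equal(unname(diag(Sigma)), rep(1, 4))
  expect_equal(Sigma["D1M1", "D1M2"], 0.8)   # same day + same session
  expect_equal(Sigma["D2M1", "D2M2"], 0.7)   # same day only
  expect_equal(Sigma["D1M1", "D2M2"], 0.6)   # cross-day
  # all 10 unique entries against the per-entry membership oracle
  for (i in 1:4) for (j in i:4)
    expect_equal(Sigma[i, j], oracle_cov_entry(vc, d, i, j))
  # PSD for random non-negative components
  set.seed(11)
  for (r in 1:20) {
    v <- variance_components(runif(1), runif(1), runif(1), runif(1))
    ev <- eigen(model_covariance(v, d), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > -1e-12))
  }
  expect_error(variance_components(-0.1, 0, 0, 1), "non-negative")
})

test_that("rescaling gives proportions summing to one, idempotently and scale-free", {
  r <- rescale_components(variance_components(2, 0, 1, 1))
  expect_equal(unclass(r), c(var_t = 0.5, var_d = 0, var_s = 0.25,
                             var_e = 0.25))
  expect_equal(sum(r), 1)
  expect_equal(rescale_components(r), r)      # idempotence
  v <- variance_components(0.3, 0.05, 0.15, 0.5)
  expect_equal(rescale_components(variance_components(3, 0.5, 1.5, 5)),
               rescale_components(v))          # scale invariance
  expect_error(rescale_components(variance_components(0, 0, 0, 0)), "zero")
})

test_that("ICC is the true-score share of total variance", {
  expect_equal(icc(variance_components(0.883, 0.000, 0.003, 0.114)), 0.883)
  expect_equal(icc(variance_components(0, 0.1, 0.2, 0.7)), 0)
  expect_equal(icc(variance_components(1, 1, 1, 1)), 0.25)
  expect_error(icc(variance_components(0, 0, 0, 0)), "zero")
})

test_that("effective error is the precision-weighted composite variance", {
  d <- mpm_design()
  # residual-only: var_e / k
  expect_equal(effective_error(variance_components(0.5, 0, 0, 0.272), d),
               0.272 / 4)
  # error-free design
  expect_equal(effective_error(variance_components(1, 0, 0, 0), d), 0)
  # session + residual structure against the matrix-inverse oracle
  vc <- variance_components(0.4, 0, 0.1, 0.2)
  err <- model_covariance(variance_components(0, 0, 0.1, 0.2), d)
  expect_equal(effective_error(vc, d), 1 / sum(solve(err)))
  expect_equal(effective_error(vc, d), 0.0857142857, tolerance = 1e-8)
  # day + session + residual, arbitrary values, same oracle
  vc2 <- variance_components(0.3, 0.15, 0.07, 0.11)
  err2 <- model_covariance(variance_components(0, 0.15, 0.07, 0.11), d)
  expect_equal(effective_error(vc2, d), 1 / sum(solve(err2)))
})

test_that("ICC2 reproduces the printed construct-level reliabilities", {
  d <- mpm_design()
  # rows of the reference decomposition table with pure residual error
  cases <- list(list(t = 0.562, e = 0.438, icc2 = 0.837),
                list(t = 0.424, e = 0.575, icc2 = 0.747))
  for (cs in cases) {
    vc <- rescale_components(variance_components(cs$t, 0, 0, cs$e))
    expect_equal(round(icc2(vc, d), 3), cs$icc2)
  }
  # limits and monotonicity
  expect_equal(icc2(variance_components(0.7, 0, 0, 0), d), 1)
  e_grid <- seq(0.05, 2, by = 0.05)
  vals <- vapply(e_grid, function(e)
    icc2(variance_components(0.5, 0.05, 0.05, e), d), numeric(1))
  expect_true(all(diff(vals) < 0))   # non-increasing in var_e
})
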