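test_that("model log-likelihood matches a direct density evaluation", {
  d <- mpm_design()
  # single person, identity covariance, means at the data: normal constant
  y1 <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("P1", d$occasion))
  ll <- iced_loglik(reliability_data(y1, d),
                    variance_components(0, 0, 0, 1), means = y1[1, ])
  expect_equal(ll, -2 * log(2 * pi))
  # random 5-person datasets at random component values
  set.seed(42)
  for (r in 1:10) {
    dat <- make_dataset(n = 5, seed = 100 + r)
    vc <- variance_components(runif(1, 0.1, 1), runif(1, 0, 0.5),
                              runif(1, 0, 0.5), runif(1, 0.1, 1))
    mu <- colMeans(dat) + rnorm(4, 0, 0.2)
    expect_equal(iced_loglik(dat, vc, means = mu),
                 oracle_mvn_loglik(unclass(dat), mu,
                                   model_covariance(vc, d)),
                 tolerance = 1e-8)
    # sample means are the ML means
    expect_gte(iced_loglik(dat, vc),
               iced_loglik(dat, vc, means = mu))
  }
  expect_error(iced_loglik(make_dataset(n = 4, seed = 1),
                           variance_components(0, 0, 0, 0)), "singular")
})

test_that("estimates recover simulated proportions and respect bounds", {
  truth <- c(0.6, 0.1, 0.1, 0.2)
  dat <- make_dataset(n = 2000, props = truth, seed = 202)
  fit <- iced(dat)
  expect_true(fit$converged)
  expect_lt(max(abs(unclass(fit$proportions) - truth)), 0.03)
  expect_equal(sum(fit$proportions), 1, tolerance = 1e-10)
  expect_equal(fit$icc, fit$proportions[["var_t"]], tolerance = 1e-10)
  # occasion means at their sample (ML) values
  expect_equal(fit$means, colMeans(unclass(dat)))
  expect_error(iced(make_dataset(n = 2, seed = 1)), "3 persons")
})

test_that("constant-within-person data pins error components at the bound", {
  d <- mpm_design()
  set.seed(9)
  base <- rnorm(12, 10, 1)
  y <- matrix(base, 12, 4)        # identical occasions, persons differ
  fit <- iced(reliability_data(y, d))
  comps <- unclass(fit$components)
  expect_equal(unname(comps[c("var_d", "var_s", "var_e")]),
               rep(fit$lower_bound, 3), tolerance = 1e-6)
  expect_equal(comps[["var_t"]], stats::var(base) * 11 / 12,
               tolerance = 0.01)
  expect_gt(fit$icc, 0.999)
})

test_that("ML solution dominates a coarse grid over the bounded simplex", {
  d <- mpm_design()
  dat <- make_dataset(n = 4, seed = 77)
  fit <- iced(dat)
  ll_hat <- fit$loglik
  grid <- seq(0.05, 1.5, length.out = 6)
  worse <- 0
  for (t in grid) for (dd in grid[1:3]) for (s in grid[1:3]) for (e in grid) {
    ll <- oracle_profile_loglik(unclass(dat),
                                variance_components(t, dd, s, e), d)
    expect_lte(ll, ll_hat + 1e-6)
  }
})

test_that("proportions, ICC, ICC2 and tests are affine invariant", {
  dat <- make_dataset(n = 200, seed = 305)
  d <- attr(dat, "design")
  a <- 3.7; b <- -12
  dat2 <- reliability_data(a * unclass(dat) + b, d)
  f1 <- iced(dat); f2 <- iced(dat2)
  # exact invariance requires an interior solution: with an absolute lower
  # bound, at-bound components carry a (tiny) scale-dependent floor
  expect_true(all(unclass(f1$components) > 2 * f1$lower_bound))
  expect_equal(unclass(f1$proportions), unclass(f2$proportions),
               tolerance = 1e-6)
  expect_equal(f1$icc, f2$icc, tolerance = 1e-6)
  expect_equal(f1$icc2, f2$icc2, tolerance = 1e-6)
  expect_equal(fit_stats(f1)$rmsea, fit_stats(f2)$rmsea, tolerance = 1e-6)
  for (cmp in c("var_t", "var_d", "var_s"))
    expect_equal(lrt_component(f1, cmp)$delta_chisq,
                 lrt_component(f2, cmp)$delta_chisq, tolerance = 1e-5)
  # raw components scale with a^2
  expect_equal(unclass(f2$components), unclass(f1$components) * a^2,
               tolerance = 1e-4)
})

test_that("standardized fitting divides by the grand SD before estimating", {
  dat <- make_dataset(n = 50, total = 4e-4, means = rep(0.874, 4),
                      seed = 404)
  d <- attr(dat, "design")
  f_std <- iced(dat, standardize = TRUE)
  f_man <- iced(reliability_data(unclass(dat) / sd(as.vector(unclass(dat))),
                                 d))
  expect_equal(unclass(f_std$proportions), unclass(f_man$proportions),
               tolerance = 1e-8)
  expect_equal(f_std$icc2, f_man$icc2, tolerance = 1e-8)
  # on unit-scale data (bound negligible) standardization changes nothing
  big <- make_dataset(n = 50, total = 1, seed = 405)
  expect_equal(unclass(iced(big)$proportions),
               unclass(iced(big, standardize = TRUE)$proportions),
               tolerance = 1e-5)
})

test_that("model-object methods are coherent", {
  dat <- make_dataset(n = 30, seed = 55)
  fit <- iced(dat)
  expect_equal(unname(coef(fit, "proportions")),
               unname(unclass(fit$proportions)))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(fitted(fit) + residuals(fit), unclass(dat),
               ignore_attr = TRUE)
  # BLUP true scores shrink toward the grand mean relative to person means
  pm <- rowMeans(unclass(dat))
  ts <- predict(fit)
  expect_true(all(abs(ts - mean(pm)) <= abs(pm - mean(pm)) + 1e-8))
  sims <- simulate(fit, nsim = 2, seed = 8)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "reliability_data")
  expect_identical(dim(sims[[1]]), dim(dat))
  expect_output(print(summary(fit)), "Component tests")
})
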