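test_that("joint log-linear fit is exact on noiseless mono-exponential decay", {
  me <- simulate_multiecho(intercepts = c(T1w = 1000, PDw = 800, MTw = 600),
                           r2star = 20, noise_sd = 0)
  fit <- estatics_fit(me)
  expect_equal(fit$r2star, 20, tolerance = 1e-9)
  expect_equal(unname(fit$intercepts), c(1000, 800, 600),
               tolerance = 1e-9)
  expect_lt(fit$residual_sse, 1e-18)
  # exact for arbitrary positive parameter sets
  set.seed(6)
  for (r in 1:10) {
    ints <- runif(3, 100, 5000); names(ints) <- c("T1w", "PDw", "MTw")
    r2 <- runif(1, 5, 60)
    f <- estatics_fit(simulate_multiecho(ints, r2, 0))
    expect_equal(f$r2star, r2, tolerance = 1e-9)
    expect_equal(unname(f$intercepts), unname(ints), tolerance = 1e-8)
  }
})

test_that("two echoes of one contrast give the closed-form slope", {
  te <- c(3, 10); s <- c(900, 500)
  f <- estatics_fit(multi_echo_set(list(PDw = list(te_ms = te, signal = s))))
  expect_equal(f$r2star, log(s[1] / s[2]) / ((te[2] - te[1]) / 1000),
               tolerance = 1e-10)
})

test_that("noisy joint fit equals a generic stacked OLS oracle", {
  me <- simulate_multiecho(r2star = 25, noise_sd = 15, seed = 99)
  fit <- estatics_fit(me)
  te <- unlist(lapply(me, `[[`, "te_ms")) / 1000
  sig <- unlist(lapply(me, `[[`, "signal"))
  grp <- factor(rep(names(me), lengths(lapply(me, `[[`, "te_ms"))),
                levels = names(me))
  ref <- lm(log(sig) ~ 0 + grp + te)
  expect_equal(fit$r2star, -unname(coef(ref)["te"]), tolerance = 1e-10)
  expect_equal(unname(fit$intercepts),
               unname(exp(coef(ref)[paste0("grp", names(me))])),
               tolerance = 1e-10)
  expect_equal(fit$residual_sse, sum(resid(ref)^2), tolerance = 1e-10)
})

test_that("joint fit beats per-contrast fits averaged to a common slope", {
  me <- simulate_multiecho(r2star = 18, noise_sd = 10, seed = 17)
  joint <- estatics_fit(me)
  slopes <- vapply(me, function(ct)
    unname(coef(lm(log(ct$signal) ~ I(ct$te_ms / 1000)))[2]), numeric(1))
  forced <- mean(-slopes)
  sse_forced <- sum(vapply(names(me), function(nm) {
    ct <- me[[nm]]
    # best intercept given the forced common slope
    res <- log(ct$signal) + forced * ct$te_ms / 1000
    sum((res - mean(res))^2)
  }, numeric(1)))
  expect_lte(joint$residual_sse, sse_forced + 1e-12)
})

test_that("fitting guards reject unusable echo sets", {
  expect_error(estatics_fit(multi_echo_set(
    list(PDw = list(te_ms = c(2, 4), signal = c(10, -1))))), "positive")
  expect_error(multi_echo_set(list(PDw = list(te_ms = c(4, 2),
                                              signal = c(1, 2)))),
               "increasing")
  expect_error(estatics_fit(multi_echo_set(
    list(PDw = list(te_ms = 3, signal = 5)))), "at least 2")
})

test_that("Ernst signal has the closed form and its limits", {
  expect_equal(ernst_signal(1000, r1 = 1, flip_angle = 90, tr_ms = 24.5),
               1000 * (1 - exp(-0.0245)), tolerance = 1e-12)
  expect_equal(ernst_signal(1000, 1, 90, 24.5), 24.2024, tolerance = 1e-4)
  expect_lt(ernst_signal(1000, 1, 1e-6, 24.5), 1e-3)       # alpha -> 0
  expect_equal(ernst_signal(1000, 1, 30, 1e7), 1000 * sin(pi / 6),
               tolerance = 1e-6)                            # TR -> inf
  expect_error(ernst_signal(1, -1, 30, 24.5), "positive")
  expect_error(ernst_signal(1, 1, 120, 24.5), "flip_angle")
})

test_that("dual-flip-angle inversion recovers R1 across the plausible range", {
  # includes the gray/white-matter levels 0.622 and 0.967 1/s
  for (r1 in c(seq(0.2, 2, by = 0.2), 0.622, 0.967)) {
    sl <- ernst_signal(900, r1, 6, 24.5)
    sh <- ernst_signal(900, r1, 21, 24.5)
    est <- dual_flip_angle_r1(sl, sh)
    expect_equal(est$r1, r1, tolerance = 1e-6)
    expect_equal(est$amplitude, 900, tolerance = 1e-4)
  }
  # ratio invariance: common scaling moves only the amplitude
  sl <- ernst_signal(900, 0.7, 6, 24.5)
  sh <- ernst_signal(900, 0.7, 21, 24.5)
  a <- dual_flip_angle_r1(sl, sh); b <- dual_flip_angle_r1(3 * sl, 3 * sh)
  expect_equal(a$r1, b$r1, tolerance = 1e-10)
  expect_equal(b$amplitude, 3 * a$amplitude, tolerance = 1e-6)
  # ratio outside the attainable range of the Ernst model has no root
  expect_error(dual_flip_angle_r1(10 * sh, sh), "no R1 root")
  # the small-angle approximation is close but not exact
  appr <- dual_flip_angle_r1_approx(sl, sh)
  expect_equal(appr$r1, 0.7, tolerance = 0.05)
  expect_gt(abs(appr$r1 - 0.7), 1e-6)
})

test_that("PD calibration forces the white-matter mean to 69 p.u.", {
  set.seed(12)
  pd <- array(runif(64, 60, 140), c(4, 4, 4))
  wm <- array(FALSE, c(4, 4, 4)); wm[1:2, , ] <- TRUE
  cal <- calibrate_pd(pd, wm)
  expect_equal(mean(cal[wm]), 69, tolerance = 1e-12)
  # idempotence and commuting with positive rescaling
  expect_equal(as.vector(calibrate_pd(cal, wm)), as.vector(cal),
               tolerance = 1e-12)
  expect_equal(as.vector(calibrate_pd(pd * 5, wm)), as.vector(cal),
               tolerance = 1e-12)
  expect_error(calibrate_pd(pd, array(FALSE, c(4, 4, 4))), "empty")
})
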