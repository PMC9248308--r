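#' Likelihood-ratio test of a variance component
#'
#' Compares the full decomposition against the null model in which one of
#' the true-score, day or session variances is fixed at zero. The test
#' statistic is twice the log-likelihood difference (clipped at zero; the
#' bound-constrained null can in principle tie the full model). The
#' default p-value uses the naive one-degree-of-freedom chi-square upper
#' tail; because the null value lies on the boundary of the parameter
#' space, a 50:50 mixture of a point mass at zero and chi-square(1) is
#' available as `mixture = TRUE`.
#'
#' @param fit an [iced()] fit (the full model), or a [reliability_data()]
#'   which is fitted first.
#' @param component one of `"var_t"`, `"var_d"`, `"var_s"`. The residual
#'   variance cannot be tested this way (its null model has no orthogonal
#'   error left); use [wald_residual()].
#' @param mixture use the boundary-corrected mixture p-value.
#' @param ... passed to [iced()] when refitting.
#' @return A list of class `iced_test`: `component`, `delta_chisq`, `df`,
#'   `p_value`, plus both fitted models.
#' @export
lrt_component <- function(fit, component = c("var_t", "var_d", "var_s"),
                          mixture = FALSE, ...) {
  component <- match.arg(component, c("var_t", "var_d", "var_s", "var_e"))
  if (component == "var_e")
    stop("the residual variance has no estimable null model; ",
         "use wald_residual()")
  if (inherits(fit, "reliability_data")) fit <- iced(fit, ...)
  stopifnot(inherits(fit, "iced"))
  if (!fit$free[[component]])
    stop("component ", component, " is not free in the full model")
  null_free <- names(fit$free)[fit$free & names(fit$free) != component]
  null_fit <- iced(fit$data, design = fit$design,
                   lower_bound = fit$lower_bound, free = null_free,
                   standardize = fit$standardize)
  if (!fit$converged || !null_fit$converged)
    warning("LRT based on a non-converged fit; interpret with caution")
  delta <- max(0, 2 * (fit$loglik - null_fit$loglik))
  p <- stats::pchisq(delta, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (delta <= 0) 1 else 0.5 * p
  structure(list(component = component, delta_chisq = delta, df = 1L,
                 p_value = p, full = fit, null = null_fit,
                 mixture = mixture),
            class = "iced_test")
}

#' Wald test of the residual error variance
#'
#' Tests whether the residual variance differs from zero using the ML
#' estimate and its standard error from the inverse observed information:
#' statistic (estimate / SE)^2 against chi-square(1).
#'
#' @param fit an [iced()] fit.
#' @param ... unused.
#' @return A list of class `iced_test` with `delta_chisq` (the Wald
#'   statistic), `df`, `p_value`, `estimate` and `se`.
#' @export
wald_residual <- function(fit, ...) {
  stopifnot(inherits(fit, "iced"))
  if (!fit$free[["var_e"]])
    stop("residual variance is not a free parameter in this fit")
  if (!fit$converged)
    warning("Wald test on a non-converged fit; interpret with caution")
  V <- vcov(fit)
  se2 <- V["var_e", "var_e"]
  if (!is.finite(se2) || se2 <= 0)
    stop("observed information for var_e is not positive; Wald test ",
         "unavailable")
  se <- sqrt(se2)
  est <- fit$components[["var_e"]]
  stat <- (est / se)^2
  structure(list(component = "var_e", delta_chisq = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 estimate = est, se = se),
            class = "iced_test")
}

#' @export
print.iced_test <- function(x, ...) {
  lab <- if (x$component == "var_e") "Wald test" else "Likelihood-ratio test"
  cat(sprintf("%s of %s: statistic = %.4f, df = %d, p = %.4g\n",
              lab, x$component, x$delta_chisq, x$df, x$p_value))
  invisible(x)
}

#' Model-fit statistics against the saturated covariance model
#'
#' The chi-square statistic is (N - 1) times the ML discrepancy
#' \eqn{F = \log|\Sigma| + tr(\Sigma^{-1} S) - \log|S| - k} between the
#' model-implied and the (ML) sample covariance, with degrees of freedom
#' k(k+1)/2 minus the number of free variance components. RMSEA is
#' \eqn{\sqrt{\max(\chi^2 - df, 0) / (df (N - 1))}}; it is zero whenever
#' the chi-square does not exceed its degrees of freedom.
#'
#' @param fit an [iced()] fit.
#' @return A list of class `iced_fit_stats`: `chisq`, `df`, `rmsea`,
#'   `discrepancy`, `n_persons`, and the conventions used.
#' @export
fit_stats <- function(fit) {
  stopifnot(inherits(fit, "iced"))
  k <- fit$k; n <- fit$n_persons
  S <- fit$S
  Sigma <- model_covariance(fit$components, fit$design)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is singular; fit statistics unavailable"))
  chM <- chol(Sigma)
  F_ml <- 2 * sum(log(diag(chM))) - 2 * sum(log(diag(chS))) +
    sum(diag(chol2inv(chM) %*% S)) - k
  F_ml <- max(F_ml, 0)
  df <- k * (k + 1) / 2 - sum(fit$free)
  if (df <= 0) stop("non-positive degrees of freedom: model is saturated")
  chisq <- (n - 1) * F_ml
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  structure(list(chisq = chisq, df = as.integer(df), rmsea = rmsea,
                 discrepancy = F_ml, n_persons = n,
                 conventions = list(chisq = "(N-1) * F_ml",
                                    rmsea_denominator = "N-1")),
            class = "iced_fit_stats")
}

#' @export
print.iced_fit_stats <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, RMSEA = %.4f (N = %d)\n",
              x$chisq, x$df, x$rmsea, x$n_persons))
  invisible(x)
}

#' Bootstrap confidence interval for ICC or ICC2
#'
#' Nonparametric person-level bootstrap: persons are resampled with
#' replacement, the decomposition is refitted on each resample, and the
#' percentile interval of the requested statistic is returned. Resamples
#' whose fit fails or does not converge are dropped and counted; more
#' than 20% dropped resamples is an error.
#'
#' @param fit an [iced()] fit (the resampling scheme and options are taken
#'   from it), or a [reliability_data()].
#' @param statistic `"icc"` or `"icc2"`.
#' @param n_boot number of bootstrap resamples (>= 50; the reference
#'   analysis used 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the same seed always yields the same
#'   interval, and the global RNG state is untouched.
#' @return A list of class `iced_boot_ci`: `low`, `high`, `level`,
#'   `statistic`, `n_boot`, `n_dropped`, and the bootstrap replicates.
#' @export
bootstrap_ci <- function(fit, statistic = c("icc", "icc2"), n_boot = 1000,
                         level = 0.95, seed = 1) {
  statistic <- match.arg(statistic)
  if (inherits(fit, "reliability_data")) fit <- iced(fit)
  stopifnot(inherits(fit, "iced"))
  if (n_boot < 50) stop("n_boot must be at least 50")
  y <- unclass(fit$data)
  n <- nrow(y)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(
        suppressWarnings(iced(reliability_data(y[idx, , drop = FALSE],
                                               fit$design),
                              lower_bound = fit$lower_bound,
                              free = names(fit$free)[fit$free],
                              standardize = fit$standardize)),
        error = function(e) NULL)
      if (is.null(bf) || !bf$converged) return(NA_real_)
      if (statistic == "icc") bf$icc else bf$icc2
    }, numeric(1))
  })
  n_dropped <- sum(is.na(reps))
  if (n_dropped > 0.2 * n_boot)
    stop(sprintf("bootstrap unstable: %d of %d resamples failed to fit",
                 n_dropped, n_boot))
  qs <- stats::quantile(reps, probs = c((1 - level) / 2, (1 + level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(low = qs[1], high = qs[2], level = level,
                 statistic = statistic, n_boot = n_boot,
                 n_dropped = n_dropped, replicates = reps,
                 interval_type = "percentile", seed = seed),
            class = "iced_boot_ci")
}

#' @export
print.iced_boot_ci <- function(x, digits = 3, ...) {
  cat(sprintf("%d%% percentile bootstrap CI for %s: [%.*f, %.*f]",
              round(100 * x$level), x$statistic, digits, x$low, digits,
              x$high))
  cat(sprintf("  (%d resamples, %d dropped)\n", x$n_boot, x$n_dropped))
  invisible(x)
}
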