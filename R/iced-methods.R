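#' @export
print.iced <- function(x, digits = 3, ...) {
  cat("Intra-class effect decomposition (", x$n_persons, " persons x ",
      x$k, " occasions)\n", sep = "")
  roi <- x$roi %||% NA; mod <- x$modality %||% NA
  if (!is.na(roi) || !is.na(mod))
    cat("  ", roi, " / ", mod, "\n", sep = "")
  cat("\nVariance proportions (sum to 1):\n")
  print(round(unclass(x$proportions), digits))
  cat(sprintf("\nICC  = %.*f   ICC2 = %.*f   effective error = %.4g\n",
              digits, x$icc, digits, x$icc2, x$effective_error))
  cat(sprintf("log-likelihood = %.4f%s\n", x$loglik,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.iced <- function(object, type = c("raw", "proportions"), ...) {
  type <- match.arg(type)
  out <- if (type == "raw") object$components else object$proportions
  unclass(out)
}

#' @export
logLik.iced <- function(object, ...) {
  structure(object$loglik,
            df = sum(object$free) + object$k,
            nobs = object$n_persons, class = "logLik")
}

#' Observed-information covariance of the variance estimates
#'
#' Inverse of the observed information (negative Hessian of the
#' log-likelihood) at the ML solution, over the free variance components.
#'
#' @param object an [iced()] fit.
#' @param ... unused.
#' @return Covariance matrix of the free variance-component estimates.
#' @export
vcov.iced <- function(object, ...) {
  H <- observed_information(object)
  V <- tryCatch(solve(H), error = function(e)
    stop("observed information is singular"))
  nm <- names(object$free)[object$free]
  dimnames(V) <- list(nm, nm)
  V
}

# negative Hessian of the profile log-likelihood w.r.t. the free variances;
# evaluated without the non-negativity guard so finite-difference steps may
# cross zero at bound-adjacent estimates
observed_information <- function(fit) {
  free <- fit$free
  theta <- unclass(fit$components)[free]
  y <- scaled_values(fit)
  k <- fit$k
  G <- list(matrix(1, k, k),
            tcrossprod(loading_matrix(fit$design, "day")),
            tcrossprod(loading_matrix(fit$design, "session")),
            diag(k))
  f <- function(th) {
    full <- unclass(fit$components)
    full[free] <- th
    Sigma <- full[1] * G[[1]] + full[2] * G[[2]] + full[3] * G[[3]] +
      full[4] * G[[4]]
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    yc <- sweep(y, 2L, fit$means)
    z <- backsolve(ch, t(yc), transpose = TRUE)
    0.5 * (fit$n_persons * (k * log(2 * pi) + 2 * sum(log(diag(ch)))) +
             sum(z^2))
  }
  pracma::hessian(f, theta)
}

scaled_values <- function(fit) {
  y <- unclass(fit$data)
  if (fit$standardize) y <- y / fit$scale_factor
  y
}

#' @export
fitted.iced <- function(object, ...) {
  matrix(object$means, nrow = object$n_persons, ncol = object$k,
         byrow = TRUE,
         dimnames = dimnames(unclass(object$data))) * object$scale_factor
}

#' @export
#' @describeIn iced marginal residuals (observations minus fitted
#'   occasion means, on the original data scale).
residuals.iced <- function(object, ...) {
  unclass(object$data) - fitted(object)
}

#' Predict person-level true scores
#'
#' Empirical-Bayes (BLUP) estimates of each person's true score: the
#' grand mean plus \eqn{\sigma^2_T 1' \Sigma^{-1} (y_p - \mu)}.
#'
#' @param object an [iced()] fit.
#' @param ... unused.
#' @return Named numeric vector, one true-score estimate per person.
#' @export
predict.iced <- function(object, ...) {
  y <- scaled_values(object)
  Sigma <- model_covariance(object$components, object$design)
  w <- solve(Sigma, rep(1, object$k))      # Sigma^{-1} 1
  yc <- sweep(y, 2L, object$means)
  blup <- object$components[["var_t"]] * drop(yc %*% w)
  (mean(object$means) + blup) * object$scale_factor
}

#' Simulate datasets from a fitted decomposition
#'
#' Parametric resampling: draws new reliability datasets from the fitted
#' occasion means and variance components (on the original data scale).
#'
#' @param object an [iced()] fit.
#' @param nsim number of datasets.
#' @param seed integer seed; all randomness flows from it and the global
#'   RNG state is left untouched.
#' @param ... unused.
#' @return A list of `nsim` [reliability_data()] objects.
#' @export
simulate.iced <- function(object, nsim = 1, seed = 1, ...) {
  sf <- object$scale_factor
  comps <- variance_components(object$components[["var_t"]] * sf^2,
                               object$components[["var_d"]] * sf^2,
                               object$components[["var_s"]] * sf^2,
                               object$components[["var_e"]] * sf^2)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_roi_dataset(n_persons = object$n_persons,
                         occasion_means = object$means * sf,
                         components = comps,
                         design = object$design,
                         seed = NULL)))
}

#' @export
plot.iced <- function(x, ...) {
  p <- unclass(x$proportions)
  graphics::barplot(p, names.arg = c("True", "Day", "Session", "Residual"),
                    ylab = "Proportion of total variance", ylim = c(0, 1),
                    col = c("grey25", "grey55", "grey75", "grey90"), ...)
  graphics::abline(h = 0)
  graphics::mtext(sprintf("ICC = %.3f   ICC2 = %.3f", x$icc, x$icc2),
                  side = 3, line = 0.5)
  invisible(x)
}

#' Summarise an intra-class effect decomposition
#'
#' Augments the fit with model-fit statistics ([fit_stats()]), the
#' likelihood-ratio test of each of true-score, day and session variance
#' against its null model, and the Wald test of the residual variance.
#'
#' @param object an [iced()] fit.
#' @param tests if `TRUE` (default) compute component significance tests.
#' @param ... unused.
#' @return An object of class `summary.iced`.
#' @export
summary.iced <- function(object, tests = TRUE, ...) {
  fs <- fit_stats(object)
  tests_tab <- NULL
  if (tests) {
    rows <- lapply(c("var_t", "var_d", "var_s"), function(cmp) {
      if (!object$free[[cmp]]) return(NULL)
      tst <- lrt_component(object, cmp)
      data.frame(component = cmp, test = "LRT",
                 statistic = tst$delta_chisq, df = tst$df,
                 p_value = tst$p_value)
    })
    if (object$free[["var_e"]]) {
      w <- wald_residual(object)
      rows <- c(rows, list(data.frame(component = "var_e", test = "Wald",
                                      statistic = w$delta_chisq, df = w$df,
                                      p_value = w$p_value)))
    }
    tests_tab <- do.call(rbind, rows)
  }
  structure(list(fit = object, fit_stats = fs, tests = tests_tab),
            class = "summary.iced")
}

#' @export
print.summary.iced <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  fs <- x$fit_stats
  cat(sprintf("\nModel fit: chi-square = %.3f, df = %d, RMSEA = %.3f\n",
              fs$chisq, fs$df, fs$rmsea))
  if (!is.null(x$tests)) {
    cat("\nComponent tests:\n")
    tt <- x$tests
    tt$statistic <- round(tt$statistic, 3)
    tt$p_value <- signif(tt$p_value, 3)
    print(tt, row.names = FALSE)
  }
  invisible(x)
}

#' Bootstrap confidence intervals for ICC / ICC2
#'
#' `confint.iced` is a convenience wrapper around [bootstrap_ci()].
#'
#' @param object an [iced()] fit.
#' @param parm `"icc"`, `"icc2"`, or both (default).
#' @param level confidence level.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param ... unused.
#' @return Matrix with one row per statistic and columns `low`, `high`.
#' @export
confint.iced <- function(object, parm = c("icc", "icc2"), level = 0.95,
                         n_boot = 1000, seed = 1, ...) {
  parm <- match.arg(parm, c("icc", "icc2"), several.ok = TRUE)
  out <- t(vapply(parm, function(p)
    unlist(bootstrap_ci(object, statistic = p, n_boot = n_boot,
                        level = level, seed = seed)[c("low", "high")]),
    numeric(2)))
  colnames(out) <- c("low", "high")
  out
}
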