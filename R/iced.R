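#' Fit the intra-class effect decomposition model
#'
#' Maximum-likelihood estimation of the four variance components of
#' repeated measurements under a structured covariance model: each
#' person's k occasions are multivariate normal with a saturated mean
#' structure (one free mean per occasion) and covariance
#' \deqn{\Sigma = \sigma^2_T 11' + \sigma^2_D L_D L_D' +
#'       \sigma^2_S L_S L_S' + \sigma^2_E I,}
#' where the binary loading matrices encode day and session membership.
#' The saturated means are profiled out at their ML values (the occasion
#' sample means); the variances are maximised by bound-constrained
#' quasi-Newton optimisation with an analytic gradient, each free
#' component kept at or above `lower_bound`.
#'
#' @param data a [reliability_data()], or a numeric persons x occasions
#'   matrix (then `design` must be given).
#' @param design a [study_design()]; defaults to the design attached to
#'   `data`.
#' @param lower_bound lower bound applied to every free variance estimate,
#'   on the scale of the fitted data (default 1e-4).
#' @param free character vector naming the components estimated freely;
#'   the others are fixed at zero. Default: all four.
#' @param standardize if `TRUE`, values are divided by the grand standard
#'   deviation across all persons and occasions before fitting, so the
#'   lower bound acts on a proportional scale. Rescaled proportions, ICC,
#'   ICC2 and test statistics are invariant to this choice.
#' @param n_starts number of additional jittered starting points tried
#'   when the first optimisation does not converge (default 3).
#' @param control passed to [stats::optim()] (method `"L-BFGS-B"`); the
#'   default convergence tolerance is `factr = 1e7 * .Machine$double.eps`
#'   relative, roughly 1e-8 on the objective.
#' @return An object of class `iced`: a list with the raw `components`
#'   (data scale), `proportions` (rescaled to sum to 1), `means`, `icc`,
#'   `icc2`, `effective_error`, `loglik`, `converged`, `n_persons`, the
#'   design, and optimisation details. Methods: `print`, `summary`,
#'   `coef`, `logLik`, `confint` (bootstrap), `simulate`, `plot`,
#'   `fitted`, `residuals`, `predict`, `vcov`.
#' @examples
#' set.seed(1)
#' d <- simulate_roi_dataset(n_persons = 50,
#'                           occasion_means = rep(10, 4),
#'                           components = variance_components(0.6, 0.1, 0.1, 0.2),
#'                           seed = 7)
#' fit <- iced(d)
#' fit
#' coef(fit, "proportions")
#' @export
iced <- function(data, design = attr(data, "design"),
                 lower_bound = 1e-4,
                 free = c("var_t", "var_d", "var_s", "var_e"),
                 standardize = FALSE, n_starts = 3, control = list()) {
  if (is.null(design))
    stop("no design: supply a 'study_design' or use reliability_data()")
  if (!inherits(data, "reliability_data"))
    data <- reliability_data(data, design)
  y <- unclass(data)
  n <- nrow(y); k <- ncol(y)
  if (n < 3L)
    stop("at least 3 persons are required for estimation (got ", n, ")")
  if (anyNA(y)) stop("missing cells in data")
  comp_names <- c("var_t", "var_d", "var_s", "var_e")
  free <- match.arg(free, comp_names, several.ok = TRUE)
  is_free <- comp_names %in% free
  names(is_free) <- comp_names

  scale_factor <- 1
  if (standardize) {
    scale_factor <- stats::sd(as.vector(y))
    if (!is.finite(scale_factor) || scale_factor <= 0)
      stop("cannot standardize: grand SD is not positive")
    y <- y / scale_factor
  }

  means <- colMeans(y)
  yc <- sweep(y, 2L, means)
  S <- crossprod(yc) / n                 # ML sample covariance

  # structure matrices G_i with Sigma = sum_i theta_i G_i
  G <- list(
    var_t = matrix(1, k, k),
    var_d = tcrossprod(loading_matrix(design, "day")),
    var_s = tcrossprod(loading_matrix(design, "session")),
    var_e = diag(k)
  )
  G <- lapply(G, function(g) { dimnames(g) <- NULL; g })

  build_sigma <- function(theta_full)
    Reduce(`+`, Map(function(v, g) v * g, theta_full, G))

  expand <- function(theta) {
    full <- numeric(4); names(full) <- comp_names
    full[is_free] <- theta
    full
  }

  nll <- function(theta) {
    Sigma <- build_sigma(expand(theta))
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    n / 2 * (k * log(2 * pi) + logdet + tr)
  }
  gr <- function(theta) {
    Sigma <- build_sigma(expand(theta))
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(theta)))
    P <- chol2inv(ch)
    M <- P - P %*% S %*% P
    vapply(G[is_free], function(g) n / 2 * sum(M * g), numeric(1))
  }

  start <- iced_start_values(S, design)[is_free]
  start <- pmax(start, lower_bound)
  nf <- sum(is_free)
  ctrl <- utils::modifyList(list(factr = 1e2, pgtol = 1e-12, maxit = 500),
                            control)

  run_optim <- function(par) {
    stats::optim(par, nll, gr, method = "L-BFGS-B",
                 lower = rep(lower_bound, nf),
                 upper = rep(Inf, nf), control = ctrl)
  }
  opt <- run_optim(start)
  tries <- 1L
  while (opt$convergence != 0 && tries <= n_starts) {
    jitter <- start * stats::runif(nf, 0.25, 4) + lower_bound
    cand <- tryCatch(run_optim(jitter), error = function(e) NULL)
    if (!is.null(cand) &&
        (cand$convergence == 0 || cand$value < opt$value)) opt <- cand
    tries <- tries + 1L
  }
  converged <- opt$convergence == 0
  if (!converged)
    warning("iced fit did not converge after ", tries,
            " start(s): optim code ", opt$convergence,
            if (nzchar(opt$message %||% "")) paste0(" (", opt$message, ")"))

  theta_full <- expand(opt$par)
  components <- variance_components(theta_full[1], theta_full[2],
                                    theta_full[3], theta_full[4])
  proportions <- rescale_components(components)
  fit <- list(
    call = match.call(),
    components = components,
    proportions = proportions,
    means = means,
    icc = icc(components),
    icc2 = icc2(components, design),
    effective_error = effective_error(components, design),
    loglik = -opt$value,
    converged = converged,
    n_persons = n,
    k = k,
    design = design,
    data = data,
    free = is_free,
    lower_bound = lower_bound,
    standardize = standardize,
    scale_factor = scale_factor,
    S = S,
    optim = opt,
    roi = attr(data, "roi"),
    modality = attr(data, "modality")
  )
  class(fit) <- "iced"
  fit
}

# method-of-moments starts from the ML sample covariance:
# T from the mean cross-day covariance, D from same-day/cross-session
# covariance, S from same-session off-diagonal covariance, E from the
# mean variance minus the rest; degenerate designs fall back to an
# equal split of the mean variance.
iced_start_values <- function(S, design) {
  k <- nrow(S)
  same_day <- tcrossprod(loading_matrix(design, "day")) == 1
  same_ses <- tcrossprod(loading_matrix(design, "session")) == 1
  offdiag <- !diag(k)
  cross_day <- offdiag & !same_day
  day_only <- offdiag & same_day & !same_ses
  ses_off <- offdiag & same_ses
  t0 <- if (any(cross_day)) mean(S[cross_day]) else mean(S[offdiag]) / 2
  d0 <- if (any(day_only)) mean(S[day_only]) - t0 else 0
  s0 <- if (any(ses_off)) mean(S[ses_off]) - t0 - d0 else 0
  e0 <- mean(diag(S)) - t0 - d0 - s0
  v <- c(var_t = t0, var_d = d0, var_s = s0, var_e = e0)
  bad <- !is.finite(v)
  v[bad] <- mean(diag(S)) / 4
  pmax(v, 0)
}

#' Multivariate-normal log-likelihood of a reliability dataset
#'
#' Evaluates the log-likelihood of the data under given variance
#' components and occasion means: the sum over persons of the k-variate
#' normal log-density with mean vector `means` and model-implied
#' covariance [model_covariance()].
#'
#' @param data a [reliability_data()] or persons x occasions matrix.
#' @param vc a [variance_components()] vector.
#' @param means numeric vector of k occasion means; defaults to the
#'   occasion sample means (their ML values).
#' @param design a [study_design()]; defaults to the one attached to
#'   `data`.
#' @return The log-likelihood (scalar).
#' @export
iced_loglik <- function(data, vc, means = NULL,
                        design = attr(data, "design")) {
  if (is.null(design)) stop("no design available")
  y <- unclass(as.matrix(data))
  k <- ncol(y)
  if (is.null(means)) means <- colMeans(y)
  if (length(means) != k) stop("'means' must have one entry per occasion")
  Sigma <- model_covariance(vc, design)
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("model covariance is singular (degenerate components)"))
  logdet <- 2 * sum(log(diag(ch)))
  yc <- sweep(y, 2L, means)
  # quadratic forms via triangular solve
  z <- backsolve(ch, t(yc), transpose = TRUE)
  q <- colSums(z^2)
  sum(-0.5 * (k * log(2 * pi) + logdet + q))
}
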