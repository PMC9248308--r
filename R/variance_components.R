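#' Variance components of the reliability model
#'
#' Bundles the four variances of the intra-class effect decomposition:
#' true-score variance `var_t` (stable between-person differences),
#' day-specific error variance `var_d` (shared by all measurements of one
#' day), session-specific error variance `var_s` (shared by measurements
#' acquired in one head positioning), and residual error variance `var_e`.
#'
#' @param var_t,var_d,var_s,var_e non-negative variances, in squared units
#'   of the measured modality (or unitless when working with proportions).
#' @return A named numeric vector of class `variance_components`.
#' @examples
#' variance_components(0.6, 0.1, 0.1, 0.2)
#' @export
variance_components <- function(var_t, var_d = 0, var_s = 0, var_e = 0) {
  if (length(var_t) == 4L && missing(var_d)) {
    v <- as.numeric(var_t)
  } else {
    v <- c(var_t, var_d, var_s, var_e)
  }
  if (length(v) != 4L) stop("exactly four variance components are required")
  if (!all(is.finite(v))) stop("variance components must be finite")
  if (any(v < 0)) stop("variance components must be non-negative")
  names(v) <- c("var_t", "var_d", "var_s", "var_e")
  class(v) <- "variance_components"
  v
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  y <- unclass(x)
  cat("Variance components (T / D / S / E):\n")
  print(round(y, digits))
  invisible(x)
}

as_variance_components <- function(x) {
  if (inherits(x, "variance_components")) return(x)
  variance_components(x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Rescale variance components to proportions of total variance
#'
#' Divides each component by the total so the four rescaled components sum
#' to one and can be read as relative contributions to the observed
#' variance. The rescaled true-score variance equals the ICC.
#'
#' @param vc a [variance_components()] vector (or any length-4 non-negative
#'   numeric).
#' @return A `variance_components` vector summing to 1.
#' @examples
#' rescale_components(variance_components(2, 0, 1, 1))
#' @export
rescale_components <- function(vc) {
  vc <- as_variance_components(vc)
  total <- sum(vc)
  if (total <= 0) stop("cannot rescale: total variance is zero")
  variance_components(vc[1] / total, vc[2] / total, vc[3] / total,
                      vc[4] / total)
}

#' Model-implied covariance matrix of the occasions
#'
#' Builds the k x k covariance implied by the decomposition: true-score
#' variance loads on every pair of occasions, day variance on pairs sharing
#' a day, session variance on pairs sharing a session, and residual
#' variance on the diagonal only.
#'
#' @param vc a [variance_components()] vector.
#' @param design a [study_design()].
#' @return Symmetric positive semidefinite k x k matrix with occasion
#'   labels as dimnames.
#' @examples
#' model_covariance(variance_components(0.6, 0.1, 0.1, 0.2), mpm_design())
#' @export
model_covariance <- function(vc, design) {
  vc <- as_variance_components(vc)
  stopifnot(inherits(design, "study_design"))
  k <- n_occasions(design)
  Ld <- loading_matrix(design, "day")
  Ls <- loading_matrix(design, "session")
  Sigma <- vc[["var_t"]] * matrix(1, k, k) +
    vc[["var_d"]] * tcrossprod(Ld) +
    vc[["var_s"]] * tcrossprod(Ls) +
    vc[["var_e"]] * diag(k)
  dimnames(Sigma) <- list(design$occasion, design$occasion)
  Sigma
}

#' Intraclass correlation of a single measurement
#'
#' The ratio of true-score (between-person) variance to total variance:
#' the test-retest reliability of one measurement occasion.
#'
#' @param vc a [variance_components()] vector with positive total.
#' @return ICC in \[0, 1\].
#' @examples
#' icc(variance_components(0.883, 0.000, 0.003, 0.114))
#' @export
icc <- function(vc) {
  vc <- as_variance_components(vc)
  total <- sum(vc)
  if (total <= 0) stop("ICC undefined: total variance is zero")
  unname(vc[["var_t"]] / total)
}

#' Effective error variance of the whole design
#'
#' The error variance of the best (precision-weighted, linear unbiased)
#' composite of all k occasions: with error covariance
#' \eqn{\Sigma_E = \Sigma - \sigma^2_T 11'}, the effective error is
#' \eqn{1 / (1' \Sigma_E^{-1} 1)}. When day and session variance are zero
#' it reduces to the classical `var_e / k`.
#'
#' @param vc a [variance_components()] vector.
#' @param design a [study_design()].
#' @return Effective error variance (>= 0).
#' @examples
#' effective_error(variance_components(0.562, 0, 0, 0.438), mpm_design())
#' # equals 0.438 / 4
#' @export
effective_error <- function(vc, design) {
  vc <- as_variance_components(vc)
  stopifnot(inherits(design, "study_design"))
  err <- variance_components(0, vc[["var_d"]], vc[["var_s"]], vc[["var_e"]])
  if (sum(err) == 0) return(0)
  Sigma_e <- model_covariance(err, design)
  W <- tryCatch(solve(Sigma_e), error = function(e)
    stop("error covariance is singular; cannot form the effective error"))
  1 / sum(W)
}

#' Construct-level reliability (ICC2)
#'
#' Reliability of the person-level construct estimated from the complete
#' design: true-score variance over true-score variance plus the
#' [effective_error()] of the k-occasion composite. For a pure residual
#' error structure this is the classical
#' \eqn{\sigma^2_T / (\sigma^2_T + \sigma^2_E / k)}.
#'
#' @param vc a [variance_components()] vector.
#' @param design a [study_design()].
#' @return ICC2 in \[0, 1\].
#' @examples
#' icc2(variance_components(0.562, 0, 0, 0.438), mpm_design())
#' @export
icc2 <- function(vc, design) {
  vc <- as_variance_components(vc)
  ee <- effective_error(vc, design)
  denom <- vc[["var_t"]] + ee
  if (denom <= 0) stop("ICC2 undefined: true-score plus effective error is zero")
  unname(vc[["var_t"]] / denom)
}
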