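#' Bundle multi-echo gradient-echo acquisitions
#'
#' Up to three contrast-weighted echo trains (T1w, PDw, MTw), each with
#' strictly increasing echo times (ms), positive signal amplitudes
#' (arbitrary units), a flip angle (degrees) and repetition time (ms).
#'
#' @param contrasts named list; each element a list with fields `te_ms`,
#'   `signal`, and optionally `flip_angle`, `tr_ms`.
#' @return Object of class `multi_echo_set`.
#' @export
multi_echo_set <- function(contrasts) {
  stopifnot(is.list(contrasts), length(contrasts) >= 1L,
            length(contrasts) <= 3L)
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts))))
    stop("contrasts must be named (e.g. T1w, PDw, MTw)")
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (is.null(ct$te_ms) || is.null(ct$signal))
      stop("contrast ", nm, " needs 'te_ms' and 'signal'")
    if (length(ct$te_ms) != length(ct$signal))
      stop("contrast ", nm, ": te_ms and signal lengths differ")
    if (is.unsorted(ct$te_ms, strictly = TRUE))
      stop("contrast ", nm, ": echo times must be strictly increasing")
  }
  structure(contrasts, class = "multi_echo_set")
}

#' @export
print.multi_echo_set <- function(x, ...) {
  cat("Multi-echo set:\n")
  for (nm in names(x)) {
    ct <- x[[nm]]
    cat(sprintf("  %s: %d echoes, TE %.2f-%.2f ms", nm,
                length(ct$te_ms), min(ct$te_ms), max(ct$te_ms)))
    if (!is.null(ct$flip_angle))
      cat(sprintf(", flip %g deg, TR %g ms", ct$flip_angle, ct$tr_ms))
    cat("\n")
  }
  invisible(x)
}

#' Joint log-linear R2* estimation across contrasts (ESTATICS)
#'
#' Fits all echo trains jointly by ordinary least squares on the
#' log-signals: one common slope (-R2*, with TE converted to seconds so
#' R2* is in 1/s) and one TE=0 intercept per contrast. The intercepts are
#' returned exponentiated back to the signal scale; they are estimates of
#' the contrast amplitudes free of transverse-relaxation decay.
#'
#' @param echoes a [multi_echo_set()] with all signals > 0 and at least
#'   two echoes per contrast.
#' @return A list of class `estatics_fit`: `r2star` (1/s), `intercepts`
#'   (named, signal units), `residual_sse` (log-signal scale),
#'   `coefficients` of the underlying linear model.
#' @examples
#' me <- simulate_multiecho(r2star = 20, noise_sd = 0)
#' estatics_fit(me)$r2star
#' @export
estatics_fit <- function(echoes) {
  stopifnot(inherits(echoes, "multi_echo_set"))
  te <- unlist(lapply(echoes, `[[`, "te_ms"), use.names = FALSE)
  sig <- unlist(lapply(echoes, `[[`, "signal"), use.names = FALSE)
  contrast <- rep(names(echoes),
                  vapply(echoes, function(c) length(c$te_ms), integer(1)))
  n_per <- table(contrast)
  if (any(n_per < 2L))
    stop("each contrast needs at least 2 echoes for the joint fit")
  if (length(te) < 2L) stop("need at least 2 echoes in total")
  if (any(sig <= 0))
    stop("non-positive signal: log-linear fitting requires signals > 0")
  if (max(te) - min(te) <= 0) stop("degenerate echo-time spread")
  te_s <- te / 1000
  # design: per-contrast intercept dummies + common TE column
  Xd <- outer(contrast, names(echoes), `==`) * 1
  X <- cbind(Xd, te_s)
  colnames(X) <- c(names(echoes), "te_s")
  fit <- stats::lm.fit(X, log(sig))
  coefs <- fit$coefficients
  r2star <- -coefs[["te_s"]]
  intercepts <- exp(coefs[names(echoes)])
  structure(list(r2star = r2star, intercepts = intercepts,
                 residual_sse = sum(fit$residuals^2),
                 coefficients = coefs),
            class = "estatics_fit")
}

#' @export
print.estatics_fit <- function(x, digits = 4, ...) {
  cat(sprintf("ESTATICS joint fit: R2* = %.*g 1/s\n", digits, x$r2star))
  cat("TE=0 intercepts (a.u.):\n")
  print(round(x$intercepts, digits))
  cat(sprintf("residual SSE (log scale): %.4g\n", x$residual_sse))
  invisible(x)
}

#' Steady-state spoiled gradient-echo signal (Ernst equation)
#'
#' \deqn{S = A \sin\alpha (1 - E_1) / (1 - \cos\alpha\, E_1)}
#' with \eqn{E_1 = \exp(-TR \cdot R_1)}.
#'
#' @param amplitude signal amplitude A (arbitrary units, proportional to
#'   proton density).
#' @param r1 longitudinal relaxation rate, 1/s (> 0).
#' @param flip_angle flip angle in degrees, in (0, 90].
#' @param tr_ms repetition time in milliseconds (> 0).
#' @return Signal in the units of `amplitude`.
#' @examples
#' ernst_signal(1000, r1 = 1, flip_angle = 90, tr_ms = 24.5)  # 24.2024
#' @export
ernst_signal <- function(amplitude, r1, flip_angle, tr_ms) {
  if (any(r1 <= 0)) stop("r1 must be positive")
  if (any(flip_angle <= 0) || any(flip_angle > 90))
    stop("flip_angle must be in (0, 90] degrees")
  if (any(tr_ms <= 0)) stop("tr_ms must be positive")
  a <- flip_angle * pi / 180
  e1 <- exp(-tr_ms / 1000 * r1)
  amplitude * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Dual-flip-angle R1 recovery
#'
#' Solves the pair of Ernst equations sharing one amplitude for R1, from
#' the steady-state signals at a low and a high flip angle with common
#' TR. The signal ratio depends monotonically on R1 and is inverted
#' exactly by bracketed root finding on \[1e-4, 100\] 1/s; the common
#' amplitude is returned as a by-product. [dual_flip_angle_r1_approx()]
#' implements the classical small-angle rational approximation for
#' comparison.
#'
#' @param s_low,s_high signals (> 0) at the low and high flip angle.
#' @param a_low,a_high flip angles in degrees, `a_low < a_high` (protocol
#'   default 6 and 21 degrees).
#' @param tr_ms common repetition time in ms (protocol default 24.5).
#' @return List with `r1` (1/s) and `amplitude` (signal units).
#' @examples
#' s6 <- ernst_signal(900, 0.622, 6, 24.5)
#' s21 <- ernst_signal(900, 0.622, 21, 24.5)
#' dual_flip_angle_r1(s6, s21)$r1
#' @export
dual_flip_angle_r1 <- function(s_low, s_high, a_low = 6, a_high = 21,
                               tr_ms = 24.5) {
  if (s_low <= 0 || s_high <= 0) stop("signals must be positive")
  if (a_low >= a_high) stop("a_low must be smaller than a_high")
  al <- a_low * pi / 180; ah <- a_high * pi / 180
  ratio <- function(r1) {
    e1 <- exp(-tr_ms / 1000 * r1)
    sin(al) * (1 - cos(ah) * e1) / (sin(ah) * (1 - cos(al) * e1))
  }
  g <- function(r1) ratio(r1) - s_low / s_high
  lower <- 1e-4; upper <- 100
  if (g(lower) * g(upper) > 0)
    stop("signal ratio inconsistent with the Ernst model: no R1 root in ",
         "[1e-4, 100] 1/s")
  root <- stats::uniroot(g, c(lower, upper), tol = 1e-12)
  r1 <- root$root
  amplitude <- s_low / (ernst_signal(1, r1, a_low, tr_ms))
  list(r1 = r1, amplitude = amplitude)
}

#' @rdname dual_flip_angle_r1
#' @export
dual_flip_angle_r1_approx <- function(s_low, s_high, a_low = 6,
                                      a_high = 21, tr_ms = 24.5) {
  if (s_low <= 0 || s_high <= 0) stop("signals must be positive")
  al <- a_low * pi / 180; ah <- a_high * pi / 180
  tr <- tr_ms / 1000
  r1 <- (s_high * ah - s_low * al) / (2 * tr * (s_low / al - s_high / ah))
  # small-angle amplitude: A = S (R1 TR + a^2/2) / (a R1 TR)
  amplitude <- s_low * (r1 * tr + al^2 / 2) / (al * r1 * tr)
  list(r1 = r1, amplitude = amplitude)
}

#' Calibrate a proton-density map to white-matter units
#'
#' Rescales a PD map so the mean over the white-matter mask equals 69
#' percent units; the global PD level is not identified without an
#' external standard, so white matter serves as the internal reference.
#'
#' @param pd_map numeric vector/array of PD values (arbitrary units).
#' @param wm_mask logical/0-1 object of the same shape selecting
#'   white-matter voxels.
#' @param target calibration target in percent units (default 69).
#' @return The rescaled map, same shape as `pd_map`, with attribute
#'   `scale` (the factor applied).
#' @export
calibrate_pd <- function(pd_map, wm_mask, target = 69) {
  if (!identical(dim(pd_map) %||% length(pd_map),
                 dim(wm_mask) %||% length(wm_mask)))
    stop("pd_map and wm_mask shapes differ")
  mask <- as.logical(wm_mask)
  if (!any(mask, na.rm = TRUE)) stop("white-matter mask is empty")
  m <- mean(pd_map[which(mask)], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("masked mean must be positive for calibration")
  scale <- target / m
  out <- pd_map * scale
  attr(out, "scale") <- scale
  out
}
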