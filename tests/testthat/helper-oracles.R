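# Independent oracles kept deliberately naive: they re-derive quantities
# from first principles via different numerical routes than the package.

# multivariate normal log-density, summed over rows, via det()/solve()
oracle_mvn_loglik <- function(y, mu, Sigma) {
  k <- ncol(y)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  Sinv <- solve(Sigma)
  total <- 0
  for (p in seq_len(nrow(y))) {
    d <- y[p, ] - mu
    total <- total - 0.5 * (k * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }
  as.numeric(total)
}

# covariance entry (i, j) by summing shared-factor memberships directly
oracle_cov_entry <- function(vc, design, i, j) {
  v <- unclass(vc)
  out <- v[["var_t"]]
  if (design$day[i] == design$day[j]) out <- out + v[["var_d"]]
  if (design$session[i] == design$session[j]) out <- out + v[["var_s"]]
  if (i == j) out <- out + v[["var_e"]]
  out
}

# profile log-likelihood at given variances (means at sample means)
oracle_profile_loglik <- function(y, vc, design) {
  oracle_mvn_loglik(y, colMeans(y), model_covariance(vc, design))
}

# naive central-difference Hessian (fixed step), independent of pracma
oracle_hessian <- function(f, x, h = 1e-5) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ei <- ej <- rep(0, n); ei[i] <- h; ej[j] <- h
    H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                f(x - ei + ej) + f(x - ei - ej)) / (4 * h * h)
  }
  (H + t(H)) / 2
}

make_dataset <- function(n = 30, props = c(0.6, 0.1, 0.1, 0.2),
                         total = 1, means = rep(10, 4), seed = 1) {
  simulate_roi_dataset(
    n_persons = n, occasion_means = means,
    components = variance_components(props[1] * total, props[2] * total,
                                     props[3] * total, props[4] * total),
    seed = seed)
}
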