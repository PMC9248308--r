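# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = env)
  on.exit({
    if (has) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate an ROI-level reliability dataset
#'
#' Generates measurements from the generative model behind [iced()]:
#' \deqn{y_{po} = \mu_o + T_p + D_{p,day(o)} + S_{p,session(o)} + E_{po}}
#' with independent zero-mean Gaussian effects of the specified
#' variances. Defaults mirror the reference scan-rescan study: 15
#' persons, the four-occasion two-day design, occasion means at the
#' gray-matter magnetization-transfer level (0.874 p.u.), and components
#' whose proportions (0.883 / 0 / 0.003 / 0.114 of a total variance of
#' 0.0025) match the gray-matter MT decomposition.
#'
#' @param n_persons number of persons (default 15).
#' @param occasion_means numeric vector of k occasion means, in modality
#'   units.
#' @param components absolute (not rescaled) [variance_components()].
#' @param design a [study_design()].
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return A [reliability_data()].
#' @examples
#' d <- simulate_roi_dataset(seed = 42)
#' dim(d)
#' @export
simulate_roi_dataset <- function(n_persons = 15,
                                 occasion_means = rep(0.874, n_occasions(design)),
                                 components = variance_components(
                                   0.883 * 0.0025, 0, 0.003 * 0.0025,
                                   0.114 * 0.0025),
                                 design = mpm_design(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (n_persons < 1) stop("n_persons must be at least 1")
  components <- as_variance_components(components)
  k <- n_occasions(design)
  if (length(occasion_means) != k)
    stop("occasion_means must have one entry per occasion")
  Ld <- loading_matrix(design, "day")
  Ls <- loading_matrix(design, "session")
  with_seed(seed, {
    Tp <- stats::rnorm(n_persons, 0, sqrt(components[["var_t"]]))
    D <- matrix(stats::rnorm(n_persons * ncol(Ld), 0,
                             sqrt(components[["var_d"]])),
                n_persons, ncol(Ld))
    S <- matrix(stats::rnorm(n_persons * ncol(Ls), 0,
                             sqrt(components[["var_s"]])),
                n_persons, ncol(Ls))
    E <- matrix(stats::rnorm(n_persons * k, 0, sqrt(components[["var_e"]])),
                n_persons, k)
    y <- matrix(occasion_means, n_persons, k, byrow = TRUE) +
      Tp + D %*% t(Ld) + S %*% t(Ls) + E
    reliability_data(y, design)
  })
}

#' Simulate aligned per-person per-occasion voxel maps
#'
#' Every in-mask voxel follows the ROI generative model of
#' [simulate_roi_dataset()] with its own local mean and variance
#' components; voxels outside the mask are `NA`. Component fields may be
#' scalars (spatially constant) or arrays of the map shape.
#'
#' @param shape integer vector of 3 dimensions (keep small, e.g. <= 32^3).
#' @param n_persons number of persons.
#' @param mean_field scalar or 3D array of voxel means.
#' @param component_fields list with elements `var_t`, `var_d`, `var_s`,
#'   `var_e`, each a scalar or 3D array.
#' @param design a [study_design()].
#' @param mask logical/0-1 3D array; default all voxels in-mask.
#' @param seed integer seed.
#' @return A [voxel_map_set()] whose `values` array has dimensions
#'   `c(shape, n_persons, k)`.
#' @export
simulate_voxel_maps <- function(shape, n_persons = 15, mean_field = 1,
                                component_fields = list(
                                  var_t = 0.6, var_d = 0.1,
                                  var_s = 0.1, var_e = 0.2),
                                design = mpm_design(), mask = NULL,
                                seed = NULL) {
  stopifnot(length(shape) == 3L, inherits(design, "study_design"))
  shape <- as.integer(shape)
  nvox <- prod(shape)
  k <- n_occasions(design)
  expand_field <- function(f, name) {
    if (length(f) == 1L) return(rep(as.numeric(f), nvox))
    if (!all(dim(f) == shape))
      stop("field '", name, "' does not match the map shape")
    as.numeric(f)
  }
  mu <- expand_field(mean_field, "mean")
  vt <- expand_field(component_fields$var_t, "var_t")
  vd <- expand_field(component_fields$var_d, "var_d")
  vs <- expand_field(component_fields$var_s, "var_s")
  ve <- expand_field(component_fields$var_e, "var_e")
  if (any(c(vt, vd, vs, ve) < 0)) stop("negative variance field")
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (!all(dim(mask) == shape)) stop("mask does not match the map shape")
  mask <- array(as.logical(mask), shape)
  Ld <- loading_matrix(design, "day"); Ls <- loading_matrix(design, "session")
  values <- array(NA_real_, c(shape, n_persons, k))
  idx <- which(mask)
  with_seed(seed, {
    # effects drawn per voxel: persons x (1 + days + sessions + k) each
    for (v in idx) {
      Tp <- stats::rnorm(n_persons, 0, sqrt(vt[v]))
      D <- matrix(stats::rnorm(n_persons * ncol(Ld), 0, sqrt(vd[v])),
                  n_persons, ncol(Ld))
      S <- matrix(stats::rnorm(n_persons * ncol(Ls), 0, sqrt(vs[v])),
                  n_persons, ncol(Ls))
      E <- matrix(stats::rnorm(n_persons * k, 0, sqrt(ve[v])),
                  n_persons, k)
      y <- mu[v] + Tp + D %*% t(Ld) + S %*% t(Ls) + E
      ijk <- arrayInd(v, shape)
      values[ijk[1], ijk[2], ijk[3], , ] <- y
    }
  })
  voxel_map_set(values, mask = mask, design = design)
}

#' Simulate a multi-echo FLASH acquisition
#'
#' Mono-exponential decay over the protocol echo times: the T1-weighted
#' and MT-weighted trains have six equidistant echoes from 2.34 to
#' 14.04 ms; the PD-weighted train has two additional echoes at 16.38 and
#' 18.72 ms. Signals are `intercept * exp(-R2* * TE)` plus additive
#' Gaussian noise.
#'
#' @param intercepts named numeric: TE=0 signal amplitudes for `T1w`,
#'   `PDw`, `MTw` (arbitrary units, > 0).
#' @param r2star effective transverse relaxation rate, 1/s (> 0).
#' @param noise_sd additive Gaussian noise SD in signal units (>= 0).
#' @param seed integer seed.
#' @return A [multi_echo_set()] with the protocol flip angles (T1w 21
#'   degrees, PDw/MTw 6 degrees) and TR = 24.5 ms.
#' @export
simulate_multiecho <- function(intercepts = c(T1w = 1000, PDw = 800,
                                              MTw = 600),
                               r2star = 20, noise_sd = 0, seed = NULL) {
  if (any(intercepts <= 0)) stop("intercepts must be positive")
  if (r2star <= 0) stop("r2star must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  tes <- protocol_echo_times()
  flips <- c(T1w = 21, PDw = 6, MTw = 6)
  with_seed(seed, {
    contrasts <- lapply(names(tes), function(cn) {
      te <- tes[[cn]]
      s <- intercepts[[cn]] * exp(-r2star * te / 1000) +
        stats::rnorm(length(te), 0, noise_sd)
      list(te_ms = te, signal = s, flip_angle = flips[[cn]], tr_ms = 24.5)
    })
    names(contrasts) <- names(tes)
    multi_echo_set(contrasts)
  })
}

#' Protocol echo times of the multi-echo FLASH sequences
#'
#' @return Named list of echo-time vectors in milliseconds: six
#'   equidistant echoes 2.34-14.04 ms for T1w and MTw, with two extra
#'   echoes (16.38, 18.72 ms) for PDw.
#' @export
protocol_echo_times <- function() {
  base <- seq(2.34, 14.04, length.out = 6)
  list(T1w = base, PDw = c(base, 16.38, 18.72), MTw = base)
}
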