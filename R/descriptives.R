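#' Within-person coefficient of variation
#'
#' SD of one person's repeated measurements (sample SD, n-1 denominator)
#' divided by their mean. Reported as a fraction; multiply by 100 for
#' percent.
#'
#' @param values numeric vector of k >= 2 measurements with a positive
#'   mean.
#' @return CoV as a fraction (>= 0).
#' @examples
#' participant_cov(c(0.9, 1.0, 1.1, 1.0))   # 0.08165
#' @export
participant_cov <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CoV needs at least 2 values")
  if (anyNA(values)) stop("missing values in CoV input")
  m <- mean(values)
  if (m == 0) stop("CoV undefined: mean is zero")
  if (m < 0) stop("CoV undefined for a negative mean")
  stats::sd(values) / m
}

#' Per-person CoVs with group mean and SD
#'
#' Computes each person's coefficient of variation across the occasions
#' and summarises them across persons (mean and sample SD).
#'
#' @param data a [reliability_data()] or a list of them (e.g. one per
#'   ROI x modality).
#' @return For a single dataset, a list of class `cov_summary` with
#'   `per_person`, `mean`, `sd`, `roi`, `modality`; for a list, a data
#'   frame with one row per dataset (`roi`, `modality`, `cov_mean`,
#'   `cov_sd`, both as fractions).
#' @export
cov_table <- function(data) {
  if (inherits(data, "reliability_data")) {
    per <- apply(unclass(data), 1L, participant_cov)
    return(structure(list(per_person = per, mean = mean(per),
                          sd = stats::sd(per),
                          roi = attr(data, "roi"),
                          modality = attr(data, "modality")),
                     class = "cov_summary"))
  }
  stopifnot(is.list(data))
  rows <- lapply(data, function(d) {
    s <- cov_table(d)
    data.frame(roi = s$roi %||% NA_character_,
               modality = s$modality %||% NA_character_,
               cov_mean = s$mean, cov_sd = s$sd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cov_summary <- function(x, ...) {
  cat(sprintf("CoV across %d persons: mean %.2f%% +/- %.2f%% SD\n",
              length(x$per_person), 100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Grand mean and between-occasion SD
#'
#' Summarises a dataset the way reference tables report modality levels:
#' the mean over all persons and occasions, and the sample SD (n-1
#' denominator) across the k occasion-level means.
#'
#' @param data a [reliability_data()].
#' @return Named numeric vector `c(mean, sd)`.
#' @examples
#' d <- simulate_roi_dataset(seed = 1)
#' occasion_mean_sd(d)
#' @export
occasion_mean_sd <- function(data) {
  y <- unclass(as.matrix(data))
  if (ncol(y) < 2L) stop("need at least 2 occasions")
  om <- colMeans(y)
  c(mean = mean(y), sd = stats::sd(om))
}
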