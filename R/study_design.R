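#' Define a repeated-measures study design
#'
#' A study design lists measurement occasions and assigns each one to a day
#' and to a session (a contiguous block of measurements acquired without
#' repositioning the participant). Sessions are nested within days: every
#' session belongs to exactly one day. The day and session memberships
#' determine which occasions share day-specific and session-specific error,
#' and hence the structure of the model-implied covariance matrix used by
#' [iced()].
#'
#' @param occasion character vector of unique occasion labels, in acquisition
#'   order.
#' @param day vector (coerced to character) giving the day of each occasion.
#' @param session vector (coerced to character) giving the session of each
#'   occasion. Each session label must map to a single day.
#' @return An object of class `study_design`: a data frame with columns
#'   `occasion`, `day`, `session` and attribute `k` (number of occasions).
#' @examples
#' # two days; day 1 acquired back-to-back, day 2 with repositioning
#' d <- study_design(
#'   occasion = c("D1M1", "D1M2", "D2M1", "D2M2"),
#'   day      = c(1, 1, 2, 2),
#'   session  = c(1, 1, 2, 3)
#' )
#' d
#' @seealso [mpm_design()] for the default two-day scan-rescan design.
#' @export
study_design <- function(occasion, day, session) {
  occasion <- as.character(occasion)
  day <- as.character(day)
  session <- as.character(session)
  k <- length(occasion)
  if (k < 2L)
    stop("a study design needs at least 2 occasions")
  if (length(day) != k || length(session) != k)
    stop("'occasion', 'day' and 'session' must have equal length")
  if (anyDuplicated(occasion))
    stop("occasion labels must be unique")
  # sessions nested in days: one day per session label
  nd <- tapply(day, session, function(x) length(unique(x)))
  if (any(nd > 1L))
    stop("session(s) ", paste(names(nd)[nd > 1L], collapse = ", "),
         " span more than one day; sessions must be nested within days")
  out <- data.frame(occasion = occasion, day = day, session = session,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  class(out) <- c("study_design", "data.frame")
  out
}

#' Default multiparameter-mapping scan-rescan design
#'
#' Four measurement occasions over two consecutive days: on day 1 the
#' participant is measured twice back-to-back without repositioning (both
#' measurements share one session), and on day 2 twice with repositioning
#' in between (each measurement is its own session). This is the canonical
#' 2-day / 3-session / 4-occasion test-retest design for which session
#' variance (the effect of repositioning plus the new prescan adjustments)
#' is identifiable from the day-1 within-pair covariance.
#'
#' @return A `study_design` with occasions `D1M1, D1M2, D2M1, D2M2`.
#' @examples
#' mpm_design()
#' @export
mpm_design <- function() {
  study_design(
    occasion = c("D1M1", "D1M2", "D2M1", "D2M2"),
    day      = c("1", "1", "2", "2"),
    session  = c("1", "1", "2", "3")
  )
}

#' Binary factor-loading matrix of a design
#'
#' Materialises the membership of occasions in the levels of a grouping
#' factor as a k x n_levels 0/1 matrix: entry (i, j) is 1 iff occasion i
#' belongs to level j. Row sums are always 1 (levels partition occasions).
#'
#' @param design a [study_design()].
#' @param factor one of `"day"` or `"session"`.
#' @return Binary matrix with occasions as rows and factor levels as columns.
#' @examples
#' loading_matrix(mpm_design(), "day")
#' loading_matrix(mpm_design(), "session")
#' @export
loading_matrix <- function(design, factor = c("day", "session")) {
  stopifnot(inherits(design, "study_design"))
  factor <- match.arg(factor)
  g <- design[[factor]]
  levels <- unique(g)
  L <- outer(g, levels, `==`) * 1L
  dimnames(L) <- list(design$occasion, levels)
  L
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d occasions, %d day(s), %d session(s)\n",
              n_occasions(x), length(unique(x$day)),
              length(unique(x$session))))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Number of occasions in a design
#' @param design a [study_design()].
#' @return Integer count of measurement occasions.
#' @export
n_occasions <- function(design) {
  stopifnot(inherits(design, "study_design"))
  nrow(design)
}

#' Read a study design from a YAML or JSON file
#'
#' The file must contain a list `occasions`, each element with fields
#' `occasion` (or `label`), `day` and `session`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [study_design()].
#' @export
read_study_design <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported design file extension: ", ext)
  )
  occ <- spec$occasions
  if (is.null(occ)) stop("design file has no 'occasions' entry")
  lab <- vapply(occ, function(o)
    as.character(o$occasion %||% o$label), character(1))
  study_design(
    occasion = lab,
    day = vapply(occ, function(o) as.character(o$day), character(1)),
    session = vapply(occ, function(o) as.character(o$session), character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
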