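#' Construct a reliability dataset
#'
#' A persons x occasions table of measurements for one region of interest
#' and one modality, with the column order matching the occasions of a
#' [study_design()].
#'
#' @param values numeric matrix or data frame, persons in rows and
#'   occasions in columns. Column names, if present, must match the
#'   design's occasion labels.
#' @param design a [study_design()]; defaults to [mpm_design()].
#' @param person_ids optional person identifiers (default row names or
#'   `P1..Pn`).
#' @param roi,modality optional labels carried through to output tables
#'   (modalities in the source protocol are MT, PD, R1 and R2*, but any
#'   label is accepted).
#' @param na_action `"error"` (default) refuses missing cells;
#'   `"omit"` drops persons with any missing value (listwise deletion).
#' @return A numeric matrix of class `reliability_data` with attributes
#'   `design`, `roi`, `modality`.
#' @export
reliability_data <- function(values, design = mpm_design(),
                             person_ids = NULL, roi = NA_character_,
                             modality = NA_character_,
                             na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  stopifnot(inherits(design, "study_design"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  k <- n_occasions(design)
  if (ncol(values) != k)
    stop("data has ", ncol(values), " columns but the design has ", k,
         " occasions")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), design$occasion)) {
    if (all(design$occasion %in% colnames(values))) {
      values <- values[, design$occasion, drop = FALSE]
    } else {
      stop("column names do not match the design occasions: ",
           paste(design$occasion, collapse = ", "))
    }
  }
  if (anyNA(values)) {
    if (na_action == "error")
      stop("missing cells in reliability data (use na_action = \"omit\" ",
           "for listwise deletion)")
    keep <- stats::complete.cases(values)
    values <- values[keep, , drop = FALSE]
    if (!is.null(person_ids)) person_ids <- person_ids[keep]
  }
  if (is.null(person_ids)) {
    person_ids <- rownames(values) %||% paste0("P", seq_len(nrow(values)))
  }
  rownames(values) <- as.character(person_ids)
  colnames(values) <- design$occasion
  structure(values, design = design, roi = roi, modality = modality,
            class = c("reliability_data", "matrix", "array"))
}

#' @export
print.reliability_data <- function(x, ...) {
  cat(sprintf("Reliability dataset: %d persons x %d occasions", nrow(x),
              ncol(x)))
  roi <- attr(x, "roi"); mod <- attr(x, "modality")
  if (!is.na(roi) || !is.na(mod))
    cat(sprintf("  [%s, %s]", roi, mod))
  cat("\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read reliability data from CSV
#'
#' Two layouts are supported. Wide: a `person` column plus one column per
#' occasion label of the design. Long: columns `person`, `occasion` (or
#' `day`+`measurement`), `value`, and optionally `roi` and `modality`; a
#' separate dataset is returned for every roi x modality combination.
#'
#' @param path CSV file path.
#' @param design a [study_design()].
#' @param na_action passed to [reliability_data()].
#' @return A `reliability_data` (wide input, or long input with a single
#'   roi/modality) or a named list of them.
#' @export
read_reliability_csv <- function(path, design = mpm_design(),
                                 na_action = "error") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"person" %in% names(df))
    stop("input CSV is missing required column 'person'")
  occ <- design$occasion
  if (all(occ %in% names(df))) {            # wide layout
    m <- as.matrix(df[occ])
    rownames(m) <- as.character(df$person)
    return(reliability_data(m, design, na_action = na_action))
  }
  if (!"value" %in% names(df))
    stop("input CSV is missing required column 'value' ",
         "(long layout) or occasion columns ",
         paste(occ, collapse = ", "), " (wide layout)")
  if (!"occasion" %in% names(df)) {
    if (!all(c("day", "measurement") %in% names(df)))
      stop("long CSV needs an 'occasion' column or 'day' + 'measurement'")
    df$occasion <- paste0("D", df$day, "M", df$measurement)
  }
  df$roi <- if ("roi" %in% names(df)) df$roi else NA_character_
  df$modality <- if ("modality" %in% names(df)) df$modality else NA_character_
  pieces <- split(df, list(df$roi, df$modality), drop = TRUE, sep = "|")
  out <- lapply(pieces, function(p) {
    w <- stats::reshape(p[c("person", "occasion", "value")],
                        idvar = "person", timevar = "occasion",
                        direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    missing_occ <- setdiff(occ, names(w))
    if (length(missing_occ))
      stop("long CSV lacks occasion(s) ", paste(missing_occ, collapse = ", "))
    m <- as.matrix(w[occ]); rownames(m) <- as.character(w$person)
    reliability_data(m, design, roi = p$roi[1], modality = p$modality[1],
                     na_action = na_action)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a reliability dataset to wide CSV
#'
#' @param data a [reliability_data()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reliability_csv <- function(data, path) {
  stopifnot(inherits(data, "reliability_data"))
  df <- data.frame(person = rownames(data), unclass(data),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
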