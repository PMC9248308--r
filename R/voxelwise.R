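#' Bundle aligned per-person per-occasion voxel maps
#'
#' @param values 5D numeric array with dimensions
#'   `c(nx, ny, nz, n_persons, k)`; all volumes must share shape and
#'   alignment.
#' @param mask logical/0-1 3D array selecting analysed voxels; default
#'   marks voxels with complete finite data.
#' @param design a [study_design()] whose occasions match the 5th
#'   dimension.
#' @param affine optional 4x4 spatial transform carried to output maps.
#' @return Object of class `voxel_map_set`.
#' @export
voxel_map_set <- function(values, mask = NULL, design = mpm_design(),
                          affine = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 5L,
            inherits(design, "study_design"))
  shape <- dim(values)[1:3]
  k <- n_occasions(design)
  if (dim(values)[5] != k)
    stop("5th dimension (", dim(values)[5], ") must equal the number of ",
         "design occasions (", k, ")")
  if (is.null(mask)) {
    mask <- array(apply(is.finite(values), 1:3, all), shape)
  } else {
    if (!all(dim(mask) == shape)) stop("mask shape does not match maps")
    mask <- array(as.logical(mask), shape)
  }
  structure(list(values = values, mask = mask, design = design,
                 affine = affine, shape = shape,
                 n_persons = dim(values)[4]),
            class = "voxel_map_set")
}

#' @export
print.voxel_map_set <- function(x, ...) {
  cat(sprintf("Voxel map set: %s volume, %d persons x %d occasions, %d in-mask voxels\n",
              paste(x$shape, collapse = "x"), x$n_persons,
              n_occasions(x$design), sum(x$mask)))
  invisible(x)
}

#' Voxel-wise intra-class effect decomposition
#'
#' Fits [iced()] independently at every in-mask voxel and returns 3D maps
#' of ICC, ICC2, the four rescaled variance proportions and a convergence
#' flag. Out-of-mask voxels are `NA`; voxels whose fit fails are flagged
#' (`converged = 0`) with `NA` summaries rather than aborting the run.
#' Voxels are processed independently, so results do not depend on
#' traversal order.
#'
#' @param maps a [voxel_map_set()].
#' @param lower_bound,free,standardize shared fitting options, as in
#'   [iced()].
#' @param verbose print progress every few thousand voxels.
#' @return A list of class `iced_maps` of 3D arrays: `icc`, `icc2`,
#'   `var_t`, `var_d`, `var_s`, `var_e` (proportions), `converged`;
#'   attributes carry the mask, design and affine.
#' @export
voxelwise_iced <- function(maps, lower_bound = 1e-4,
                           free = c("var_t", "var_d", "var_s", "var_e"),
                           standardize = FALSE, verbose = FALSE) {
  stopifnot(inherits(maps, "voxel_map_set"))
  if (maps$n_persons < 3L) stop("at least 3 persons are required")
  idx <- which(maps$mask)
  if (!length(idx)) stop("mask is empty")
  shape <- maps$shape
  out_names <- c("icc", "icc2", "var_t", "var_d", "var_s", "var_e",
                 "converged")
  out <- lapply(out_names, function(n) array(NA_real_, shape))
  names(out) <- out_names
  flat <- matrix(maps$values, nrow = prod(shape))   # voxel x (person*occ)
  np <- maps$n_persons; k <- n_occasions(maps$design)
  for (i in seq_along(idx)) {
    v <- idx[i]
    y <- matrix(flat[v, ], np, k)
    fit <- tryCatch(
      suppressWarnings(iced(reliability_data(y, maps$design),
                            lower_bound = lower_bound, free = free,
                            standardize = standardize)),
      error = function(e) NULL)
    if (is.null(fit)) {
      out$converged[v] <- 0
      next
    }
    out$converged[v] <- as.numeric(fit$converged)
    if (!fit$converged) next
    out$icc[v] <- fit$icc
    out$icc2[v] <- fit$icc2
    p <- unclass(fit$proportions)
    out$var_t[v] <- p[["var_t"]]; out$var_d[v] <- p[["var_d"]]
    out$var_s[v] <- p[["var_s"]]; out$var_e[v] <- p[["var_e"]]
    if (verbose && i %% 2000 == 0)
      message("  fitted ", i, " / ", length(idx), " voxels")
  }
  structure(out, mask = maps$mask, design = maps$design,
            affine = maps$affine, class = "iced_maps")
}

#' Extract ROI-level reliability datasets from voxel maps
#'
#' Averages in-label voxels per person and occasion for every label of an
#' integer label volume, yielding one [reliability_data()] (and the
#' within-label SDs) per region.
#'
#' @param maps a [voxel_map_set()].
#' @param labels integer 3D array aligned with the maps; 0 = background.
#' @param which_labels labels to extract (default: all nonzero present).
#' @return Named list (one element per label) of `reliability_data`
#'   objects with an `sd` attribute holding the person x occasion
#'   within-ROI SDs.
#' @export
roi_extract <- function(maps, labels, which_labels = NULL) {
  stopifnot(inherits(maps, "voxel_map_set"))
  if (!all(dim(labels) == maps$shape))
    stop("label volume shape does not match maps")
  labels <- array(as.integer(labels), maps$shape)
  present <- sort(unique(labels[labels != 0L]))
  if (is.null(which_labels)) which_labels <- present
  missing_lab <- setdiff(which_labels, present)
  if (length(missing_lab))
    stop("label(s) absent from volume: ", paste(missing_lab, collapse = ", "))
  flat <- matrix(maps$values, nrow = prod(maps$shape))
  np <- maps$n_persons; k <- n_occasions(maps$design)
  out <- lapply(which_labels, function(lb) {
    v <- which(labels == lb & maps$mask)
    if (!length(v)) stop("label ", lb, " has no in-mask voxels")
    block <- flat[v, , drop = FALSE]                 # voxels x (np*k)
    m <- matrix(colMeans(block), np, k)
    s <- matrix(apply(block, 2L, stats::sd), np, k)
    d <- reliability_data(m, maps$design, roi = paste0("label_", lb))
    attr(d, "sd") <- s
    d
  })
  names(out) <- paste0("label_", which_labels)
  out
}

#' Read aligned NIfTI volumes into a voxel map set
#'
#' @param files character matrix (persons x occasions) of NIfTI paths.
#' @param mask_file optional NIfTI mask path.
#' @param design a [study_design()] matching the columns of `files`.
#' @return A [voxel_map_set()] carrying the first volume's affine.
#' @export
read_voxel_maps <- function(files, mask_file = NULL,
                            design = mpm_design()) {
  stopifnot(is.matrix(files), ncol(files) == n_occasions(design))
  first <- RNifti::readNifti(files[1, 1])
  shape <- dim(first)[1:3]
  values <- array(NA_real_, c(shape, nrow(files), ncol(files)))
  for (p in seq_len(nrow(files))) for (o in seq_len(ncol(files))) {
    vol <- RNifti::readNifti(files[p, o])
    if (!all(dim(vol)[1:3] == shape))
      stop("volume ", files[p, o], " is not aligned with the first volume")
    values[, , , p, o] <- as.array(vol)
  }
  mask <- if (!is.null(mask_file)) {
    array(as.array(RNifti::readNifti(mask_file)) > 0, shape)
  } else NULL
  voxel_map_set(values, mask = mask, design = design,
                affine = RNifti::xform(first))
}

#' Write reliability maps as NIfTI volumes
#'
#' @param result an `iced_maps` object from [voxelwise_iced()].
#' @param dir output directory (created if needed).
#' @param reference optional NIfTI image or path whose header geometry is
#'   reused.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_iced_maps <- function(result, dir, reference = NULL) {
  stopifnot(inherits(result, "iced_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(result), function(nm) {
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- if (!is.null(reference)) {
      RNifti::asNifti(result[[nm]], reference = RNifti::asNifti(reference))
    } else RNifti::asNifti(result[[nm]])
    RNifti::writeNifti(img, path)
    path
  }, character(1))
  invisible(paths)
}
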