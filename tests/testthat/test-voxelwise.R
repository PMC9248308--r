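test_that("voxel-wise fitting on constant data reproduces the ROI fit", {
  d <- mpm_design()
  dat <- make_dataset(n = 12, seed = 21)
  shape <- c(2, 2, 1)
  values <- array(NA_real_, c(shape, 12, 4))
  for (i in 1:2) for (j in 1:2) values[i, j, 1, , ] <- unclass(dat)
  vm <- voxel_map_set(values, design = d)
  res <- voxelwise_iced(vm)
  ref <- iced(dat)
  expect_equal(unique(as.vector(res$icc)), ref$icc, tolerance = 1e-10)
  expect_equal(unique(as.vector(res$icc2)), ref$icc2, tolerance = 1e-10)
  expect_equal(unique(as.vector(res$var_t)),
               ref$proportions[["var_t"]], tolerance = 1e-10)
  expect_true(all(res$converged == 1))
})

test_that("out-of-mask voxels stay NA and failures are flagged not fatal", {
  shape <- c(3, 3, 1)
  mask <- array(TRUE, shape); mask[3, 3, 1] <- FALSE
  vm <- simulate_voxel_maps(shape, n_persons = 8, mask = mask, seed = 2)
  res <- voxelwise_iced(vm)
  expect_true(is.na(res$icc[3, 3, 1]))
  expect_true(is.na(res$converged[3, 3, 1]))
  expect_true(all(is.finite(res$icc[mask])))
  expect_error(voxelwise_iced(voxel_map_set(vm$values,
                                            mask = array(FALSE, shape))),
               "empty")
})

test_that("a two-region phantom's region-mean ICC recovers the truth", {
  shape <- c(8, 8, 2)
  vt <- array(0.2, shape); vt[1:4, , ] <- 0.8      # left high, right low
  ve <- array(0.8, shape); ve[1:4, , ] <- 0.2
  vm <- simulate_voxel_maps(shape, n_persons = 60, mean_field = 1,
                            component_fields = list(var_t = vt, var_d = 0,
                                                    var_s = 0, var_e = ve),
                            seed = 33)
  res <- voxelwise_iced(vm, free = c("var_t", "var_e"))
  left <- mean(res$icc[1:4, , ]); right <- mean(res$icc[5:8, , ])
  expect_lt(abs(left - 0.8), 0.05)
  expect_lt(abs(right - 0.2), 0.05)
  expect_gt(left - right, 0.4)                      # the step is visible
})

test_that("ROI extraction averages labelled voxels into datasets", {
  shape <- c(4, 4, 1)
  vm <- simulate_voxel_maps(shape, n_persons = 7, mean_field = 2, seed = 8)
  # single label covering everything: ROI mean equals global mean
  lab_all <- array(1L, shape)
  ds <- roi_extract(vm, lab_all)
  expect_length(ds, 1)
  flat <- matrix(vm$values, nrow = prod(shape))
  expect_equal(unclass(ds$label_1),
               matrix(colMeans(flat), 7, 4), ignore_attr = TRUE)
  # one-voxel label returns that voxel verbatim
  lab1 <- array(0L, shape); lab1[2, 3, 1] <- 5L
  d5 <- roi_extract(vm, lab1)$label_5
  expect_equal(unclass(d5), matrix(vm$values[2, 3, 1, , ], 7, 4),
               ignore_attr = TRUE)
  expect_error(roi_extract(vm, lab1, which_labels = 9), "absent")
  # phantom with known per-region means
  mu <- array(1, shape); mu[3:4, , ] <- 4
  vm2 <- simulate_voxel_maps(shape, n_persons = 200, mean_field = mu,
                             component_fields = list(var_t = 0.01,
                                                     var_d = 0, var_s = 0,
                                                     var_e = 0.01),
                             seed = 9)
  lab2 <- array(1L, shape); lab2[3:4, , ] <- 2L
  ex <- roi_extract(vm2, lab2)
  expect_equal(mean(ex$label_1), 1, tolerance = 0.05)
  expect_equal(mean(ex$label_2), 4, tolerance = 0.05)
})

test_that("NIfTI round trip preserves geometry and values", {
  tmp <- withr::local_tempdir()
  shape <- c(3, 3, 2)
  vm <- simulate_voxel_maps(shape, n_persons = 4, seed = 12)
  files <- matrix("", 4, 4)
  for (p in 1:4) for (o in 1:4) {
    f <- file.path(tmp, sprintf("p%d_o%d.nii.gz", p, o))
    RNifti::writeNifti(RNifti::asNifti(vm$values[, , , p, o]), f)
    files[p, o] <- f
  }
  rt <- read_voxel_maps(files)
  expect_equal(rt$values, vm$values, tolerance = 1e-6)
  res <- voxelwise_iced(rt)
  paths <- write_iced_maps(res, file.path(tmp, "maps"))
  expect_true(all(file.exists(paths)))
  icc_back <- RNifti::readNifti(paths[["icc"]])
  expect_equal(dim(icc_back)[1:3], shape)
  expect_equal(as.array(icc_back), res$icc, tolerance = 1e-6,
               ignore_attr = TRUE)
})
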