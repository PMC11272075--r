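test_that("NIfTI roundtrip is exact for float64 and close for float32", {
  set.seed(42)
  arr <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  aff <- diag(c(2, 2, 2.5, 1)); aff[1:3, 4] <- c(-10, 5, 3)
  f64 <- tempfile(fileext = ".nii.gz")
  write_nifti(arr, f64, affine = aff, datatype = "float64")
  img <- read_nifti(f64)
  expect_identical(img$data, arr)
  expect_equal(img$affine, aff)
  expect_equal(img$pixdim, c(2, 2, 2.5))

  f32 <- tempfile(fileext = ".nii")
  write_nifti(arr, f32, affine = aff)
  expect_lt(max(abs(read_nifti(f32)$data - arr)), 1e-6)

  arr4 <- array(runif(3 * 3 * 3 * 2), dim = c(3, 3, 3, 2))
  f4 <- tempfile(fileext = ".nii.gz")
  write_nifti(arr4, f4, datatype = "float64")
  expect_identical(read_nifti(f4)$data, arr4)
})

test_that("written NIfTI agrees with an independent reader (nibabel)", {
  set.seed(7)
  arr <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  aff <- diag(c(1.5, 1.5, 2, 1)); aff[1:3, 4] <- c(-20, 8, 1)
  path <- tempfile(fileext = ".nii.gz")
  write_nifti(arr, path, affine = aff, datatype = "float64")
  script <- paste(
    "import nibabel, numpy, sys",
    sprintf("img = nibabel.load('%s')", path),
    "d = numpy.asarray(img.dataobj)",
    "print(repr(d.shape))",
    "print(float(d.sum()))",
    "print(float(numpy.abs(img.affine).sum()))",
    sep = "; ")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE))
  expect_equal(out[1], "(3, 4, 5)")
  expect_equal(as.numeric(out[2]), sum(arr), tolerance = 1e-12)
  expect_equal(as.numeric(out[3]), sum(abs(aff)), tolerance = 1e-6)
})

test_that("vectorize/devectorize are inverse in the declared voxel order", {
  set.seed(1)
  mask <- array(runif(4 * 4 * 4) > 0.5, dim = c(4, 4, 4))
  g <- tiny_grid(mask = mask)
  expect_equal(nrow(g$voxel_index), sum(mask))

  vol <- array(rnorm(64), dim = c(4, 4, 4))
  v <- vectorize_volume(vol, g)
  # order contract: flat index k holds the voxel at voxel_index[k, ]
  for (k in sample(length(v), 5))
    expect_identical(v[k], vol[g$voxel_index[k, 1], g$voxel_index[k, 2],
                               g$voxel_index[k, 3]])
  back <- devectorize_volume(v, g, fill = 0)
  expect_identical(back[g$mask], vol[g$mask])
  expect_true(all(back[!g$mask] == 0))
  expect_identical(vectorize_volume(back, g), v)

  filled <- devectorize_volume(v, g, fill = NA_real_)
  expect_equal(sum(is.na(filled)), prod(dim(mask)) - sum(mask))

  const <- devectorize_volume(rep(7, nrow(g$voxel_index)), g)
  expect_true(all(vectorize_volume(const, g) == 7))
  expect_error(vectorize_volume(array(0, c(3, 4, 4)), g), "shape")
  expect_error(devectorize_volume(numeric(3), g), "length")
})

test_that("load_image_set stacks masked voxels, clamps, and validates", {
  g <- tiny_grid()
  dir <- tempfile(); dir.create(dir)
  set.seed(3)
  vols <- lapply(1:3, function(i) array(runif(64), dim = c(4, 4, 4)))
  vols[[2]][] <- 0
  paths <- vapply(1:3, function(i) {
    p <- file.path(dir, sprintf("s%02d.nii.gz", i))
    write_nifti(vols[[i]], p, datatype = "float64")
    p
  }, character(1))

  vm <- load_image_set(paths, g, modality = "MRI")
  expect_s3_class(vm, "voxel_matrix")
  expect_equal(dim(vm$values), c(3, 64))
  for (i in 1:3)
    expect_identical(vm$values[i, ], vectorize_volume(vols[[i]], g))
  expect_true(all(vm$values[2, ] == 0))
  expect_equal(vm$subject_ids, c("s01", "s02", "s03"))

  # permuting paths permutes rows and IDs identically
  vm2 <- load_image_set(paths[c(3, 1, 2)], g, modality = "MRI")
  expect_identical(vm2$values[1, ], vm$values[3, ])
  expect_identical(vm2$subject_ids, vm$subject_ids[c(3, 1, 2)])

  # tiny negatives clamp to zero, real negatives are rejected
  tiny_neg <- vols[[1]]; tiny_neg[1, 1, 1] <- -1e-7
  p_tiny <- file.path(dir, "tiny.nii.gz")
  write_nifti(tiny_neg, p_tiny, datatype = "float64")
  vm3 <- load_image_set(p_tiny, g)
  expect_equal(unname(vm3$values[1, 1]), 0)

  bad <- vols[[1]]; bad[2, 1, 1] <- -0.5
  p_bad <- file.path(dir, "bad.nii.gz")
  write_nifti(bad, p_bad, datatype = "float64")
  expect_error(load_image_set(p_bad, g), "negative")

  nan <- vols[[1]]; nan[1, 2, 1] <- NaN
  p_nan <- file.path(dir, "nan.nii.gz")
  write_nifti(nan, p_nan, datatype = "float64")
  expect_error(load_image_set(p_nan, g), "finite")

  p_small <- file.path(dir, "small.nii.gz")
  write_nifti(array(0, c(3, 3, 3)), p_small, datatype = "float64")
  expect_error(load_image_set(p_small, g), "small.nii.gz")
})

test_that("suvr_normalize divides by the reference median", {
  dims <- c(8, 8, 8)
  set.seed(9)
  pet <- array(runif(prod(dims), 0.5, 4), dim = dims)
  ref <- array(FALSE, dims); ref[3:6, 3:6, 3:6] <- TRUE

  out <- suvr_normalize(pet, ref)
  # brute-force per-voxel oracle
  med <- median(pet[ref])
  for (i in sample(prod(dims), 20))
    expect_equal(out[i], pet[i] / med, tolerance = 1e-12)
  expect_equal(median(out[ref]), 1, tolerance = 1e-12)

  const <- array(4, dims)
  expect_true(all(suvr_normalize(const, ref) == 1))

  # forced by the definition: reference {1,2,3} has median 2, so 5 -> 2.5
  pet2 <- array(c(1, 2, 3, 5), c(4, 1, 1))
  ref2 <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  expect_equal(suvr_normalize(pet2, ref2)[4, 1, 1], 2.5)

  # scale equivariance
  expect_equal(suvr_normalize(3.7 * pet, ref), out, tolerance = 1e-12)

  expect_error(suvr_normalize(pet, array(FALSE, dims)), "no voxels")
  neg <- pet; neg[ref] <- -1
  expect_error(suvr_normalize(neg, ref), "not positive")
})
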