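test_that("masking uses C order and round-trips with restoreVolume", {
  full <- brainMask(array(TRUE, dim = c(2, 2, 2)))
  # volume whose value is its C-order linear index
  vol <- array(0, dim = c(2, 2, 2))
  idx <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    vol[i, j, k] <- idx
    idx <- idx + 1
  }
  expect_equal(mapValues(applyMask(vol, full)), as.numeric(0:7))

  # constant field through a partial mask
  flags <- array(FALSE, dim = c(2, 2, 2))
  flags[c(1, 4, 7)] <- TRUE
  m3 <- brainMask(flags)
  expect_equal(mapValues(applyMask(array(1, dim = c(2, 2, 2)), m3)),
               c(1, 1, 1))

  # round trip on a random volume
  mask <- gridMask(200)
  v <- array(rnorm(prod(mask@dim)), dim = mask@dim)
  sm <- applyMask(v, mask)
  back <- restoreVolume(sm, fill = 0)
  expect_equal(back[mask@flags], v[mask@flags])
  expect_true(all(back[!mask@flags] == 0))
  expect_equal(mapValues(applyMask(back, mask)), mapValues(sm))

  # fill value outside the mask
  z <- restoreVolume(rep(0, nVoxels(mask)), mask, fill = -1)
  expect_true(all(z[!mask@flags] == -1))
  expect_true(all(z[mask@flags] == 0))
})

test_that("dimension mismatches are rejected with informative errors", {
  mask <- gridMask(50)
  expect_error(applyMask(array(0, dim = c(2, 2, 2)), mask), "match mask grid")
  expect_error(restoreVolume(rep(0, 7), mask), "voxel count")
  expect_error(brainMask(matrix(TRUE, 2, 2)), "3-D")
  expect_error(brainMask(array(TRUE, dim = c(2, 2, 2)),
                         affine = matrix(0, 4, 4)), "invertible")
})

test_that("NIfTI write/read round-trips maps, masks and cohorts", {
  mask <- gridMask(120)
  map <- new("SpatialMap", values = rnorm(120), mask = mask, label = "t")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiMap(map, f)
  back <- readSubjectMaps(c(s1 = f), readNiftiMask({
    fm <- withr::local_tempfile(fileext = ".nii.gz")
    writeNiftiMap(mask, fm)
    fm
  }))
  expect_equal(drop(stackData(back)), mapValues(map), tolerance = 1e-6)

  # two identical subject files give two equal rows; a wrong grid names the
  # offending subject
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiMap(map, f2)
  stack <- readSubjectMaps(c(a = f, b = f2), mask)
  expect_equal(stack@data[1, ], stack@data[2, ])
  expect_equal(subjectIds(stack), c("a", "b"))

  other <- gridMask(800)
  fbad <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiMap(new("SpatialMap", values = rnorm(800), mask = other,
                    label = ""), fbad)
  expect_error(readSubjectMaps(c(a = f, oddball = fbad), mask), "oddball")
  expect_error(readSubjectMaps(c(ghost = "no-such-file.nii"), mask), "ghost")
})

test_that("delimited cohort tables round-trip", {
  mask <- gridMask(40)
  stack <- new("CohortStack", subjects = c("s1", "s2", "s3"),
               data = rmat(3, 40, seed = 9), mask = mask)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCohortTable(stack, f)
  back <- readCohortTable(f, mask)
  expect_equal(back@data, stack@data, tolerance = 1e-12)
  expect_identical(back@subjects, stack@subjects)
  expect_error(readCohortTable(f, gridMask(30)), "does not match mask")
})

test_that("container validity catches inconsistent objects", {
  mask <- gridMask(10)
  expect_error(new("CohortStack", subjects = c("a", "a"),
                   data = matrix(0, 2, 10), mask = mask), "unique")
  expect_error(new("CohortStack", subjects = "a",
                   data = matrix(0, 2, 10), mask = mask), "row count")
  expect_error(new("SpatialMap", values = rep(0, 9), mask = mask,
                   label = "x"), "in-mask")
  expect_error(new("SpatialMap", values = c(rep(0, 9), NA), mask = mask,
                   label = "x"), "finite")
})
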