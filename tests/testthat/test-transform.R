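test_that("rotation matrices match the stated axis conventions", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  R90 <- rotation_matrix(0, 0, 90)
  expect_equal(R90[, 1], c(0, -1, 0), tolerance = 1e-12)
  expect_equal(R90[3, ], c(0, 0, 1), tolerance = 1e-12)
})

test_that("rotation matrices are orthonormal with determinant +1", {
  set.seed(8)
  for (i in 1:30) {
    ang <- runif(3, -360, 360)
    R <- rotation_matrix(ang[1], ang[2], ang[3])
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("rigid transforms map points as rotation about a center plus shift", {
  p <- c(3, -2, 7)
  expect_equal(apply_transform(rigid_transform(), p), p)
  tr <- rigid_transform(translation = c(20, 10, 2))
  expect_equal(apply_transform(tr, p), p + c(20, 10, 2))
  # rotation about a center leaves the center fixed
  ctr <- c(5, 5, 5)
  rot <- rigid_transform(angles = c(10, 20, 30), center = ctr)
  expect_equal(apply_transform(rot, ctr), ctr, tolerance = 1e-12)
})

test_that("a transform composed with its inverse is the identity", {
  tr <- rigid_transform(angles = c(0, 0, 120), translation = c(20, 10, 2),
                        center = c(4, 4, 4))
  inv <- invert_transform(tr)
  set.seed(2)
  pts <- matrix(rnorm(30, sd = 40), ncol = 3)
  mapped <- apply_transform(tr, pts)
  back <- swarmreg:::apply_matrix_form(inv, mapped)
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("rigid transforms are isometries", {
  tr <- rigid_transform(angles = c(33, -21, 140), translation = c(5, -3, 9),
                        center = c(10, 0, -5))
  set.seed(4)
  pts <- matrix(rnorm(30, sd = 25), ncol = 3)
  mapped <- apply_transform(tr, pts)
  expect_equal(as.numeric(dist(mapped)), as.numeric(dist(pts)),
               tolerance = 1e-9)
})

test_that("the homogeneous matrix form agrees with direct application", {
  tr <- rigid_transform(angles = c(12, 34, -56), translation = c(1, 2, 3),
                        center = c(7, 8, 9))
  A <- transform_matrix(tr)
  p <- c(-4, 6, 2)
  expect_equal(as.numeric(A %*% c(p, 1))[1:3], apply_transform(tr, p),
               tolerance = 1e-12)
})

test_that("identity resampling reproduces the volume at voxel centers", {
  v <- smooth_volume()
  out <- resample(v, rigid_transform(), v)
  expect_equal(out$data, v$data)
  expect_true(all(out$mask))
})

test_that("integer-voxel translation shifts a block without blur", {
  dims <- c(16L, 16L, 8L)
  arr <- array(0, dims)
  arr[5:8, 5:8, 3:4] <- 7
  v <- volume3d(arr, spacing = c(2, 2, 4))
  # transform maps fixed coords into moving space: shifting the sampling
  # point by +1 voxel in x moves the block to lower indices
  tr <- rigid_transform(translation = c(2, 0, 0))  # one voxel in x (2 mm)
  out <- resample(v, tr, v)
  expected <- array(0, dims)
  expected[4:7, 5:8, 3:4] <- 7
  expect_equal(out$data, expected)
})

test_that("transform round trips keep interpolation error small and bounded", {
  v <- smooth_volume()
  tr <- rigid_transform(angles = c(0, 0, 15), translation = c(3, -2, 1),
                        center = volume_center(v))
  there <- resample(v, tr, v)
  back <- resample(there, invert_transform(tr), v)
  ok <- back$mask & there$mask
  mae <- mean(abs(back$data[ok] - v$data[ok]))
  # trilinear error is O(h^2 |f''|); the fixture's curvature and grid give
  # a generous analytic cap well below the signal amplitude (~1.5)
  expect_lt(mae, 0.05)
  expect_gt(mean(ok), 0.5)
})

test_that("landmark error is the mean displacement between transforms", {
  set.seed(12)
  lm <- matrix(rnorm(24, sd = 60), ncol = 3)
  gold <- rigid_transform()
  expect_equal(landmark_error(gold, lm, gold), 0)
  shift <- rigid_transform(translation = c(2, 0, 0))
  expect_equal(landmark_error(shift, lm, gold), 2, tolerance = 1e-12)
  # a pure translation offset d gives exactly ||d|| for any landmarks
  d <- c(3, -4, 12)
  expect_equal(landmark_error(rigid_transform(translation = d), lm, gold),
               sqrt(sum(d^2)), tolerance = 1e-12)
  # zero iff the transforms agree on the landmarks; not symmetric in general
  rot <- rigid_transform(angles = c(0, 0, 10), center = c(1, 2, 3))
  expect_gt(landmark_error(rot, lm, gold), 0)
  expect_error(landmark_error(gold, lm[0, , drop = FALSE], gold),
               "at least one landmark")
})

test_that("volumes survive NIfTI and MetaImage round trips", {
  v <- volume3d(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                spacing = c(2.59, 2.59, 8), origin = c(-10, 5, 0))
  for (ext in c(".nii.gz", ".mha", ".mhd")) {
    path <- tempfile(fileext = ext)
    write_volume(v, path)
    back <- read_volume(path)
    expect_equal(back$data, v$data, tolerance = 1e-7)
    expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(back$origin, v$origin, tolerance = 1e-6)
    unlink(path)
    unlink(sub("\\.mhd$", ".raw", path))
  }
})

test_that("transform JSON records round trip", {
  tr <- rigid_transform(angles = c(0, 0, 120), translation = c(20, 10, 2),
                        center = c(82.2, 82.2, 56))
  path <- tempfile(fileext = ".json")
  write_transform_json(tr, path)
  back <- read_transform_json(path)
  expect_equal(back$angles, tr$angles)
  expect_equal(back$translation, tr$translation)
  expect_equal(back$center, tr$center)
  unlink(path)
})
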