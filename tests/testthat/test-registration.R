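test_that("parameter_diff is the error-vector norm over three", {
  expect_equal(parameter_diff(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(parameter_diff(c(3, 0, 0), c(0, 0, 0)), 1)
  expect_equal(parameter_diff(c(1, 1, 1), c(0, 0, 0)), sqrt(3) / 3)
  expect_error(parameter_diff(c(1, 2), c(1, 2, 3)), "length 3")
})

test_that("evaluate_against_truth splits translation and rotation blocks", {
  est <- rigid_transform(angles = c(-0.25, -0.48, 117.57),
                         translation = c(20.04, 11.16, 1.75))
  tru <- rigid_transform(angles = c(0, 0, 120), translation = c(20, 10, 2))
  d <- evaluate_against_truth(est, tru)
  expect_s3_class(d, "tbl_df")
  expect_equal(d$diff_translation, 0.40, tolerance = 0.005 / 0.40)
  expect_equal(d$diff_rotation, 0.83, tolerance = 0.005 / 0.83)
  zero <- evaluate_against_truth(tru, tru)
  expect_equal(zero$diff_translation, 0)
  expect_equal(zero$diff_rotation, 0)
})

test_that("default parameter bounds follow the field of view", {
  v <- volume3d(array(0, c(64, 64, 15)), spacing = c(2.59, 2.59, 8))
  b <- default_parameter_bounds(v)
  expect_equal(b$parameter, c("tx", "ty", "tz", "rx", "ry", "rz"))
  expect_equal(b$upper[1], 64 * 2.59 / 2)
  expect_equal(b$upper[3], 15 * 8 / 2)
  expect_equal(b$lower[4:6], c(-30, -30, -180))
  expect_equal(b$upper[6], 180)
})

test_that("self-registration with tight bounds recovers the identity", {
  spec <- small_phantom_spec(size = c(24L, 24L, 8L))
  vol <- make_phantom(spec)
  bounds <- data.frame(parameter = c("tx", "ty", "tz", "rx", "ry", "rz"),
                       lower = c(-6, -6, -6, -5, -5, -10),
                       upper = c(6, 6, 6, 5, 5, 10))
  fit <- register_volumes(vol, vol, bounds = bounds, bins = 32,
                          control = swarm_control(n_particles = 24,
                                                  n_subpopulations = 4,
                                                  iterations = 40, seed = 3),
                          truth = rigid_transform(center = volume_center(vol)))
  expect_lt(fit$diff_translation, 0.5)
  expect_lt(fit$diff_rotation, 0.5)
  # at the optimum the MI approaches the fixed image's own entropy (it can
  # slightly exceed the full-volume entropy because the metric conditions
  # on the overlap mask, which drops background-heavy border regions)
  h <- joint_histogram(vol$data, vol$data, bins = 32)
  h_fixed <- shannon_entropy(rowSums(h$counts) / h$n)
  expect_gt(fit$best_mi, 0.9 * h_fixed)
})

test_that("the best MI is recomputable from the reported transform", {
  spec <- small_phantom_spec(size = c(24L, 24L, 8L))
  pair <- make_multimodal_pair(spec, rigid_transform(translation = c(4, 2, 0)))
  fit <- register_volumes(pair$fixed, pair$moving, bins = 32,
                          control = swarm_control(n_particles = 16,
                                                  n_subpopulations = 2,
                                                  iterations = 20, seed = 8))
  mi <- registration_mi(pair$fixed, pair$moving, fit$best_transform,
                        bins = 32)
  expect_equal(fit$best_mi, mi, tolerance = 1e-9)
})

test_that("registration traces are monotone and tidy methods work", {
  spec <- small_phantom_spec(size = c(24L, 24L, 8L))
  pair <- make_multimodal_pair(spec, rigid_transform(translation = c(4, 2, 0)))
  fit <- register_volumes(pair$fixed, pair$moving, bins = 32,
                          control = swarm_control(n_particles = 16,
                                                  n_subpopulations = 2,
                                                  iterations = 15, seed = 2),
                          truth = pair$truth)
  expect_true(all(diff(fit$trace$best_mi) >= -1e-12))
  td <- tidy(fit)
  expect_named(td, c("iteration", "inertia", "best_mi"))
  gl <- glance(fit)
  expect_equal(gl$best_mi, fit$best_mi)
  expect_equal(gl$diff_translation, fit$diff_translation)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("two seeds give different traces but comparable recoveries", {
  spec <- small_phantom_spec(size = c(24L, 24L, 8L))
  pair <- make_multimodal_pair(spec, rigid_transform(translation = c(5, -3, 0)))
  bounds <- data.frame(parameter = c("tx", "ty", "tz", "rx", "ry", "rz"),
                       lower = c(-15, -15, -6, -5, -5, -20),
                       upper = c(15, 15, 6, 5, 5, 20))
  ctl <- swarm_control(n_particles = 24, n_subpopulations = 4,
                       iterations = 30)
  fits <- lapply(c(11, 12), function(sd) {
    ctl$seed <- sd
    register_volumes(pair$fixed, pair$moving, bounds = bounds, bins = 32,
                     control = ctl, truth = pair$truth)
  })
  expect_false(identical(fits[[1]]$trace$best_mi, fits[[2]]$trace$best_mi))
  expect_lt(fits[[1]]$diff_translation, 2)
  expect_lt(fits[[2]]$diff_translation, 2)
})

test_that("hopeless bounds raise an overlap error", {
  v <- volume3d(array(runif(16 * 16 * 4), c(16, 16, 4)), spacing = c(2, 2, 4))
  bounds <- data.frame(parameter = c("tx", "ty", "tz", "rx", "ry", "rz"),
                       lower = c(4000, 4000, 4000, -1, -1, -1),
                       upper = c(5000, 5000, 5000, 1, 1, 1))
  expect_error(
    register_volumes(v, v, bounds = bounds, bins = 16,
                     control = swarm_control(n_particles = 8,
                                             n_subpopulations = 2,
                                             iterations = 3, seed = 1)),
    "widen the parameter bounds")
})
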