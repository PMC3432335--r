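test_that("initialization partitions particles evenly and stays in bounds", {
  sp <- sphere_space()
  ctl <- swarm_control(n_particles = 56, n_subpopulations = 4,
                       iterations = 10, seed = 1)
  st <- initialize_swarm(sp, ctl, sphere3)
  expect_equal(as.integer(table(st$sub_id)), rep(14L, 4))
  expect_true(all(st$position >= -5.12 & st$position <= 5.11))
  vmax <- 0.5 * (5.11 - (-5.12))
  expect_true(all(abs(st$velocity) <= vmax))
  expect_equal(st$inertia, 0.98)
  # personal bests equal the first evaluation
  expect_equal(st$pbest_score,
               -apply(st$position, 1, sphere3))  # internal maximize sense
  # uneven partition differs by at most one
  sizes <- table(initialize_swarm(
    sp, swarm_control(n_particles = 11, n_subpopulations = 3,
                      iterations = 5, seed = 1), sphere3)$sub_id)
  expect_lte(diff(range(sizes)), 1)
})

test_that("initialization is deterministic per seed", {
  sp <- sphere_space()
  ctl <- quick_control()
  a <- initialize_swarm(sp, ctl, sphere3)
  b <- initialize_swarm(sp, ctl, sphere3)
  expect_identical(a, b)
})

test_that("subpopulations smaller than 2 members are rejected", {
  expect_error(swarm_control(n_particles = 5, n_subpopulations = 4),
               "at least 2 members")
})

test_that("non-finite objective values are reported with the position", {
  sp <- search_space(c(-1, -1), c(1, 1))
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_error(
    hpso_optimize(bad, sp, swarm_control(n_particles = 8,
                                         n_subpopulations = 2,
                                         iterations = 3, seed = 1)),
    "non-finite value at position")
})

test_that("the velocity update matches a hand calculation with stubbed rand", {
  # v' = w v + c1 r1 (p - x) + c2 r2 (g - x); x' = x + v'
  # with r1 = r2 = 1, w = 0.5, c1 = c2 = 2:
  upd <- swarmreg:::velocity_update(pos = 1, vel = 0.2, pbest = 1.5,
                                    attractor = 3, w = 0.5, c1 = 2, c2 = 2,
                                    r1 = 1, r2 = 1)
  expect_equal(upd$velocity, 0.5 * 0.2 + 2 * (1.5 - 1) + 2 * (3 - 1))
  expect_equal(upd$position, 1 + upd$velocity)
})

test_that("a particle at the shared best with zero velocity does not move", {
  p <- c(0.5, -0.5)
  upd <- swarmreg:::velocity_update(pos = p, vel = c(0, 0), pbest = p,
                                    attractor = p, w = 0.7, c1 = 2, c2 = 2,
                                    r1 = 1, r2 = 1)
  expect_equal(upd$velocity, c(0, 0))
  expect_equal(upd$position, p)
})

test_that("the inertia weight decreases linearly and clamps at its bounds", {
  sp <- sphere_space()
  ctl <- swarm_control(n_particles = 8, n_subpopulations = 2,
                       iterations = 100, seed = 1)
  st <- initialize_swarm(sp, ctl, sphere3)
  dw <- (0.4 - 0.98) / 100
  expect_equal(dw, -0.0058)
  ws <- numeric(120)
  for (i in 1:120) {
    st <- update_inertia(st, ctl)
    ws[i] <- st$inertia
  }
  expect_equal(ws[1], 0.98 + dw)
  expect_equal(ws[100], 0.4)   # exact endpoint of the schedule
  expect_true(all(ws >= 0.4 & ws <= 0.98))  # clamp beyond T
})

test_that("arithmetic crossover produces complementary convex offspring", {
  off <- arithmetic_crossover(c(0, 0), c(2, 4), r = 0.25)
  expect_equal(off$offspring_i, c(1.5, 3))
  expect_equal(off$offspring_j, c(0.5, 1))
  # r = 1 returns the parents unchanged
  off1 <- arithmetic_crossover(c(1, 2, 3), c(4, 5, 6), r = 1)
  expect_equal(off1$offspring_i, c(1, 2, 3))
  expect_equal(off1$offspring_j, c(4, 5, 6))
  # identical parents are a fixed point for any r
  offp <- arithmetic_crossover(c(2, 2), c(2, 2), r = 0.3)
  expect_equal(offp$offspring_i, c(2, 2))
  expect_equal(offp$offspring_j, c(2, 2))
  expect_error(arithmetic_crossover(1:2, 1:3), "same dimension")
})

test_that("crossover offspring lie in the interval spanned by the parents", {
  set.seed(99)
  for (i in 1:25) {
    a <- runif(4, -10, 10)
    b <- runif(4, -10, 10)
    off <- arithmetic_crossover(a, b)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    expect_true(all(off$offspring_i >= lo - 1e-12 & off$offspring_i <= hi + 1e-12))
    expect_true(all(off$offspring_j >= lo - 1e-12 & off$offspring_j <= hi + 1e-12))
  }
})

test_that("velocity recombination preserves each parent's speed", {
  rec <- recombine_velocities(c(3, 0), c(0, 4))
  expect_equal(rec$v_i, c(1.8, 2.4))
  expect_equal(rec$v_j, c(2.4, 3.2))
  # equal parents are unchanged
  rec2 <- recombine_velocities(c(1, 2), c(1, 2))
  expect_equal(rec2$v_i, c(1, 2))
  expect_equal(rec2$v_j, c(1, 2))
  # property: speeds preserved for random inputs
  set.seed(5)
  for (i in 1:25) {
    vi <- rnorm(3); vj <- rnorm(3)
    rec <- recombine_velocities(vi, vj)
    expect_equal(sqrt(sum(rec$v_i^2)), sqrt(sum(vi^2)), tolerance = 1e-12)
    expect_equal(sqrt(sum(rec$v_j^2)), sqrt(sum(vj^2)), tolerance = 1e-12)
  }
  # cancelling parents fall back to the originals
  rec0 <- recombine_velocities(c(1, -2), c(-1, 2))
  expect_equal(rec0$v_i, c(1, -2))
  expect_equal(rec0$v_j, c(-1, 2))
})

test_that("the crossover step conserves subpopulation sizes and the best", {
  sp <- sphere_space()
  ctl <- quick_control()
  obj <- function(x) -sum(x^2)  # maximize sense via space? keep explicit
  space_max <- search_space(rep(-5.12, 3), rep(5.11, 3), sense = "maximize")
  st <- initialize_swarm(space_max, ctl, obj)
  before_sizes <- table(st$sub_id)
  before_best <- st$gbest_score
  st2 <- crossover_step(st, obj, space_max, ctl)
  expect_identical(table(st2$sub_id), before_sizes)
  expect_gte(st2$gbest_score, before_best)
})

test_that("single-population PSO converges on the sphere function", {
  sp <- sphere_space()
  fit <- pso_optimize(sphere3, sp,
                      swarm_control(n_particles = 56, n_subpopulations = 1,
                                    iterations = 100, seed = 4))
  expect_lt(fit$best_score, 1e-6)
  # trace is the best-so-far: non-increasing for a minimization problem
  expect_true(all(diff(fit$trace$best_score) <= 1e-12))
})

test_that("hpso with one subpopulation and no crossover reduces to pso", {
  sp <- sphere_space()
  ctl <- swarm_control(n_particles = 20, n_subpopulations = 1,
                       iterations = 30, seed = 9, crossover = FALSE)
  a <- pso_optimize(sphere3, sp, ctl)
  b <- hpso_optimize(sphere3, sp, ctl)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
})

test_that("optimizer runs are reproducible and respect bounds", {
  sp <- sphere_space()
  ctl <- quick_control()
  a <- hpso_optimize(sphere3, sp, ctl)
  b <- hpso_optimize(sphere3, sp, ctl)
  expect_identical(a$trace, b$trace)
  st <- a$final_state
  expect_true(all(st$position >= -5.12 & st$position <= 5.11))
  expect_true(all(st$pbest_position >= -5.12 & st$pbest_position <= 5.11))
})

test_that("tidy, glance and autoplot work on swarm fits", {
  fit <- hpso_optimize(sphere3, sphere_space(), quick_control(iterations = 10L))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "inertia", "best_score"))
  expect_equal(nrow(td), 11)
  gl <- glance(fit)
  expect_equal(gl$best_score, fit$best_score)
  expect_s3_class(autoplot(fit), "ggplot")
})
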