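test_that("trajectory kinds evaluate per contract", {
  expect_equal(trajectory_value(traj_constant(100), c(0, 5, 1000)),
               c(100, 100, 100))
  expect_equal(trajectory_value(traj_linear(0, 10, 2), 5), 20)
  # linear trajectories clamp at zero
  expect_equal(trajectory_value(traj_linear(0, 10, -3), 10), 0)
  expect_equal(trajectory_value(traj_exponential(0, 100, log(2)), 3), 800)
  st <- traj_step(c(0, 10), c(100, 200))
  expect_equal(trajectory_value(st, 9), 100)
  expect_equal(trajectory_value(st, 10), 200)
  expect_equal(trajectory_value(traj_step(5, 7), 0), 7)
  expect_error(trajectory_value(traj_constant(1), -1), ">= 0")
  expect_error(traj_step(c(5, 5), c(1, 2)), "strictly increasing")
})

test_that("distribution specs draw from the right distributions", {
  set.seed(21)
  expect_equal(draw_values(dist_constant(3), 4), rep(3, 4))
  u <- draw_values(dist_uniform(2, 5), 1e4)
  expect_true(all(u >= 2 & u <= 5))
  expect_lt(abs(mean(u) - 3.5), 0.05)
  n <- draw_values(dist_normal(1, 2), 1e4)
  expect_lt(abs(sd(n) - 2), 0.1)
  expect_error(dist_uniform(5, 2), "low")
})

test_that("migration matrices are row-stochastic with the stated topology", {
  d0 <- demography(3, 10, traj_constant(10), migration = "none")
  expect_equal(migration_matrix(d0, 0), diag(3))

  d2 <- demography(2, 10, traj_constant(10), migration = "island",
                   migration_rate = 0.1)
  expect_equal(migration_matrix(d2, 0),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))

  d3 <- demography(3, 10, traj_constant(10), migration = "stepping_stone",
                   migration_rate = 0.05)
  m <- migration_matrix(d3, 0)
  expect_equal(m[2, ], c(0.05, 0.90, 0.05))
  expect_equal(m[1, ], c(0.95, 0.05, 0.0))
  expect_equal(m[3, ], c(0.0, 0.05, 0.95))
  expect_equal(rowSums(m), rep(1, 3))

  dc <- demography(2, 10, traj_constant(10), migration = "custom",
                   migration_rates = list("1_2" = traj_linear(0, 0, 0.01)))
  expect_equal(migration_matrix(dc, 10)[1, 2], 0.1)
  expect_equal(migration_matrix(dc, 10)[2, 1], 0)

  dbad <- demography(2, 10, traj_constant(10), migration = "island",
                     migration_rate = 0.7)
  expect_error(migration_matrix(demography(3, 10, traj_constant(10),
                                           migration = "island",
                                           migration_rate = 0.7), 0),
               "sum")
  expect_equal(rowSums(migration_matrix(dbad, 0)), rep(1, 2))
})

test_that("parent sampling is fitness-proportional and migration-aware", {
  set.seed(22)
  # uniform fitness: parenthood uniform (chi-square)
  pp <- sample_parent_pairs(10L, list(rep(1, 10)), 1, 5e4)
  tab <- tabulate(pp$index, 10)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # degenerate fitness concentrates all parenthood
  pp0 <- sample_parent_pairs(3L, list(c(1, 0, 0)), 1, 100)
  expect_true(all(pp0$index == 1L))

  # proportional sampling 1:2:1
  pp2 <- sample_parent_pairs(3L, list(c(1, 2, 1)), 1, 5e4)
  f <- tabulate(pp2$index, 3) / 1e5
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 1e5)
  expect_true(all(abs(f - c(0.25, 0.5, 0.25)) < 3 * se))

  # migration row routes parents to source populations
  set.seed(23)
  pp3 <- sample_parent_pairs(c(5L, 5L), list(rep(1, 5), rep(1, 5)),
                             c(0.8, 0.2), 5e3)
  frac <- mean(pp3$population == 2L)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 1e4))

  expect_error(sample_parent_pairs(c(5L, 0L), list(rep(1, 5), numeric(0)),
                                   c(0, 1), 10, generation = 4),
               "extinct.*generation 4")
  expect_error(sample_parent_pairs(3L, list(c(0, 0, 0)), 1, 10),
               "no positive fitness")
})

test_that("population sizes follow their trajectories exactly", {
  dem <- demography(2, 8, sizes = list(traj_linear(0, 10, 2.4),
                                       traj_constant(5)))
  cfg <- simulation_config(chrom = chrom_config(1000),
                           demography = dem,
                           maps = recomb_map_uniform(0, 1000))
  res <- run_simulation(cfg, seed = 1)
  expect_identical(res$stats$size[res$stats$population == 1],
                   as.integer(round(10 + 2.4 * 0:8)))
  expect_identical(res$stats$size[res$stats$population == 2], rep(5L, 9))
})
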