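test_that("a neutral run keeps its bookkeeping clean", {
  cfg <- neutral_config(N = 50, generations = 10, length = 1e6, rate = 1)
  res <- run_simulation(cfg, seed = 1)
  expect_equal(res$stats$size, rep(50L, 11))
  expect_false(anyNA(res$freqs$freq))
  expect_true(all(res$freqs$freq >= 0 & res$freqs$freq <= 1))
  expect_equal(res$stats$mean_fitness, rep(1, 11)) # identity fitness
  expect_equal(nrow(res$freqs), 11L)
})

test_that("identical (config, seed) gives byte-identical outputs", {
  cfg <- parse_config(system.file("extdata", "truncation_example.conf",
                                  package = "mosaicsim"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_simulation(cfg, seed = 7, outdir = d1)
  r2 <- run_simulation(cfg, seed = 7, outdir = d2)
  for (f in list.files(d1)) {
    h1 <- unname(tools::md5sum(file.path(d1, f)))
    h2 <- unname(tools::md5sum(file.path(d2, f)))
    expect_identical(h1, h2)
  }
  # a different seed changes the trajectory
  r3 <- run_simulation(cfg, seed = 8)
  expect_false(identical(r1$freqs$freq, r3$freqs$freq))
})

test_that("tidy, glance and the plot constructors work on results", {
  cfg <- neutral_config(N = 20, generations = 5, length = 1e6, rate = 1)
  res <- run_simulation(cfg, seed = 3)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("generation", "population", "freq", "size") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$final_size, 20L)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_mosaic(res$populations[[1]]), "ggplot")
})

test_that("population dumps are written at the configured generations", {
  cfg <- neutral_config(N = 10, generations = 4, length = 1e5, rate = 1,
                        dump_generations = c(0L, 4L))
  d <- withr::local_tempdir()
  run_simulation(cfg, seed = 2, outdir = d)
  expect_setequal(
    list.files(d, pattern = "^population_p"),
    c("population_p1_gen0.txt", "population_p1_gen4.txt"))
  pop <- read_population(file.path(d, "population_p1_gen4.txt"), 1e5)
  expect_equal(pop$generation, 4L)
  expect_equal(pop$size, 10L)
})

test_that("early stopping fires after reporting the stopping generation", {
  cfg <- neutral_config(N = 30, generations = 50, length = 1e5, rate = 0,
                        freq = 0.5)
  res <- run_simulation(cfg, seed = 11, stop_when = function(state)
    state$generation >= 7)
  expect_equal(res$generations_run, 7L)
  expect_equal(max(res$freqs$generation), 7L)
})

test_that("an extinct population is tolerated until parents are needed", {
  # a crash to zero is fine while no offspring are requested, but asking
  # an extinct population to reproduce raises a clear error
  dem <- demography(1, 5, sizes = traj_step(c(0, 3, 4), c(10, 0, 10)))
  cfg <- simulation_config(chrom = chrom_config(1000), demography = dem,
                           maps = recomb_map_uniform(0, 1000))
  expect_error(run_simulation(cfg, seed = 1), "extinct")
  dem2 <- demography(1, 3, sizes = traj_step(c(0, 3), c(10, 0)))
  cfg2 <- simulation_config(chrom = chrom_config(1000), demography = dem2,
                            maps = recomb_map_uniform(0, 1000))
  res <- run_simulation(cfg2, seed = 1)
  expect_equal(res$stats$size, c(10L, 10L, 10L, 0L))
})
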