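test_that("genetic_length integrates the map", {
  expect_equal(genetic_length(recomb_map_uniform(1, 100e6)), 1.0)
  expect_equal(genetic_length(recomb_map_uniform(0, 100e6)), 0.0)

  # piecewise map checked against numeric integration of the rate
  pos <- c(0, 1e6, 3e6, 5e6)
  rates <- c(1, 2, 0.5, 0)
  m <- recomb_map_table(pos, rates, 8e6)
  grid <- seq(0, 8e6 - 1, by = 1000)
  rate_at <- rates[findInterval(grid, pos)]
  expect_equal(genetic_length(m), sum(rate_at * 1000 / 1e6) / 100,
               tolerance = 1e-3)
  # rate beyond the last listed position is 0
  expect_equal(genetic_length(m),
               genetic_length(recomb_map_table(pos, rates, 5e6)))
})

test_that("map files read and cumulative-cM consistency is enforced", {
  path <- system.file("extdata", "example_map.txt", package = "mosaicsim")
  m <- read_genetic_map(path, length = 5e6)
  expect_equal(genetic_length(m), 0.06) # 6 cM
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("position rate cM", "0 1.0 0.0", "1000000 1.0 9.0"), bad)
  expect_error(read_genetic_map(bad, length = 2e6), "inconsistent")
})

test_that("sample_crossovers is Poisson with uniform bp positions", {
  expect_length(sample_crossovers(recomb_map_uniform(0, 1e6)), 0L)

  set.seed(11)
  m <- recomb_map_uniform(1, 100e6) # 1 Morgan
  draws <- replicate(2e4, sample_crossovers(m), simplify = FALSE)
  counts <- lengths(draws)
  # mean count = genetic length (duplicate removal is negligible at this
  # scale); 3 SE band
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 2e4))
  # positions uniform on the chromosome
  pos <- unlist(draws)[1:1e4]
  ks <- suppressWarnings(stats::ks.test(pos / 100e6, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pos > 0 & pos < 100e6))
})

test_that("crossovers concentrate where the map is hot", {
  set.seed(12)
  # all genetic length in the first tenth of the chromosome
  m <- recomb_map_table(c(0, 1e6), c(100, 0), 10e6)
  pos <- unlist(replicate(2000, sample_crossovers(m), simplify = FALSE))
  expect_true(all(pos <= 1e6))
})

test_that("recombine splices chunks as a double crossover mosaic", {
  a <- chromosome(0, 7, 100)
  b <- chromosome(0, 11, 100)
  r <- recombine(a, b, c(30, 70), start_with_a = TRUE)
  expect_identical(r$pos, c(0L, 30L, 70L))
  expect_identical(r$id, c(7L, 11L, 7L))

  expect_identical(unclass(recombine(a, b, integer(0)))[1:2],
                   unclass(a)[1:2])
  expect_identical(recombine(a, b, integer(0), start_with_a = FALSE)$id, 11L)
  expect_error(recombine(a, chromosome(0, 1, 50), 10), "length")
  expect_error(recombine(a, b, c(70, 30)), "increasing")
  expect_error(recombine(a, b, 100), "interior")
})

test_that("recombine matches the per-base crossover-count oracle", {
  set.seed(13)
  len <- 1000L
  for (i in 1:50) {
    a <- random_chromosome(len, id_pool = 0:4)
    b <- random_chromosome(len, id_pool = 5:9)
    nxo <- sample(0:4, 1)
    xo <- sort(sample.int(len - 1L, nxo))
    start_a <- runif(1) < 0.5
    r <- recombine(a, b, xo, start_a)
    expect_identical(expand_to_base_array(r),
                     recombine_oracle_base(a, b, xo, start_a))
    # never invents ids; bounded chunk count
    expect_true(all(r$id %in% c(a$id, b$id)))
    expect_lte(length(r$pos), length(a$pos) + length(b$pos) + nxo)
  }
})

test_that("make_gamete picks each parental copy half the time without maps", {
  set.seed(14)
  cc <- chrom_config(1000)
  pop <- make_founder_population(1, 0, cc)
  parent <- get_individual(pop, 1)
  maps <- list(recomb_map_uniform(0, 1000))
  picks <- replicate(1e4, make_gamete(parent, maps)[[1]]$id)
  expect_true(all(picks %in% 0:1))
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(picks == 0L) - 0.5), 3 * se)
})

test_that("gamete junction count matches the map length in Morgans", {
  set.seed(15)
  cc <- chrom_config(100e6)
  pop <- make_founder_population(1, 0, cc)
  parent <- get_individual(pop, 1)
  maps <- list(recomb_map_uniform(1, 100e6)) # 1 Morgan
  junctions <- replicate(1e4, length(make_gamete(parent, maps)[[1]]$pos) - 1L)
  # every crossover between distinct founders creates one junction
  expect_lt(abs(mean(junctions) - 1), 3 * sqrt(1 / 1e4))
})

test_that("structurally homozygous parents transmit their haplotype intact", {
  set.seed(16)
  ch <- random_chromosome(1000L)
  parent <- structure(list(list(ch, ch)), class = "individual")
  maps <- list(recomb_map_uniform(200, 1000)) # many crossovers
  for (i in 1:10) {
    g <- make_gamete(parent, maps)[[1]]
    expect_identical(g$pos, ch$pos)
    expect_identical(g$id, ch$id)
  }
})
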