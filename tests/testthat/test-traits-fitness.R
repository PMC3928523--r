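test_that("founder allele assignment honours the frequency spec", {
  set.seed(31)
  loc <- locus(1, 500)
  tab1 <- assign_founder_alleles(loc, 0:9, 1)
  expect_true(all(tab1[, 1] == 1L))
  tab0 <- assign_founder_alleles(loc, 0:9, 0)
  expect_true(all(tab0[, 1] == 0L))

  tab <- assign_founder_alleles(loc, 0:1999, 0.3)
  p_hat <- mean(tab[, 1])
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))

  two <- list(locus(1, 10), locus(1, 20))
  expect_no_error(assign_founder_alleles(two, 0:9, c(0.5)))
  expect_error(assign_founder_alleles(two, 0:9, c(0.1, 0.2, 0.3)),
               "one founder allele frequency per locus")
  expect_error(assign_founder_alleles(loc, 0:9, 1.5), "\\[0, 1\\]")
})

test_that("genotype reads alleles through the mosaic structure", {
  cc <- chrom_config(100)
  loc <- locus(1, 45)
  # individual: copy1 = Fig-1 style mosaic, copy2 = single founder 2
  pop <- make_founder_population(2, 0, cc)
  pop$chrom[[1]] <- list(pos = c(0L, 30L, 70L, 0L, 0L, 0L),
                         id = c(7L, 11L, 7L, 2L, 0L, 1L),
                         nch = c(3L, 1L, 1L, 1L))
  m <- matrix(NA_integer_, nrow = 12, ncol = 1)
  m[7 + 1, 1] <- 0L   # rows are founder id + 1
  m[11 + 1, 1] <- 1L
  m[2 + 1, 1] <- 0L
  table <- allele_table(m, loc)
  ind <- get_individual(pop, 1)
  expect_identical(genotype(ind, loc, table), 1L) # 11 carries 1, 2 carries 0

  # homozygous founder
  pop2 <- make_founder_population(1, 0, cc)
  t2 <- allele_table(matrix(c(1L, 1L), ncol = 1), loc)
  expect_identical(genotype(get_individual(pop2, 1), loc, t2), 2L)

  # missing table entry raises an integrity error naming the id
  t3 <- allele_table(matrix(c(1L, NA), ncol = 1), loc)
  expect_error(genotype(get_individual(pop2, 1), loc, t3), "founder id 1")
})

test_that("population genotypes equal the per-base expansion oracle", {
  set.seed(32)
  cfg <- neutral_config(N = 20, generations = 5, length = 2000L, rate = 500,
                        loci = list(locus(1, 100), locus(1, 1500)))
  res <- run_simulation(cfg, seed = 5)
  pop <- res$populations[[1]]
  tab <- res$allele_table
  geno <- genotypes(pop, attr(tab, "loci"), tab)
  for (i in seq_len(pop$size)) {
    for (l in 1:2) {
      pos <- attr(tab, "loci")$pos[l]
      ids <- c(expand_to_base_array(get_chromosome(pop, i, 1, 1))[pos + 1],
               expand_to_base_array(get_chromosome(pop, i, 1, 2))[pos + 1])
      expect_identical(geno[i, l], sum(tab[ids + 1, l]))
    }
  }
})

test_that("trait values sum QTL genotypic values plus Gaussian noise", {
  cc <- chrom_config(1000)
  pop <- make_founder_population(2, 0, cc)
  loci <- list(locus(1, 100), locus(1, 200))
  # founders 0,1 (ind 1) carry allele 1 at locus 1 only on id 0;
  # make ind 1 genotype (1, 2) by hand
  m <- matrix(c(1L, 0L, 1L, 0L,   # locus 1: ids 0..3
                1L, 1L, 0L, 0L),  # locus 2
              ncol = 2)
  table <- allele_table(m, loci)
  tr <- quantitative_trait("t", list(qtl(loci[[1]], values = c(0, 0.5, 1)),
                                     qtl(loci[[2]], values = c(0, 0.5, 1))),
                           Ve = 0)
  gv <- genetic_values(pop, tr, table)
  expect_equal(gv[1], 0.5 + 1.0) # genotypes 1 and 2
  expect_equal(trait_values(pop, tr, table), gv) # Ve = 0: no noise

  none <- quantitative_trait("null", list(), Ve = 0)
  expect_equal(trait_values(pop, none, table), c(0, 0))

  set.seed(33)
  big <- make_founder_population(1e5 %/% 2, 0, chrom_config(1000))
  bt <- quantitative_trait("noise", list(), Ve = 1)
  tv <- trait_values(big, bt, allele_table(
    matrix(integer(0), nrow = 1e5, ncol = 0), list()), Ve = 1)
  expect_lt(abs(var(tv) - 1), 3 * sqrt(2 / 5e4))
})

test_that("environmental variance calibration follows Ve = Vg(1-h2)/h2", {
  tr <- quantitative_trait("t", list(), h2 = 0.5)
  expect_equal(calibrate_environmental_variance(tr, c(0, 2)), 2) # Vg = 2
  tr1 <- quantitative_trait("t", list(), h2 = 1)
  expect_equal(calibrate_environmental_variance(tr1, c(0, 2)), 0)
  expect_error(calibrate_environmental_variance(tr, c(1, 1, 1)),
               "unattainable")

  # single additive QTL at p = 0.5, a = 1: Vg ~ 2pq a^2 = 0.5
  set.seed(34)
  ves <- replicate(30, {
    pop <- make_founder_population(500, 0, chrom_config(1000))
    loc <- locus(1, 500)
    tab <- assign_founder_alleles(loc, 0:999, 0.5)
    trq <- quantitative_trait("q", qtl(loc, effect = 1), h2 = 0.5)
    calibrate_environmental_variance(trq, genetic_values(pop, trq, tab))
  })
  se <- sd(ves) / sqrt(length(ves))
  expect_lt(abs(mean(ves) - 0.5), 3 * se + 0.01)
})

test_that("the four fitness kinds follow their formulas", {
  expect_equal(compute_fitness(fitness_identity(), 5), rep(1, 5))

  loc <- locus(1, 0)
  fs <- fitness_single_locus(loc, s = 0.1, h = 0.5)
  expect_equal(compute_fitness(fs, 3, genotype_at_locus = c(0L, 1L, 2L)),
               c(1, 1.05, 1.1))

  ft <- fitness_truncation("t", 0.2)
  w <- compute_fitness(ft, 10, trait_value = c(10, 1:9))
  expect_equal(sum(w), 2) # ceiling(0.2 * 10)
  expect_equal(which(w == 1), c(1L, 10L)) # the two largest values
  fl <- fitness_truncation("t", 0.2, direction = "low")
  expect_equal(which(compute_fitness(fl, 10, trait_value = c(10, 1:9)) == 1),
               c(2L, 3L))
  # ties at the threshold break by individual index
  wt <- compute_fitness(ft, 5, trait_value = c(1, 1, 1, 1, 1))
  expect_equal(which(wt == 1), 1L)

  fo <- fitness_optimum("t", optimum = 2, width = 0.5)
  expect_equal(compute_fitness(fo, 3, trait_value = c(2, 2.5, 1.5)),
               c(1, exp(-0.5), exp(-0.5)))
  # moving optimum follows its trajectory
  fo2 <- fitness_optimum("t", optimum = traj_linear(0, 0, 1), width = 1)
  expect_equal(compute_fitness(fo2, 1, trait_value = 5, generation = 5), 1)
})
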