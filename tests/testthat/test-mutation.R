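test_that("mutation splices a derived one-bp chunk and flips its allele", {
  loc <- locus(1, 50)
  tab <- allele_table(matrix(0L, nrow = 2, ncol = 1), loc)
  gamete <- list(chromosome(0, 0, 100))

  # mu = 0: nothing happens
  res0 <- apply_mutations(gamete, loc, mutation_spec(0), tab, next_id = 2L)
  expect_identical(res0$gamete[[1]]$id, 0L)
  expect_identical(res0$next_id, 2L)

  # mu = 1: forced mutation at position 50
  res1 <- apply_mutations(gamete, loc, mutation_spec(1), tab, next_id = 2L)
  ch <- res1$gamete[[1]]
  expect_identical(ch$pos, c(0L, 50L, 51L))
  expect_identical(ch$id, c(0L, 2L, 0L))
  expect_identical(res1$table[3, 1], 1L) # flipped copy of founder 0's row
  expect_identical(res1$next_id, 3L)

  # derived ids never collide and the mutated base is the only change
  expect_identical(founder_id_at(ch, 49), 0L)
  expect_identical(founder_id_at(ch, 50), 2L)
  expect_identical(founder_id_at(ch, 51), 0L)
})

test_that("mutation at a chunk start or chromosome end splices correctly", {
  loc0 <- locus(1, 0)
  tab <- allele_table(matrix(1L, nrow = 1, ncol = 1), loc0)
  g <- apply_mutations(list(chromosome(0, 0, 100)), loc0, mutation_spec(1),
                       tab, 1L)
  expect_identical(g$gamete[[1]]$pos, c(0L, 1L))
  expect_identical(g$gamete[[1]]$id, c(1L, 0L))
  expect_identical(g$table[2, 1], 0L)

  locend <- locus(1, 99)
  gend <- apply_mutations(list(chromosome(0, 0, 100)), locend,
                          mutation_spec(1),
                          allele_table(matrix(1L, 1, 1), locend), 1L)
  expect_identical(gend$gamete[[1]]$pos, c(0L, 99L))
  expect_identical(gend$gamete[[1]]$id, c(0L, 1L))
})

test_that("mutation counts are binomial in a simulated population", {
  set.seed(41)
  mu <- 5e-3
  n_gen <- 10
  N <- 500
  cfg <- neutral_config(N = N, generations = n_gen, length = 1000L,
                        rate = 0, loci = locus(1, 500), freq = 0,
                        mutation = mutation_spec(mu))
  # allele 1 starts absent; its mean frequency rises ~ mu per generation
  finals <- vapply(1:20, function(s) {
    res <- run_simulation(cfg, seed = s)
    res$freqs$freq[res$freqs$generation == n_gen]
  }, 1)
  se <- stats::sd(finals) / sqrt(length(finals))
  # exact symmetric-flip recursion E[p_t] = (1 - (1 - 2 mu)^t) / 2,
  # ~ mu t for small mu t
  expected <- (1 - (1 - 2 * mu)^n_gen) / 2
  expect_lt(abs(mean(finals) - expected), 4 * se)
  # derived ids extend the table, never collide with founder ids
  res <- run_simulation(cfg, seed = 9)
  expect_gt(res$next_id, 2 * N)
  expect_identical(anyDuplicated(res$origin[seq_len(2 * N)]), 0L)
})

test_that("genotypes after mutation match a per-base oracle", {
  set.seed(42)
  cfg <- neutral_config(N = 30, generations = 8, length = 2000L, rate = 100,
                        loci = list(locus(1, 400), locus(1, 1600)),
                        freq = 0.5, mutation = mutation_spec(0.05))
  res <- run_simulation(cfg, seed = 2)
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
  # every derived id's origin points back to a founding haplotype
  expect_true(all(res$origin >= 0 & res$origin < 60))
})
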