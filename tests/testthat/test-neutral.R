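test_that("ms-style founder output parses into variant data", {
  path <- system.file("extdata", "example_founders.ms",
                      package = "mosaicsim")
  fv <- read_ms(path, length = 1000)
  expect_equal(length(fv$positions), 6L)
  expect_equal(fv$positions, as.integer(round(
    c(0.05, 0.20, 0.35, 0.50, 0.75, 0.90) * 1000)))
  expect_equal(dim(fv$haplotypes), c(8L, 6L))
  expect_equal(fv$haplotypes[1, ], c(0L, 1L, 0L, 0L, 1L, 0L))

  # rounding collisions keep the first site
  txt <- c("segsites: 3", "positions: 0.1001 0.1002 0.5", "010", "101")
  fv2 <- read_ms(text = txt, length = 100)
  expect_equal(fv2$positions, c(10L, 50L))
  expect_equal(dim(fv2$haplotypes), c(2L, 2L))

  expect_error(read_ms(text = c("positions: 0.1"), length = 100),
               "segsites")
  expect_error(read_ms(text = c("segsites: 2", "positions: 0.1", "01"),
                       length = 100), "expected 2")
})

test_that("generation-0 decoration is the identity", {
  set.seed(61)
  N <- 4L
  pop <- make_founder_population(N, 0, chrom_config(1000))
  hap <- matrix(rbinom(8 * 5, 1, 0.5), nrow = 8)
  fv <- structure(list(positions = c(10L, 200L, 500L, 700L, 900L),
                       haplotypes = hap, length = 1000L, id_offset = 0L),
                  class = "founder_variants")
  out <- propagate_neutral_variation(pop, fv)
  expect_identical(out, hap)
})

test_that("decoration reads each site through the mosaic", {
  pop <- make_founder_population(6, 0, chrom_config(100))
  # replace copy 1 by the three-chunk mosaic (0,7) (30,11) (70,7)
  pop$chrom[[1]] <- list(pos = c(0L, 30L, 70L, rep(0L, 11)),
                         id = c(7L, 11L, 7L, 1:11),
                         nch = c(3L, rep(1L, 11)))
  hap <- matrix(0L, nrow = 12, ncol = 1)
  hap[11 + 1, 1] <- 1L
  fv <- structure(list(positions = 45L, haplotypes = hap, length = 100L,
                       id_offset = 0L), class = "founder_variants")
  out <- propagate_neutral_variation(pop, fv)
  expect_identical(out[1, 1], 1L) # copy 1 carries founder 11 at 45
  expect_identical(out[2, 1], 0L)

  fv$positions <- 10L
  expect_identical(propagate_neutral_variation(pop, fv)[1, 1], 0L)
})

test_that("decoration equals forward tracking of zero-effect loci", {
  # register every site as a tracked locus with no fitness effect; after
  # several generations the decoration must reproduce the forward-tracked
  # genotypes exactly
  set.seed(62)
  N <- 100L
  n_sites <- 200L
  len <- 1e6L
  site_pos <- sort(sample.int(len, n_sites)) - 1L
  loci <- lapply(site_pos, function(p) locus(1, p))
  cfg <- simulation_config(
    chrom = chrom_config(len),
    demography = demography(1, 5, sizes = traj_constant(N)),
    maps = recomb_map_uniform(2, len),
    loci = loci, freq = 0.5)
  res <- run_simulation(cfg, seed = 3)
  pop <- res$populations[[1]]
  tab <- res$allele_table

  fv <- structure(list(positions = site_pos,
                       haplotypes = unclass(tab)[, , drop = FALSE],
                       length = len, id_offset = 0L),
                  class = "founder_variants")
  decorated <- propagate_neutral_variation(pop, fv, origin = res$origin)
  odd <- seq(1L, 2L * N, by = 2L)
  geno_from_decoration <- decorated[odd, ] + decorated[odd + 1L, ]
  geno_forward <- genotypes(pop, attr(tab, "loci"), tab)
  expect_identical(unname(geno_from_decoration), unname(geno_forward))
})

test_that("decorated populations export as minimal phased VCF", {
  pop <- make_founder_population(2, 0, chrom_config(1000))
  hap <- matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L), nrow = 4)
  fv <- structure(list(positions = c(99L, 499L), haplotypes = hap,
                       length = 1000L, id_offset = 0L),
                  class = "founder_variants")
  out <- propagate_neutral_variation(pop, fv)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_gt(out, fv$positions, path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), 2L)
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(rec[2], "500") # 1-based position
  expect_equal(rec[10], "1|1")
  expect_equal(rec[11], "0|0")
})
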