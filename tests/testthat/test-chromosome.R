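test_that("chromosome construction enforces the chunk invariants", {
  ch <- chromosome(c(0, 30, 70), c(7, 11, 7), 100)
  expect_s3_class(ch, "chromosome")
  expect_identical(ch$pos, c(0L, 30L, 70L))

  expect_error(chromosome(c(10, 30), c(1, 2), 100), "start at position 0")
  expect_error(chromosome(c(0, 30, 20), c(1, 2, 3), 100),
               "strictly increasing")
  expect_error(chromosome(c(0, 120), c(1, 2), 100), "smaller than")
  expect_error(chromosome(0, -1, 100), "non-negative")
  expect_error(chromosome(integer(0), integer(0), 100), "at least one")
})

test_that("founder_id_at uses half-open chunk intervals", {
  ch <- chromosome(c(0, 30, 70), c(7, 11, 7), 100)
  expect_identical(founder_id_at(ch, 45), 11L)
  expect_identical(founder_id_at(ch, 29), 7L)
  expect_identical(founder_id_at(ch, 30), 11L) # boundary belongs to the
  expect_identical(founder_id_at(ch, 70), 7L)  # chunk that begins there
  expect_identical(founder_id_at(ch, 99), 7L)
  expect_error(founder_id_at(ch, 100), "out of range")
  expect_error(founder_id_at(ch, -1), "out of range")

  single <- chromosome(0, 5, 1000)
  expect_true(all(founder_id_at(single, c(0, 1, 500, 999)) == 5L))
})

test_that("founder_id_at agrees with a linear-scan oracle on random mosaics", {
  set.seed(42)
  for (i in 1:100) {
    ch <- random_chromosome(1000L)
    pos <- sample.int(1000L, 100L) - 1L
    expect_identical(founder_id_at(ch, pos),
                     vapply(pos, linear_scan_id, 1L, chrom = ch))
  }
})

test_that("normalize_chunks merges adjacent equal ids and preserves lookups", {
  expect_identical(
    unclass(normalize_chunks(chromosome(c(0, 50), c(3, 3), 100)))[1:2],
    list(pos = 0L, id = 3L))
  expect_identical(
    normalize_chunks(chromosome(c(0, 10, 20, 30), c(1, 2, 2, 1), 50))$pos,
    c(0L, 10L, 30L))

  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    pos <- c(0L, sort(sample.int(999L, n - 1L)))
    ids <- sample(0:3, n, replace = TRUE)
    raw <- structure(list(pos = pos, id = ids, length = 1000L),
                     class = "chromosome")
    norm <- normalize_chunks(raw)
    p <- sample.int(1000L, 1000L, replace = TRUE) - 1L
    expect_identical(founder_id_at(norm, p), founder_id_at(raw, p))
    expect_true(all(diff(norm$id) != 0L))
  }
})

test_that("chunk_table reports half-open intervals covering the chromosome", {
  tab <- chunk_table(chromosome(c(0, 30, 70), c(7, 11, 7), 100))
  expect_identical(tab$start, c(0L, 30L, 70L))
  expect_identical(tab$end, c(30L, 70L, 100L))
  expect_identical(sum(tab$end - tab$start), 100L)
})
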