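# Independent brute-force oracles used across the suite.  These expand
# the chunk representation into explicit per-base arrays or recompute
# quantities by direct enumeration; they deliberately share no code with
# the package internals they check.

# founder id at every base of a chromosome, by linear left-to-right scan
expand_to_base_array <- function(chrom) {
  out <- integer(chrom$length)
  n <- length(chrom$pos)
  for (i in seq_len(n)) {
    from <- chrom$pos[i] + 1L
    to <- if (i < n) chrom$pos[i + 1L] else chrom$length
    out[from:to] <- chrom$id[i]
  }
  out
}

# linear-scan founder id lookup at one position
linear_scan_id <- function(chrom, position) {
  hit <- chrom$id[1L]
  for (i in seq_along(chrom$pos)) {
    if (chrom$pos[i] <= position) hit <- chrom$id[i] else break
  }
  hit
}

# random normalized chromosome with ids drawn from id_pool
random_chromosome <- function(length, max_chunks = 8L, id_pool = 0:9) {
  n <- sample.int(max_chunks, 1L)
  pos <- c(0L, sort(sample.int(length - 1L, n - 1L)))
  ids <- sample(id_pool, n, replace = TRUE)
  keep <- c(TRUE, diff(ids) != 0L)
  chromosome(pos[keep], ids[keep], length)
}

# per-base recombination oracle: source copy at base p is determined by
# the number of crossovers at positions <= p
recombine_oracle_base <- function(a, b, crossovers, start_with_a) {
  base_a <- expand_to_base_array(a)
  base_b <- expand_to_base_array(b)
  p <- seq_len(a$length) - 1L
  n_xo_before <- vapply(p, function(x) sum(crossovers <= x), 1L)
  from_a <- (n_xo_before %% 2L == 0L) == start_with_a
  ifelse(from_a, base_a, base_b)
}

# per-base IBD oracle: maximal runs of shared founder id
ibd_oracle_base <- function(a, b) {
  ida <- expand_to_base_array(a)
  idb <- expand_to_base_array(b)
  seg <- ifelse(ida == idb, ida, -1L)
  r <- rle(seg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0L
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             founder_id = r$values[keep])
}

# deterministic single-locus selection recursion p' = p(p w2 + q w1)/wbar
selection_recursion <- function(p0, s, h, generations) {
  w <- c(1, 1 + h * s, 1 + s)
  p <- numeric(generations + 1L)
  p[1L] <- p0
  for (g in seq_len(generations)) {
    pq <- p[g]
    q <- 1 - pq
    wbar <- pq^2 * w[3L] + 2 * pq * q * w[2L] + q^2 * w[1L]
    p[g + 1L] <- pq * (pq * w[3L] + q * w[2L]) / wbar
  }
  p
}

# minimal neutral one-population config used by several tests
neutral_config <- function(N = 50, generations = 10, length = 1e6,
                           rate = 1, loci = locus(1, length %/% 2),
                           freq = 0.5, ...) {
  simulation_config(
    chrom = chrom_config(length),
    demography = demography(1, generations, sizes = traj_constant(N)),
    maps = recomb_map_uniform(rate, length),
    loci = loci, freq = freq, ...)
}
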