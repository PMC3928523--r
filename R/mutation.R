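#' Mutation at tracked loci
#'
#' Mutation acts on gametes: independently for each tracked locus, with
#' per-gamete probability mu the allele carried at the locus is flipped.
#' Because allele-table rows are shared by all carriers of a founder id,
#' a flip never edits the table in place.  Instead a fresh founder id is
#' allocated, its table row copies the source founder's alleles with the
#' mutated locus flipped, and a one-bp chunk `[pos, pos + 1)` carrying the
#' new id is spliced into the gamete.  Neutral genome-wide mutation is
#' out of scope here; see [propagate_neutral_variation()] for decorating
#' simulations with coalescent-simulated neutral variation.
#'
#' @param mu Per-locus per-gamete mutation probability, a single value
#'   applied to all tracked loci or one value per locus.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(mu) {
  mu <- as.numeric(mu)
  if (any(mu < 0 | mu > 1))
    stop("mutation probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(mu = mu), class = "mutation_spec")
}

# splice a 1-bp chunk [at, at+1) carrying new_id into raw chunk vectors;
# the chunk covering `at` is truncated around it and its id restored on
# [at+1, ...) only where it originally extended that far
splice_point_chunk <- function(pos, id, len, at, new_id) {
  i <- findInterval(at, pos)
  old <- id[i]
  nxt <- if (i < length(pos)) pos[i + 1L] else len
  left_pos <- pos[seq_len(i - 1L)]
  left_id <- id[seq_len(i - 1L)]
  if (pos[i] < at) {
    left_pos <- c(left_pos, pos[i])
    left_id <- c(left_id, old)
  }
  mid_pos <- at
  mid_id <- new_id
  if (nxt > at + 1L) {
    mid_pos <- c(mid_pos, at + 1L)
    mid_id <- c(mid_id, old)
  }
  right <- if (i < length(pos)) (i + 1L):length(pos) else integer(0)
  out_pos <- c(left_pos, mid_pos, pos[right])
  out_id <- c(left_id, mid_id, id[right])
  keep <- c(TRUE, diff(out_id) != 0L)
  list(pos = as.integer(out_pos[keep]), id = as.integer(out_id[keep]))
}

#' Apply mutation to one gamete
#'
#' @param gamete A haploid complement: list of one [chromosome()] per
#'   pair (see [make_gamete()]).
#' @param loci Tracked loci matching the columns of `table`.
#' @param spec A [mutation_spec()].
#' @param table An `allele_table` covering every founder id in the
#'   gamete.
#' @param next_id First unused founder id (monotone allocator).
#' @return A list with the mutated `gamete`, the possibly extended
#'   `table`, and the updated `next_id`.
#' @export
apply_mutations <- function(gamete, loci, spec, table, next_id) {
  tab <- loci_table(loci)
  mu <- spec$mu
  if (length(mu) == 1L) mu <- rep(mu, nrow(tab))
  if (length(mu) != nrow(tab))
    stop("need one mutation probability per locus", call. = FALSE)
  for (l in seq_len(nrow(tab))) {
    if (stats::runif(1) >= mu[l]) next
    k <- tab$chrom[l]
    ch <- gamete[[k]]
    src <- founder_id_at(ch, tab$pos[l])
    if (src + 1L > nrow(table) || anyNA(table[src + 1L, ]))
      stop("allele table has no entry for founder id ", src, call. = FALSE)
    new_row <- table[src + 1L, , drop = TRUE]
    new_row[l] <- 1L - new_row[l]
    table <- grow_allele_table(table, next_id, new_row)
    spl <- splice_point_chunk(ch$pos, ch$id, ch$length, tab$pos[l], next_id)
    gamete[[k]] <- chromosome(spl$pos, spl$id, ch$length)
    next_id <- next_id + 1L
  }
  list(gamete = gamete, table = table, next_id = next_id)
}

# extend an allele table with a row for a freshly allocated founder id
grow_allele_table <- function(table, id, row) {
  loci <- attr(table, "loci")
  m <- unclass(table)
  if (id + 1L > nrow(m)) {
    extra <- matrix(NA_integer_, nrow = id + 1L - nrow(m), ncol = ncol(m))
    m <- rbind(m, extra)
  }
  m[id + 1L, ] <- as.integer(row)
  new_allele_table(m, loci)
}

# Engine-level mutation over a whole offspring population (flat layout).
# Draw order: loci in column order, then chromosome copies in index
# order.  Returns updated pop/table/next_id/origin.
mutate_population <- function(pop, loci_tab, mu, table, next_id, origin) {
  ncopy <- 2L * pop$size
  if (ncopy == 0L || nrow(loci_tab) == 0L)
    return(list(pop = pop, table = table, next_id = next_id,
                origin = origin))
  if (length(mu) == 1L) mu <- rep(mu, nrow(loci_tab))
  for (l in seq_len(nrow(loci_tab))) {
    if (mu[l] == 0) next
    hits <- which(stats::runif(ncopy) < mu[l])
    for (j in hits) {
      k <- loci_tab$chrom[l]
      cd <- pop$chrom[[k]]
      ends <- cumsum(cd$nch)
      from <- ends[j] - cd$nch[j] + 1L
      rng <- from:ends[j]
      src <- cd$id[rng][findInterval(loci_tab$pos[l], cd$pos[rng])]
      new_row <- unclass(table)[src + 1L, , drop = TRUE]
      new_row[l] <- 1L - new_row[l]
      table <- grow_allele_table(table, next_id, new_row)
      origin[next_id + 1L] <- origin[src + 1L]
      spl <- splice_point_chunk(cd$pos[rng], cd$id[rng], pop$lengths[k],
                                loci_tab$pos[l], next_id)
      cd$pos <- c(cd$pos[seq_len(from - 1L)], spl$pos,
                  if (ends[j] < length(cd$pos))
                    cd$pos[(ends[j] + 1L):length(cd$pos)])
      cd$id <- c(cd$id[seq_len(from - 1L)], spl$id,
                 if (ends[j] < length(cd$id))
                   cd$id[(ends[j] + 1L):length(cd$id)])
      cd$nch[j] <- length(spl$pos)
      pop$chrom[[k]] <- cd
      next_id <- next_id + 1L
    }
  }
  list(pop = pop, table = table, next_id = next_id, origin = origin)
}
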