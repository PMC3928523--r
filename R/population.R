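#' Chromosome-pair configuration
#'
#' @param lengths Integer vector of chromosome lengths in bp, one per pair.
#' @return An object of class `chrom_config` with fields `pair_count` and
#'   `lengths`.
#' @examples
#' chrom_config(c(1e6, 2e6))
#' @export
chrom_config <- function(lengths) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || anyNA(lengths) || any(lengths < 1L))
    stop("chromosome lengths must be integers >= 1", call. = FALSE)
  structure(list(pair_count = length(lengths), lengths = lengths),
            class = "chrom_config")
}

# Populations are stored flat for speed: per chromosome pair, the chunk
# arrays of all 2*size copies are concatenated (`pos`, `id`) with `nch`
# giving each copy's chunk count.  Copy 2*i + c (c in 0:1) is the c-th
# copy of 0-based individual i.
new_population <- function(id, generation, size, lengths, chrom) {
  structure(list(id = as.integer(id), generation = as.integer(generation),
                 size = as.integer(size), lengths = as.integer(lengths),
                 chrom = chrom),
            class = "sim_population")
}

#' Create a founder population
#'
#' Builds generation 0 of a simulation.  Every founding individual carries
#' two founding haplotypes, each assigned a unique integer id; ids are
#' allocated contiguously from `id_offset`, two per individual, and the
#' same id is reused across all chromosome pairs of one haploid complement
#' (so the id range identifies the population of origin under admixture).
#' Every chromosome copy starts as a single chunk `(0, id)`.
#'
#' @param size Number of diploid individuals (>= 0; 0 gives an extinct
#'   population that downstream code must tolerate).
#' @param id_offset First founder id to allocate (>= 0).  Use disjoint
#'   offsets (e.g. multiples of `2 * size`) for multiple populations.
#' @param chrom_cfg A [chrom_config()].
#' @param pop_id Integer label for the population.
#' @return A `sim_population` at generation 0.
#' @examples
#' make_founder_population(2, 0, chrom_config(100))
#' @export
make_founder_population <- function(size, id_offset, chrom_cfg, pop_id = 1L) {
  size <- as.integer(size)
  id_offset <- as.integer(id_offset)
  if (is.na(size) || size < 0L) stop("size must be >= 0", call. = FALSE)
  if (is.na(id_offset) || id_offset < 0L)
    stop("id_offset must be >= 0", call. = FALSE)
  ncopy <- 2L * size
  ids <- if (ncopy > 0L) id_offset + seq_len(ncopy) - 1L else integer(0)
  chrom <- lapply(seq_len(chrom_cfg$pair_count), function(k) {
    list(pos = integer(ncopy), id = ids, nch = rep(1L, ncopy))
  })
  new_population(pop_id, 0L, size, chrom_cfg$lengths, chrom)
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> id", x$id, "generation", x$generation,
      "size", x$size, "\n")
  cat("chromosome pairs:", length(x$lengths),
      "(lengths", paste(x$lengths, collapse = ", "), "bp)\n")
  nch <- unlist(lapply(x$chrom, `[[`, "nch"))
  if (length(nch))
    cat("mean chunks per chromosome copy:",
        format(mean(nch), digits = 4), "\n")
  invisible(x)
}

#' Number of chromosome copies in a population
#' @param pop A `sim_population`.
#' @return `2 * size`.
#' @export
n_copies <- function(pop) 2L * pop$size

#' Extract one chromosome copy from a population
#'
#' @param pop A `sim_population`.
#' @param individual 1-based individual index.
#' @param pair 1-based chromosome-pair index.
#' @param copy Copy within the pair, 1 or 2.
#' @return A [chromosome()].
#' @export
get_chromosome <- function(pop, individual, pair, copy) {
  if (individual < 1L || individual > pop$size)
    stop("individual index out of range", call. = FALSE)
  if (pair < 1L || pair > length(pop$lengths))
    stop("chromosome pair index out of range", call. = FALSE)
  if (!copy %in% c(1L, 2L)) stop("copy must be 1 or 2", call. = FALSE)
  cd <- pop$chrom[[pair]]
  j <- 2L * (individual - 1L) + copy
  ends <- cumsum(cd$nch)
  from <- ends[j] - cd$nch[j] + 1L
  chromosome(cd$pos[from:ends[j]], cd$id[from:ends[j]], pop$lengths[pair])
}

#' Extract one diploid individual
#'
#' @inheritParams get_chromosome
#' @return An object of class `individual`: a list with one element per
#'   chromosome pair, each a list of two [chromosome()] copies.
#' @export
get_individual <- function(pop, individual) {
  pairs <- lapply(seq_along(pop$lengths), function(k) {
    list(get_chromosome(pop, individual, k, 1L),
         get_chromosome(pop, individual, k, 2L))
  })
  structure(pairs, class = "individual")
}

#' All founder ids present in a population
#' @param pop A `sim_population`.
#' @return Sorted integer vector of distinct founder ids.
#' @export
founder_ids <- function(pop) {
  sort(unique(unlist(lapply(pop$chrom, `[[`, "id"))))
}

#' Chunks of every chromosome copy as a tibble
#'
#' @param pop A `sim_population`.
#' @return A tibble with columns `individual` (1-based), `pair`, `copy`
#'   (1/2), `start`, `end`, `founder_id`.
#' @export
population_table <- function(pop) {
  purrr::map_dfr(seq_along(pop$lengths), function(k) {
    cd <- pop$chrom[[k]]
    copy_of_chunk <- rep.int(seq_along(cd$nch), cd$nch)
    ends <- cumsum(cd$nch)
    # chunk end = next chunk's start within the same copy, else chrom end
    end_pos <- c(cd$pos[-1L], NA_integer_)
    end_pos[ends] <- pop$lengths[k]
    tibble::tibble(
      individual = (copy_of_chunk + 1L) %/% 2L,
      pair = k,
      copy = 2L - copy_of_chunk %% 2L,
      start = cd$pos,
      end = end_pos,
      founder_id = cd$id
    )
  })
}

#' Write a population dump
#'
#' Plain-text, round-trip exact format:
#' \preformatted{
#' population <id> generation <g> size <n>
#' individual <i>
#' chrom <k> copy <0|1> : (pos1,id1) (pos2,id2) ...
#' }
#' Individual indices `i` are 0-based, pair indices `k` are 1-based.
#'
#' @param pop A `sim_population`.
#' @param path Output file path (or a connection).
#' @return `path`, invisibly.
#' @seealso [read_population()]
#' @export
write_population <- function(pop, path) {
  lines <- character(1L + pop$size * (1L + 2L * length(pop$lengths)))
  lines[1L] <- sprintf("population %d generation %d size %d",
                       pop$id, pop$generation, pop$size)
  at <- 2L
  offsets <- lapply(pop$chrom, function(cd) {
    ends <- cumsum(cd$nch)
    cbind(ends - cd$nch + 1L, ends)
  })
  for (i in seq_len(pop$size)) {
    lines[at] <- sprintf("individual %d", i - 1L)
    at <- at + 1L
    for (k in seq_along(pop$lengths)) {
      cd <- pop$chrom[[k]]
      for (cc in 0:1) {
        j <- 2L * (i - 1L) + cc + 1L
        rng <- offsets[[k]][j, ]
        chunks <- paste0("(", cd$pos[rng[1L]:rng[2L]], ",",
                         cd$id[rng[1L]:rng[2L]], ")", collapse = " ")
        lines[at] <- sprintf("chrom %d copy %d : %s", k, cc, chunks)
        at <- at + 1L
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a population dump written by [write_population()]
#'
#' @param path File path (or connection).
#' @param lengths Chromosome lengths in bp, one per pair (the dump stores
#'   chunk starts only).
#' @return A `sim_population`.
#' @export
read_population <- function(path, lengths) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1L],
                    regexec("^population (\\d+) generation (\\d+) size (\\d+)$",
                            lines[1L]))[[1L]]
  if (length(hdr) != 4L)
    stop("malformed population header: ", lines[1L], call. = FALSE)
  id <- as.integer(hdr[2L]); gen <- as.integer(hdr[3L])
  size <- as.integer(hdr[4L])
  lengths <- as.integer(lengths)
  npair <- length(lengths)
  chrom <- lapply(seq_len(npair), function(k)
    list(pos = vector("list", 2L * size), id = vector("list", 2L * size)))
  at <- 2L
  for (i in seq_len(size)) {
    if (lines[at] != sprintf("individual %d", i - 1L))
      stop("expected 'individual ", i - 1L, "' at line ", at, call. = FALSE)
    at <- at + 1L
    for (k in seq_len(npair)) {
      for (cc in 0:1) {
        m <- regexec("^chrom (\\d+) copy ([01]) : (.+)$", lines[at])
        parts <- regmatches(lines[at], m)[[1L]]
        if (length(parts) != 4L || as.integer(parts[2L]) != k ||
            as.integer(parts[3L]) != cc)
          stop("malformed chunk line at line ", at, ": ", lines[at],
               call. = FALSE)
        nums <- as.integer(unlist(regmatches(
          parts[4L], gregexpr("-?\\d+", parts[4L]))))
        pos <- nums[seq(1L, length(nums), by = 2L)]
        cid <- nums[seq(2L, length(nums), by = 2L)]
        j <- 2L * (i - 1L) + cc + 1L
        chrom[[k]]$pos[[j]] <- pos
        chrom[[k]]$id[[j]] <- cid
        at <- at + 1L
      }
    }
  }
  chrom <- lapply(chrom, function(cd) {
    nch <- vapply(cd$pos, length, 1L)
    list(pos = as.integer(unlist(cd$pos)), id = as.integer(unlist(cd$id)),
         nch = nch)
  })
  new_population(id, gen, size, lengths, chrom)
}

# Concatenate several populations into one flat structure (used for
# cross-population parent indexing during migration).  Returns the merged
# chromosome data plus the 0-based global index offset of each population.
merge_population_chrom <- function(pops) {
  sizes <- vapply(pops, `[[`, 1L, "size")
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  npair <- length(pops[[1L]]$lengths)
  chrom <- lapply(seq_len(npair), function(k) {
    list(pos = unlist(lapply(pops, function(p) p$chrom[[k]]$pos)),
         id = unlist(lapply(pops, function(p) p$chrom[[k]]$id)),
         nch = unlist(lapply(pops, function(p) p$chrom[[k]]$nch)))
  })
  list(chrom = chrom, offsets = offsets, sizes = sizes)
}
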