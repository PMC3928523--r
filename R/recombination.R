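#' Recombination maps
#'
#' A recombination map converts base-pair positions to genetic distance and
#' drives crossover sampling during meiosis.  Two kinds are supported:
#' a uniform map (constant rate in cM/Mb over the chromosome) and a table
#' map (piecewise-constant rates between listed positions, as in
#' HapMap-style genetic-map files).  Internally both are stored as a
#' breakpoint table with cumulative genetic position; genetic distance is
#' linear between breakpoints and the rate beyond the last listed position
#' is 0.
#'
#' @param rate Recombination rate in cM per Mb.
#' @param length Chromosome length in bp.
#' @return An object of class `recomb_map` with fields `bp` (breakpoint
#'   positions, starting at 0 and ending at `length`) and `cum_morgans`
#'   (cumulative genetic position in Morgans at each breakpoint).
#' @examples
#' m <- recomb_map_uniform(1, 100e6) # 1 cM/Mb over 100 Mb = 1 Morgan
#' genetic_length(m)
#' @export
recomb_map_uniform <- function(rate, length) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  length <- as.integer(length)
  new_recomb_map(bp = c(0, length),
                 cum_morgans = c(0, rate * length / 1e6 / 100),
                 length = length)
}

#' @rdname recomb_map_uniform
#' @param positions Positions in bp, strictly increasing, starting at 0.
#' @param rates Rates in cM/Mb applying from each position to the next.
#' @param cum_cM Cumulative genetic map position in cM at each position.
#'   If `NULL`, computed from the rates.  When given, it must be
#'   consistent with the rates between consecutive positions (within 1e-6
#'   cM).
#' @export
recomb_map_table <- function(positions, rates, length, cum_cM = NULL) {
  positions <- as.numeric(positions)
  if (length(positions) < 1L || positions[1L] != 0)
    stop("map positions must start at 0", call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE))
    stop("map positions must be strictly increasing", call. = FALSE)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (length(rates) != length(positions))
    stop("one rate per position is required", call. = FALSE)
  length <- as.integer(length)
  if (positions[length(positions)] > length)
    stop("map positions exceed the chromosome length", call. = FALSE)
  implied <- cumsum(c(0, rates[-length(rates)] * diff(positions) / 1e6))
  if (is.null(cum_cM)) {
    cum_cM <- implied
  } else {
    if (any(abs(diff(cum_cM) - diff(implied)) > 1e-6))
      stop("cumulative cM inconsistent with rates between positions",
           call. = FALSE)
    cum_cM <- cum_cM - cum_cM[1L]
  }
  # rate beyond the last listed position is 0
  bp <- c(positions, length)
  cum <- c(cum_cM, cum_cM[length(cum_cM)] +
             rates[length(rates)] * (length - positions[length(positions)]) / 1e6)
  keep <- !duplicated(bp, fromLast = TRUE)
  new_recomb_map(bp = bp[keep], cum_morgans = cum[keep] / 100,
                 length = length)
}

new_recomb_map <- function(bp, cum_morgans, length) {
  if (any(diff(cum_morgans) < -1e-12))
    stop("cumulative genetic position must be non-decreasing", call. = FALSE)
  structure(list(bp = as.numeric(bp), cum_morgans = as.numeric(cum_morgans),
                 length = as.integer(length)),
            class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat("<recomb_map>", x$length, "bp,",
      format(genetic_length(x), digits = 4), "Morgans,",
      length(x$bp), "breakpoints\n")
  invisible(x)
}

#' Read a HapMap-style genetic map file
#'
#' Whitespace- or tab-delimited text with one header line and columns
#' `position`, `COMBINED_rate(cM/Mb)`, `Genetic_Map(cM)`; one file per
#' chromosome.
#'
#' @param path Path to the map file.
#' @param length Chromosome length in bp; defaults to the last listed
#'   position.
#' @return A `recomb_map`.
#' @export
read_genetic_map <- function(path, length = NULL) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  if (ncol(tab) < 3L)
    stop("genetic map file needs 3 columns: position, rate (cM/Mb), ",
         "cumulative cM", call. = FALSE)
  if (is.null(length)) length <- tab[[1L]][nrow(tab)]
  recomb_map_table(tab[[1L]], tab[[2L]], length, cum_cM = tab[[3L]])
}

#' Total genetic length of a map
#'
#' @param map A `recomb_map`.
#' @return Length in Morgans (cumulative cM at the chromosome end / 100).
#'   The expected number of crossovers per meiosis equals this value.
#' @export
genetic_length <- function(map) {
  map$cum_morgans[length(map$cum_morgans)]
}

#' Sample crossover positions for one meiosis
#'
#' The number of crossovers is Poisson with mean equal to the genetic map
#' length in Morgans (no interference, no obligate chiasma); genetic
#' positions are i.i.d. uniform on the genetic map and converted to bp by
#' inverting the cumulative map with linear interpolation, then rounded to
#' the nearest integer bp.  Duplicates and chromosome-end collisions after
#' rounding are removed.
#'
#' @param map A `recomb_map`.
#' @return Sorted integer vector of distinct crossover positions, all in
#'   `(0, length)`.
#' @export
sample_crossovers <- function(map) {
  cpp_sample_crossovers(map$bp, map$cum_morgans, map$length)
}

#' Recombine two chromosome copies at given crossover positions
#'
#' Produces the mosaic that reads from the starting copy on `[0, x1)`, the
#' other copy on `[x1, x2)`, and so on, alternating source at each
#' crossover.  The result is normalized (no adjacent chunks with equal
#' founder id).  Two crossovers between two single-chunk founder
#' chromosomes therefore yield three chunks, the outer two carrying the
#' starting founder's id.
#'
#' @param copy_a,copy_b [chromosome()] copies of equal length.
#' @param crossovers Sorted distinct integer positions in `(0, length)`.
#' @param start_with_a Read from `copy_a` before the first crossover?
#' @return A [chromosome()].
#' @examples
#' a <- chromosome(0, 7, 100)
#' b <- chromosome(0, 11, 100)
#' recombine(a, b, c(30, 70)) # chunks (0,7) (30,11) (70,7)
#' @export
recombine <- function(copy_a, copy_b, crossovers, start_with_a = TRUE) {
  if (copy_a$length != copy_b$length)
    stop("chromosome copies differ in length", call. = FALSE)
  crossovers <- as.integer(crossovers)
  if (length(crossovers)) {
    if (is.unsorted(crossovers, strictly = TRUE))
      stop("crossovers must be strictly increasing", call. = FALSE)
    if (crossovers[1L] <= 0L || crossovers[length(crossovers)] >= copy_a$length)
      stop("crossovers must be interior to the chromosome", call. = FALSE)
  }
  res <- cpp_recombine(copy_a$pos, copy_a$id, copy_b$pos, copy_b$id,
                       copy_a$length, crossovers, isTRUE(start_with_a))
  chromosome(res$pos, res$id, copy_a$length)
}

#' Form one gamete from a diploid parent
#'
#' For each chromosome pair independently: sample crossovers from that
#' pair's map, pick the starting copy by a fair coin, and recombine.
#' Chromosome pairs assort freely (independent coins).
#'
#' @param parent An `individual` (see [get_individual()]).
#' @param maps List of `recomb_map`, one per chromosome pair.
#' @return A haploid complement: list of one [chromosome()] per pair.
#' @export
make_gamete <- function(parent, maps) {
  if (length(maps) != length(parent))
    stop("one recombination map per chromosome pair is required",
         call. = FALSE)
  lapply(seq_along(parent), function(k) {
    xo <- sample_crossovers(maps[[k]])
    start_a <- stats::runif(1) < 0.5
    recombine(parent[[k]][[1L]], parent[[k]][[2L]], xo, start_a)
  })
}
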