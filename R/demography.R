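#' Demographic configuration
#'
#' Describes how many populations exist, how long the simulation runs,
#' how population sizes change over time, and how much migration connects
#' the populations.  Migration is parameterized from the offspring's side:
#' the rate for the ordered pair (i, j) is the probability that an
#' offspring born in population i draws a parent from population j
#' (gamete migration; the two parents migrate independently).
#'
#' Three topologies are provided.  `island`: every ordered pair of
#' distinct populations gets the same rate.  `stepping_stone`: only
#' adjacent populations (|i - j| = 1) exchange migrants, each at the given
#' rate.  `custom`: an explicit list of per-pair rate trajectories.
#'
#' @param population_count Number of populations (>= 1).
#' @param generation_count Number of generations to simulate (>= 1).
#' @param sizes A single trajectory (shared by all populations) or a list
#'   of one size trajectory per population.  Sizes are rounded to the
#'   nearest integer, minimum 0.
#' @param migration `"none"`, `"island"`, `"stepping_stone"`, or
#'   `"custom"`.
#' @param migration_rate Trajectory (or single number) giving the
#'   per-pair migration rate for the island / stepping-stone topologies.
#' @param migration_rates For `migration = "custom"`: a named list with
#'   entries `"i_j"` (offspring population i, parent population j) each a
#'   trajectory or number; missing pairs default to 0.
#' @return An object of class `demography`.
#' @examples
#' demography(2, 50, sizes = traj_constant(100),
#'            migration = "island", migration_rate = 0.1)
#' @export
demography <- function(population_count, generation_count, sizes,
                       migration = c("none", "island", "stepping_stone",
                                     "custom"),
                       migration_rate = NULL, migration_rates = NULL) {
  population_count <- as.integer(population_count)
  generation_count <- as.integer(generation_count)
  if (population_count < 1L) stop("need at least one population",
                                  call. = FALSE)
  if (generation_count < 1L) stop("need at least one generation",
                                  call. = FALSE)
  migration <- match.arg(migration)
  as_traj <- function(x) if (inherits(x, "trajectory")) x else
    traj_constant(x)
  if (inherits(sizes, "trajectory") || is.numeric(sizes))
    sizes <- rep(list(as_traj(sizes)), population_count)
  if (length(sizes) != population_count)
    stop("one size trajectory per population is required", call. = FALSE)
  sizes <- lapply(sizes, as_traj)
  if (migration %in% c("island", "stepping_stone")) {
    if (is.null(migration_rate))
      stop("migration_rate is required for ", migration, " topology",
           call. = FALSE)
    migration_rate <- as_traj(migration_rate)
  }
  if (migration == "custom") {
    if (is.null(migration_rates))
      stop("migration_rates is required for custom topology", call. = FALSE)
    migration_rates <- lapply(migration_rates, as_traj)
  }
  structure(list(population_count = population_count,
                 generation_count = generation_count,
                 sizes = sizes, migration = migration,
                 migration_rate = migration_rate,
                 migration_rates = migration_rates),
            class = "demography")
}

#' Population sizes at a generation
#' @param dem A [demography()].
#' @param generation Generation `>= 0`.
#' @return Integer vector of sizes (trajectory values rounded to nearest
#'   integer, minimum 0).
#' @export
population_sizes <- function(dem, generation) {
  vapply(dem$sizes, function(tr)
    max(0L, as.integer(round(trajectory_value(tr, generation)))), 1L)
}

#' Migration matrix at a generation
#'
#' Entry `m[i, j]` (j != i) is the probability that an offspring born in
#' population i draws a given parent from population j; `m[i, i]` is the
#' remainder, so rows sum to 1.
#'
#' @param dem A [demography()].
#' @param generation Generation `>= 0`.
#' @return A `population_count` x `population_count` row-stochastic
#'   matrix.
#' @export
migration_matrix <- function(dem, generation) {
  K <- dem$population_count
  m <- matrix(0, K, K)
  if (dem$migration %in% c("island", "stepping_stone")) {
    r <- trajectory_value(dem$migration_rate, generation)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (i == j) next
      if (dem$migration == "island" || abs(i - j) == 1L) m[i, j] <- r
    }
  } else if (dem$migration == "custom") {
    for (nm in names(dem$migration_rates)) {
      ij <- as.integer(strsplit(nm, "_", fixed = TRUE)[[1L]])
      if (length(ij) != 2L || anyNA(ij) || any(ij < 1L) || any(ij > K) ||
          ij[1L] == ij[2L])
        stop("bad migration pair name: ", nm, call. = FALSE)
      m[ij[1L], ij[2L]] <-
        trajectory_value(dem$migration_rates[[nm]], generation)
    }
  }
  off <- rowSums(m)
  if (any(off > 1 + 1e-12))
    stop("off-diagonal migration rates of a row sum to more than 1",
         call. = FALSE)
  diag(m) <- 1 - off
  m
}

#' Draw fitness-weighted parent pairs for a batch of offspring
#'
#' For each offspring, the source population of each of its two parents is
#' drawn independently from the migration row of the offspring's
#' population; within the source population the parent index is drawn with
#' probability proportional to fitness.  The two parents are independent
#' draws, so selfing is possible.
#'
#' @param pop_sizes Integer vector of current population sizes.
#' @param fitness List of non-negative fitness vectors, one per
#'   population.
#' @param migration_row Numeric vector of source-population probabilities
#'   for the target population (a row of [migration_matrix()]).
#' @param n_offspring Number of offspring to create.
#' @param generation Generation label used in error messages.
#' @return A list with integer matrices `population` and `index`, each
#'   `2 x n_offspring`: source population and 1-based parent index of the
#'   two parents of each offspring.
#' @export
sample_parent_pairs <- function(pop_sizes, fitness, migration_row,
                                n_offspring, generation = NA) {
  K <- length(pop_sizes)
  n2 <- 2L * n_offspring
  src <- if (K == 1L) rep(1L, n2) else
    sample.int(K, n2, replace = TRUE, prob = migration_row)
  idx <- integer(n2)
  for (j in seq_len(K)) {
    take <- which(src == j)
    if (!length(take)) next
    if (pop_sizes[j] == 0L)
      stop("no viable parents: population ", j, " is extinct at generation ",
           generation, call. = FALSE)
    w <- fitness[[j]]
    if (any(w < 0) || !any(w > 0))
      stop("no viable parents: population ", j,
           " has no positive fitness at generation ", generation,
           call. = FALSE)
    uni <- length(unique(w)) == 1L
    idx[take] <- sample.int(pop_sizes[j], length(take), replace = TRUE,
                            prob = if (uni) NULL else w)
  }
  list(population = matrix(src, nrow = 2L),
       index = matrix(idx, nrow = 2L))
}
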