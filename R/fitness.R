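#' Fitness functions
#'
#' Four fitness-function kinds determine how likely each individual is to
#' be drawn as a parent:
#'
#' * `fitness_identity()` — every individual gets fitness 1 (neutral
#'   Wright-Fisher reproduction; the default).
#' * `fitness_single_locus()` — genotypes 0/1/2 at one tracked locus get
#'   fitness 1, 1 + hs, 1 + s (h = dominance coefficient of allele 1).
#' * `fitness_truncation()` — the top (or bottom) proportion p of
#'   individuals by trait value get fitness 1, everyone else 0.  The
#'   number selected is `ceiling(p * n)`; ties at the threshold are broken
#'   by individual index.
#' * `fitness_optimum()` — Gaussian stabilizing selection,
#'   `w = exp(-(T - opt_g)^2 / (2 * width^2))`, where the optimum `opt_g`
#'   follows a trajectory so it can move over time.
#'
#' Fitness is relative: parent sampling only uses proportionality, but
#' truncation's zeros are absolute exclusions.
#'
#' @return An object of class `fitness_spec`.
#' @export
fitness_identity <- function() {
  new_fitness_spec("identity")
}

#' @rdname fitness_identity
#' @param loc The selected [locus()].
#' @param s Selection coefficient of allele 1.
#' @param h Dominance coefficient of allele 1.
#' @export
fitness_single_locus <- function(loc, s, h = 0.5) {
  new_fitness_spec("single_locus", locus = loc, s = as.numeric(s),
                   h = as.numeric(h))
}

#' @rdname fitness_identity
#' @param trait Name of the selected [quantitative_trait()].
#' @param proportion Proportion p in (0, 1] of individuals selected.
#' @param direction `"high"` (select largest trait values) or `"low"`.
#' @export
fitness_truncation <- function(trait, proportion, direction = c("high", "low")) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]", call. = FALSE)
  new_fitness_spec("truncation", trait = trait,
                   proportion = as.numeric(proportion),
                   direction = match.arg(direction))
}

#' @rdname fitness_identity
#' @param optimum Trajectory (or number) giving the optimal trait value
#'   at each generation.
#' @param width Width sigma_w > 0 of the Gaussian fitness curve.
#' @export
fitness_optimum <- function(trait, optimum, width) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  as_traj <- function(x) if (inherits(x, "trajectory")) x else
    traj_constant(x)
  optimum <- if (is.list(optimum) && !inherits(optimum, "trajectory"))
    lapply(optimum, as_traj) else list(as_traj(optimum))
  new_fitness_spec("optimum", trait = trait, optimum = optimum,
                   width = as.numeric(width))
}

new_fitness_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat("<fitness_spec>", x$kind, "\n")
  invisible(x)
}

#' Evaluate a fitness function over a population
#'
#' @param spec A `fitness_spec` (see [fitness_identity()]).
#' @param n Number of individuals.
#' @param genotype_at_locus For `single_locus`: integer vector of
#'   genotypes (0/1/2) at the selected locus.
#' @param trait_value For `truncation` / `optimum`: numeric vector of
#'   values of the selected trait.
#' @param generation Current generation (used by moving optima).
#' @param population 1-based population index (selects the population's
#'   optimum under divergent stabilizing selection).
#' @return Numeric vector of non-negative fitness values, one per
#'   individual.
#' @export
compute_fitness <- function(spec, n, genotype_at_locus = NULL,
                            trait_value = NULL, generation = 0,
                            population = 1L) {
  switch(spec$kind,
    identity = rep(1, n),
    single_locus = {
      if (is.null(genotype_at_locus))
        stop("single_locus fitness needs genotypes at the selected locus",
             call. = FALSE)
      c(1, 1 + spec$h * spec$s, 1 + spec$s)[genotype_at_locus + 1L]
    },
    truncation = {
      if (is.null(trait_value))
        stop("truncation fitness needs trait values", call. = FALSE)
      k <- ceiling(spec$proportion * n)
      ranked <- if (spec$direction == "high")
        order(-trait_value) else order(trait_value)
      w <- numeric(n)
      w[ranked[seq_len(k)]] <- 1
      w
    },
    optimum = {
      if (is.null(trait_value))
        stop("optimum fitness needs trait values", call. = FALSE)
      tr <- spec$optimum[[(population - 1L) %% length(spec$optimum) + 1L]]
      opt <- trajectory_value(tr, generation)
      exp(-(trait_value - opt)^2 / (2 * spec$width^2))
    },
    stop("unknown fitness kind: ", spec$kind, call. = FALSE)
  )
}
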