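#' Time-varying value trajectories
#'
#' Trajectories specify values that change over generations, such as
#' population sizes, migration rates or a moving trait optimum.  Four
#' kinds are available: constant, linear (clamped below at 0),
#' exponential, and step (piecewise constant).
#'
#' @param value Constant value.
#' @return An object of class `trajectory`.
#' @examples
#' trajectory_value(traj_linear(t0 = 0, v0 = 10, slope = 2), 5) # 20
#' trajectory_value(traj_step(c(0, 10), c(100, 200)), 9)        # 100
#' @export
traj_constant <- function(value) {
  new_trajectory("constant", value = as.numeric(value))
}

#' @rdname traj_constant
#' @param t0 Reference generation.
#' @param v0 Value at generation `t0`.
#' @param slope Change per generation.
#' @export
traj_linear <- function(t0, v0, slope) {
  new_trajectory("linear", t0 = as.numeric(t0), v0 = as.numeric(v0),
                 slope = as.numeric(slope))
}

#' @rdname traj_constant
#' @param rate Exponential growth rate per generation.
#' @export
traj_exponential <- function(t0, v0, rate) {
  new_trajectory("exponential", t0 = as.numeric(t0), v0 = as.numeric(v0),
                 rate = as.numeric(rate))
}

#' @rdname traj_constant
#' @param generations Strictly increasing generations at which the value
#'   changes.
#' @param values Value taken from each listed generation onward.  Before
#'   the first listed generation the first value applies.
#' @export
traj_step <- function(generations, values) {
  generations <- as.numeric(generations)
  if (length(generations) != length(values) || length(values) == 0L)
    stop("step trajectory needs matching, non-empty generations and values",
         call. = FALSE)
  if (is.unsorted(generations, strictly = TRUE))
    stop("step generations must be strictly increasing", call. = FALSE)
  new_trajectory("step", generations = generations,
                 values = as.numeric(values))
}

new_trajectory <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$kind, "\n")
  invisible(x)
}

#' Evaluate a trajectory at a generation
#'
#' @param traj A trajectory (see [traj_constant()]).
#' @param generation Generation(s) `>= 0`.
#' @return Numeric vector of values.  Linear trajectories are clamped
#'   below at 0.
#' @export
trajectory_value <- function(traj, generation) {
  g <- as.numeric(generation)
  if (any(g < 0)) stop("generation must be >= 0", call. = FALSE)
  switch(traj$kind,
    constant = rep(traj$value, length(g)),
    linear = pmax(0, traj$v0 + traj$slope * (g - traj$t0)),
    exponential = traj$v0 * exp(traj$rate * (g - traj$t0)),
    step = traj$values[pmax(1L, findInterval(g, traj$generations))],
    stop("unknown trajectory kind: ", traj$kind, call. = FALSE)
  )
}

#' Random-value distribution specifications
#'
#' Distribution specs describe how to draw particular random values in a
#' configuration, e.g. QTL positions, effect sizes or founder allele
#' frequencies.
#'
#' @param value Constant value.
#' @return An object of class `dist_spec`.
#' @export
dist_constant <- function(value) {
  new_dist_spec("constant", value = as.numeric(value))
}

#' @rdname dist_constant
#' @param low,high Bounds of a uniform distribution (`low <= high`).
#' @export
dist_uniform <- function(low, high) {
  if (low > high) stop("low must be <= high", call. = FALSE)
  new_dist_spec("uniform", low = as.numeric(low), high = as.numeric(high))
}

#' @rdname dist_constant
#' @param mean,sd Mean and standard deviation of a normal distribution
#'   (`sd >= 0`).
#' @export
dist_normal <- function(mean, sd) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  new_dist_spec("normal", mean = as.numeric(mean), sd = as.numeric(sd))
}

new_dist_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dist_spec")
}

#' Draw values from a distribution spec
#'
#' @param spec A `dist_spec` (see [dist_constant()]).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_values <- function(spec, n) {
  switch(spec$kind,
    constant = rep(spec$value, n),
    uniform = stats::runif(n, spec$low, spec$high),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
}
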