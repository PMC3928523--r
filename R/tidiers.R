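#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' Returns one row per generation, population and tracked locus with the
#' allele-1 frequency, joined with the per-population summaries (size,
#' mean fitness, mean chunks per chromosome copy).  With no tracked loci
#' the per-population summary table is returned.
#'
#' @param x A `sim_result` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sim_result <- function(x, ...) {
  if (!nrow(x$freqs)) return(x$stats)
  dplyr::left_join(x$freqs, x$stats, by = c("generation", "population"))
}

#' Glance at a simulation result
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A one-row tibble: populations, generations run, tracked loci,
#'   final total size, final mean fitness and mean chunks per chromosome
#'   copy, and the seed.
#' @export
glance.sim_result <- function(x, ...) {
  fin <- x$stats[x$stats$generation == x$generations_run, ]
  tibble::tibble(
    populations = x$config$demography$population_count,
    generations = x$generations_run,
    loci = length(x$config$loci),
    traits = length(x$config$traits),
    fitness = x$config$fitness$kind,
    final_size = sum(fin$size),
    final_mean_fitness = stats::weighted.mean(fin$mean_fitness, fin$size),
    final_mean_chunks = stats::weighted.mean(fin$mean_chunks, fin$size),
    seed = x$seed
  )
}

#' Plot allele-frequency trajectories
#'
#' @param result A `sim_result`.
#' @return A ggplot: allele-1 frequency against generation, one line per
#'   locus, faceted by population.
#' @export
plot_allele_frequencies <- function(result) {
  df <- result$freqs
  if (!nrow(df)) stop("no tracked loci to plot", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$freq,
                                   group = .data$locus,
                                   colour = factor(.data$locus))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$population, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "generation", y = "allele-1 frequency",
                  colour = "locus") +
    ggplot2::ylim(0, 1)
}

#' Plot quantitative-trait summaries over time
#'
#' @param result A `sim_result`.
#' @return A ggplot of trait mean (ribbon: +/- 1 SD) against generation
#'   per population.
#' @export
plot_trait_stats <- function(result) {
  df <- result$traits
  if (!nrow(df)) stop("no traits to plot", call. = FALSE)
  df$sd <- sqrt(df$var)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$mean,
                                   colour = factor(.data$population),
                                   fill = factor(.data$population))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$trait) +
    ggplot2::labs(x = "generation", y = "trait value",
                  colour = "population", fill = "population")
}

#' Plot the mosaic structure of a population's chromosomes
#'
#' Draws every chromosome copy of one chromosome pair as a horizontal bar
#' coloured by founder id — the classic local-ancestry "painting".
#'
#' @param pop A `sim_population`.
#' @param pair Chromosome pair to draw.
#' @return A ggplot.
#' @export
plot_mosaic <- function(pop, pair = 1L) {
  df <- population_table(pop)
  df <- df[df$pair == pair, ]
  df$copy_index <- 2L * (df$individual - 1L) + df$copy
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$copy_index - 0.45,
                                    ymax = .data$copy_index + 0.45,
                                    fill = factor(.data$founder_id))) +
    ggplot2::labs(x = "position (bp)", y = "chromosome copy",
                  fill = "founder id") +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a simulation result
#'
#' Chooses allele-frequency trajectories when loci are tracked, trait
#' summaries otherwise.
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_result <- function(object, ...) {
  if (nrow(object$freqs)) plot_allele_frequencies(object)
  else if (nrow(object$traits)) plot_trait_stats(object)
  else stop("nothing to plot: no tracked loci and no traits",
            call. = FALSE)
}
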