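#' Validation experiments against population-genetic theory
#'
#' These helpers run batteries of small simulations and summarize them
#' for comparison with closed-form predictions from population and
#' quantitative genetics: Wright-Fisher drift variance, heterozygosity
#' decay, neutral fixation probabilities, deterministic selection
#' trajectories, the breeder's equation and divergent stabilizing
#' selection.  They are the package's own correctness battery and are
#' convenient starting points for power analyses.
#'
#' `experiment_drift()` simulates `replicates` independent neutral
#' populations of constant size `N` carrying one biallelic locus at
#' founder frequency `p0` and returns the final allele frequencies, the
#' across-replicate mean expected heterozygosity 2p(1-p) per generation,
#' and the mean chunk count per chromosome copy per generation.  Under
#' Wright-Fisher theory the variance of the final frequency is
#' `p0 (1 - p0) (1 - (1 - 1/(2N))^t)` and heterozygosity decays by a
#' factor `1 - 1/(2N)` per generation.
#'
#' @param N Diploid population size.
#' @param generations Number of generations.
#' @param replicates Number of independent replicate simulations.
#' @param p0 Founder allele-1 frequency.
#' @param seed Seed for the first replicate; replicate r uses
#'   `seed + r - 1`.
#' @param length Chromosome length in bp.
#' @param rate Uniform recombination rate in cM/Mb.
#' @return For `experiment_drift()`: a list with `final_freq`
#'   (length-`replicates` vector), `mean_het` and `mean_chunks`
#'   (length `generations + 1` vectors).
#' @export
experiment_drift <- function(N = 100, generations = 50, replicates = 2000,
                             p0 = 0.5, seed = 1, length = 100e6,
                             rate = 1) {
  cfg <- simulation_config(
    chrom = chrom_config(length),
    demography = demography(1, generations, sizes = traj_constant(N)),
    maps = recomb_map_uniform(rate, length),
    loci = locus(1, length %/% 2), freq = p0)
  final_freq <- numeric(replicates)
  het <- matrix(NA_real_, replicates, generations + 1)
  chunk_sum <- numeric(generations + 1)
  for (r in seq_len(replicates)) {
    res <- run_simulation(cfg, seed = seed + r - 1)
    p <- res$freqs$freq
    final_freq[r] <- p[generations + 1]
    het[r, ] <- 2 * p * (1 - p)
    chunk_sum <- chunk_sum + res$stats$mean_chunks
  }
  list(final_freq = final_freq, het = het, mean_het = colMeans(het),
       mean_chunks = chunk_sum / replicates)
}

#' Slope of log mean heterozygosity with a replicate-bootstrap CI
#'
#' Fits log of the across-replicate mean expected heterozygosity against
#' generation and attaches a 95% confidence interval obtained by
#' resampling whole replicates, which respects the autocorrelation of
#' the mean curve across generations (an i.i.d.-residual regression CI
#' would be anti-conservative here).  Under neutral Wright-Fisher
#' reproduction the slope is `log(1 - 1/(2N))`.
#'
#' @param het Replicates x (generations + 1) matrix of per-replicate
#'   expected heterozygosity, as returned by [experiment_drift()].
#' @param bootstraps Number of bootstrap resamples.
#' @return A list with `slope` and `ci` (length-2 vector).
#' @export
heterozygosity_decay_slope <- function(het, bootstraps = 500) {
  t <- seq_len(ncol(het)) - 1
  slope_of <- function(m) {
    y <- log(colMeans(m))
    stats::cov(y, t) / stats::var(t)
  }
  boots <- vapply(seq_len(bootstraps), function(b)
    slope_of(het[sample.int(nrow(het), replace = TRUE), , drop = FALSE]),
    1)
  list(slope = slope_of(het),
       ci = unname(stats::quantile(boots, c(0.025, 0.975))))
}

#' @rdname experiment_drift
#' @param max_generations Safety cap on the number of generations run
#'   while waiting for fixation or loss.
#' @return For `experiment_fixation()`: a list with `fixed` (logical per
#'   replicate), `lost`, and `generations_to_absorption`.
#' @export
experiment_fixation <- function(N = 50, p0 = 0.1, replicates = 2000,
                                seed = 1, max_generations = 1500,
                                length = 1e6) {
  cfg <- simulation_config(
    chrom = chrom_config(length),
    demography = demography(1, max_generations,
                            sizes = traj_constant(N)),
    maps = recomb_map_uniform(0, length),
    loci = locus(1, length %/% 2), freq = p0)
  fixed <- logical(replicates)
  lost <- logical(replicates)
  gens <- integer(replicates)
  absorbed <- function(state) {
    f <- state$freqs[1, 1]
    f == 0 || f == 1
  }
  for (r in seq_len(replicates)) {
    res <- run_simulation(cfg, seed = seed + r - 1, stop_when = absorbed)
    f <- res$freqs$freq[res$generations_run + 1]
    fixed[r] <- f == 1
    lost[r] <- f == 0
    gens[r] <- res$generations_run
  }
  list(fixed = fixed, lost = lost, generations_to_absorption = gens)
}

#' @rdname experiment_drift
#' @param s,h Selection and dominance coefficients of allele 1 at the
#'   selected locus (genotype fitnesses 1, 1 + hs, 1 + s).
#' @return For `experiment_selection_trajectory()`: a list with
#'   `mean_freq` (mean simulated trajectory, length `generations + 1`)
#'   and `deterministic` (the infinite-population recursion
#'   `p' = p (p w2 + q w1) / wbar` from the same `p0`).
#' @export
experiment_selection_trajectory <- function(N = 1e4, s = 0.05, h = 0.5,
                                            p0 = 0.5, generations = 100,
                                            replicates = 20, seed = 1,
                                            length = 1e6) {
  loc <- locus(1, length %/% 2)
  cfg <- simulation_config(
    chrom = chrom_config(length),
    demography = demography(1, generations, sizes = traj_constant(N)),
    maps = recomb_map_uniform(0, length),
    loci = loc, freq = p0,
    fitness = fitness_single_locus(loc, s = s, h = h))
  acc <- numeric(generations + 1)
  for (r in seq_len(replicates))
    acc <- acc + run_simulation(cfg, seed = seed + r - 1)$freqs$freq
  w <- c(1, 1 + h * s, 1 + s)
  det <- numeric(generations + 1)
  det[1] <- p0
  for (g in seq_len(generations)) {
    p <- det[g]
    q <- 1 - p
    wbar <- p^2 * w[3] + 2 * p * q * w[2] + q^2 * w[1]
    det[g + 1] <- p * (p * w[3] + q * w[2]) / wbar
  }
  list(mean_freq = acc / replicates, deterministic = det)
}

#' @rdname experiment_drift
#' @param n_qtl Number of additive QTLs (effect `a` each, founder
#'   frequency 0.5).
#' @param a Additive effect size per QTL.
#' @param h2 Narrow-sense heritability used to calibrate environmental
#'   variance.
#' @param proportion Truncation-selection proportion.
#' @return For `experiment_selection_response()`: a tibble with one row
#'   per replicate: selection differential `S` (mean trait of the
#'   selected parents minus the population mean), response `R`
#'   (offspring mean minus parental-generation mean), and the ratio
#'   `R / (h2 * S)` that the breeder's equation predicts to be 1.
#' @export
experiment_selection_response <- function(N = 2000, n_qtl = 50, a = 0.2,
                                          h2 = 0.5, proportion = 0.2,
                                          replicates = 50, seed = 1,
                                          length = 100e6) {
  pos <- as.integer(round(seq(0.01, 0.99, length.out = n_qtl) * length))
  loci <- lapply(pos, function(p) locus(1, p))
  trait <- quantitative_trait(
    "t", lapply(loci, function(l) qtl(l, effect = a)), h2 = h2)
  cfg <- simulation_config(
    chrom = chrom_config(length),
    demography = demography(1, 1, sizes = traj_constant(N)),
    maps = recomb_map_uniform(1, length),
    loci = loci, freq = 0.5, traits = trait,
    fitness = fitness_truncation("t", proportion, "high"))
  out <- lapply(seq_len(replicates), function(r) {
    res <- run_simulation(cfg, seed = seed + r - 1, record_values = TRUE)
    t0 <- res$values[[1]][[1]]$traits[[1]]
    w0 <- res$values[[1]][[1]]$fitness
    t1 <- res$values[[2]][[1]]$traits[[1]]
    S <- mean(t0[w0 > 0]) - mean(t0)
    R <- mean(t1) - mean(t0)
    tibble::tibble(replicate = r, S = S, R = R, ratio = R / (h2 * S))
  })
  dplyr::bind_rows(out)
}

#' @rdname experiment_drift
#' @param optimum_sd Displacement of the two optima from the founder
#'   trait mean, in units of the founder phenotypic standard deviation;
#'   population 1 is selected toward `+optimum_sd`, population 2 toward
#'   `-optimum_sd`.
#' @param width_sd Gaussian fitness width in the same units.
#' @return For `experiment_divergent_optima()`: a list with
#'   `divergence`, the across-replicate mean difference in trait means
#'   (population 1 minus population 2) per generation, and `trait_means`,
#'   the per-replicate tibble of population trait means.
#' @export
experiment_divergent_optima <- function(N = 500, n_qtl = 10, a = 0.5,
                                        h2 = 0.5, optimum_sd = 2,
                                        width_sd = 1, generations = 30,
                                        replicates = 5, seed = 1,
                                        length = 50e6) {
  pos <- as.integer(round(seq(0.05, 0.95, length.out = n_qtl) * length))
  loci <- lapply(pos, function(p) locus(1, p))
  trait <- quantitative_trait(
    "t", lapply(loci, function(l) qtl(l, effect = a)), h2 = h2)
  # founder phenotypic SD implied by the generator: Vg = 2 p q a^2 per
  # QTL at p = 0.5, doubled by the h2 = Vg/(Vg + Ve) calibration
  vg <- n_qtl * 2 * 0.25 * a^2
  sd_p <- sqrt(vg / h2)
  mean0 <- n_qtl * a # genotypic mean at p = 0.5 with values (0, a, 2a)
  cfg <- simulation_config(
    chrom = chrom_config(length),
    demography = demography(2, generations, sizes = traj_constant(N)),
    maps = recomb_map_uniform(1, length),
    loci = loci, freq = 0.5, traits = trait,
    fitness = fitness_optimum(
      "t", list(mean0 + optimum_sd * sd_p, mean0 - optimum_sd * sd_p),
      width = width_sd * sd_p))
  acc <- numeric(generations + 1)
  all_means <- list()
  for (r in seq_len(replicates)) {
    res <- run_simulation(cfg, seed = seed + r - 1)
    tm <- res$traits
    d <- tm$mean[tm$population == 1] - tm$mean[tm$population == 2]
    acc <- acc + d
    all_means[[r]] <- dplyr::mutate(tm, replicate = r)
  }
  list(divergence = acc / replicates,
       trait_means = dplyr::bind_rows(all_means))
}
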