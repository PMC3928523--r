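#' Assemble a simulation configuration
#'
#' Collects every module of a forward simulation: chromosome layout,
#' demography (sizes, migration, number of generations), per-pair
#' recombination maps, tracked loci with founder allele frequencies,
#' quantitative traits, the fitness function, mutation, and reporting.
#'
#' Locus positions, founder frequencies and QTL effect sizes may be given
#' as [dist_constant()]-family specs instead of numbers; they are then
#' drawn once at the start of [run_simulation()] (in locus order, then
#' frequency, then QTL order) so that a configuration plus a seed fully
#' determines the run.
#'
#' @param chrom A [chrom_config()].
#' @param demography A [demography()].
#' @param maps A single `recomb_map` (reused for every pair) or a list
#'   with one map per chromosome pair.
#' @param loci Tracked loci: list of [locus()] objects (positions may be
#'   `dist_spec`s) or a data frame with `chrom` and `pos` columns.
#' @param freq Founder allele-1 frequency specification passed to
#'   [assign_founder_alleles()].
#' @param traits A [quantitative_trait()] or list of them (named by their
#'   trait names).
#' @param fitness A `fitness_spec`; defaults to [fitness_identity()]
#'   (neutral reproduction).  At most one fitness function is active.
#' @param mutation A [mutation_spec()] or `NULL` for no mutation.
#' @param dump_generations Generations at which a full population chunk
#'   dump is written when an output directory is used.
#' @param seed Default random seed for [run_simulation()].
#' @param output Default output directory (`NULL`: in-memory results
#'   only).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(chrom, demography, maps, loci = list(),
                              freq = 0.5, traits = list(),
                              fitness = fitness_identity(),
                              mutation = NULL,
                              dump_generations = integer(0),
                              seed = 0L, output = NULL) {
  if (inherits(maps, "recomb_map"))
    maps <- rep(list(maps), chrom$pair_count)
  if (length(maps) != chrom$pair_count)
    stop("one recombination map per chromosome pair is required",
         call. = FALSE)
  for (k in seq_along(maps))
    if (maps[[k]]$length != chrom$lengths[k])
      stop("map length for pair ", k, " (", maps[[k]]$length,
           ") does not match the chromosome length (", chrom$lengths[k],
           ")", call. = FALSE)
  if (inherits(loci, "locus")) loci <- list(loci)
  if (inherits(traits, "quantitative_trait")) traits <- list(traits)
  if (length(traits)) {
    names(traits) <- vapply(traits, `[[`, "", "name")
  }
  cfg <- structure(
    list(chrom = chrom, demography = demography, maps = maps, loci = loci,
         freq = freq, traits = traits, fitness = fitness,
         mutation = mutation,
         dump_generations = as.integer(dump_generations),
         seed = as.integer(seed), output = output),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg$fitness, "fitness_spec"))
    stop("fitness must be a fitness_spec", call. = FALSE)
  concrete <- function(loc) !inherits(loc$pos, "dist_spec")
  for (loc in cfg$loci) {
    if (loc$chrom < 1L || loc$chrom > cfg$chrom$pair_count)
      stop("locus refers to chromosome pair ", loc$chrom,
           " but only ", cfg$chrom$pair_count, " exist", call. = FALSE)
    if (concrete(loc) && (loc$pos < 0L ||
                          loc$pos >= cfg$chrom$lengths[loc$chrom]))
      stop("locus position ", loc$pos, " outside chromosome ", loc$chrom,
           call. = FALSE)
  }
  fit <- cfg$fitness
  if (fit$kind == "single_locus") {
    found <- any(vapply(cfg$loci, function(l)
      identical(l$chrom, fit$locus$chrom) &&
        identical(l$pos, fit$locus$pos), TRUE))
    if (!found)
      stop("single-locus fitness refers to a locus that is not tracked",
           call. = FALSE)
  }
  if (fit$kind %in% c("truncation", "optimum") &&
      !fit$trait %in% names(cfg$traits))
    stop("fitness refers to undefined trait '", fit$trait, "'",
         call. = FALSE)
  for (tr in cfg$traits) for (q in tr$qtls) {
    loc <- q$locus
    found <- any(vapply(cfg$loci, function(l)
      identical(l$chrom, loc$chrom) && identical(l$pos, loc$pos), TRUE))
    if (!found && !inherits(loc$pos, "dist_spec"))
      stop("QTL of trait '", tr$name, "' refers to untracked locus (chrom ",
           loc$chrom, ", pos ", loc$pos, ")", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(" ", x$demography$population_count, "population(s),",
      x$demography$generation_count, "generation(s),",
      x$chrom$pair_count, "chromosome pair(s)\n")
  cat(" ", length(x$loci), "tracked locus/loci,",
      length(x$traits), "trait(s), fitness:", x$fitness$kind, "\n")
  invisible(x)
}

# draw any distribution-valued locus positions / frequencies / QTL
# effects (fixed order: locus positions, then frequencies, then QTL
# effects in trait order)
resolve_config_random <- function(cfg) {
  for (i in seq_along(cfg$loci)) {
    loc <- cfg$loci[[i]]
    if (inherits(loc$pos, "dist_spec")) {
      p <- round(draw_values(loc$pos, 1))
      p <- min(max(p, 0), cfg$chrom$lengths[loc$chrom] - 1)
      cfg$loci[[i]]$pos <- as.integer(p)
    }
  }
  if (inherits(cfg$freq, "dist_spec")) {
    cfg$freq <- pmin(pmax(draw_values(cfg$freq, length(cfg$loci)), 0), 1)
  } else if (is.list(cfg$freq)) {
    cfg$freq <- vapply(cfg$freq, function(f) {
      if (inherits(f, "dist_spec")) min(max(draw_values(f, 1), 0), 1)
      else as.numeric(f)
    }, 1)
  }
  for (tn in seq_along(cfg$traits)) {
    for (qi in seq_along(cfg$traits[[tn]]$qtls)) {
      q <- cfg$traits[[tn]]$qtls[[qi]]
      if (inherits(q$values, "dist_spec")) {
        a <- draw_values(q$values, 1)
        cfg$traits[[tn]]$qtls[[qi]]$values <- c(0, a, 2 * a)
      }
      if (inherits(q$locus$pos, "dist_spec")) {
        p <- round(draw_values(q$locus$pos, 1))
        p <- min(max(p, 0), cfg$chrom$lengths[q$locus$chrom] - 1)
        cfg$traits[[tn]]$qtls[[qi]]$locus$pos <- as.integer(p)
      }
    }
  }
  cfg
}

maps_for_cpp <- function(maps) {
  lapply(maps, function(m) list(bp = m$bp, cum = m$cum_morgans))
}

#' Run a forward simulation
#'
#' Executes the configured number of Wright-Fisher generations.  Each
#' cycle performs, in order: (i) generation of new populations
#' (fitness-weighted, migration-aware parent sampling and recombinant
#' gamete formation), (ii) genotyping at the tracked loci,
#' (iii) quantitative trait evaluation, (iv) fitness evaluation and
#' (v) reporting.  Fitness computed in generation g governs parent
#' sampling for generation g + 1.  All randomness flows from `seed`
#' through R's RNG in a fixed documented order, so an identical
#' (config, seed) pair yields byte-identical outputs.
#'
#' @param config A [simulation_config()].
#' @param seed Integer random seed (defaults to the config's).
#' @param outdir Output directory for tab-delimited reports and
#'   population dumps (`NULL`: in-memory results only).
#' @param stop_when Optional early-stopping predicate called after each
#'   generation's reporting with a list
#'   `(generation, freqs, pops)` where `freqs` is the populations x loci
#'   allele-1 frequency matrix; return `TRUE` to stop.
#' @param record_values Keep per-individual trait values and fitness?
#'   When `TRUE` the result gains `values`, a list indexed by
#'   `generation + 1` of per-population lists with elements `traits`
#'   (list of per-trait value vectors) and `fitness`.
#' @return A `sim_result` object with tibbles `freqs` (per generation,
#'   population and locus), `traits` (per-trait summaries) and `stats`
#'   (size, mean fitness, mean chunks per chromosome copy), the final
#'   `populations`, the final `allele_table`, the founder-origin map
#'   `origin`, and `Ve` per trait.
#' @export
run_simulation <- function(config, seed = config$seed,
                           outdir = config$output, stop_when = NULL,
                           record_values = FALSE) {
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cfg <- resolve_config_random(config)
  dem <- cfg$demography
  K <- dem$population_count
  G <- dem$generation_count
  lengths <- cfg$chrom$lengths
  loci_tab <- loci_table(cfg$loci)
  L <- nrow(loci_tab)
  cpp_maps <- maps_for_cpp(cfg$maps)

  sizes <- population_sizes(dem, 0)
  offsets <- 2L * cumsum(c(0L, sizes[-K]))
  pops <- lapply(seq_len(K), function(i)
    make_founder_population(sizes[i], offsets[i], cfg$chrom, pop_id = i))
  next_id <- 2L * sum(sizes)
  table <- assign_founder_alleles(loci_tab, seq_len(next_id) - 1L, cfg$freq)
  origin <- seq_len(next_id) - 1L

  # calibrate environmental variance once, from pooled founder genetic
  # values
  Ve <- lapply(cfg$traits, function(tr) {
    gv <- unlist(lapply(pops, function(p) genetic_values(p, tr, table)))
    calibrate_environmental_variance(tr, gv)
  })

  nt <- length(cfg$traits)
  rec_freq <- matrix(NA_real_, nrow = (G + 1L) * K, ncol = L)
  rec_stats <- matrix(NA_real_, nrow = (G + 1L) * K, ncol = 4L)
  colnames(rec_stats) <- c("size", "mean_fitness", "mean_chunks", "gen")
  rec_traits <- matrix(NA_real_, nrow = (G + 1L) * K * max(nt, 1L),
                       ncol = 4L)
  generations_run <- G
  rec_values <- if (record_values) vector("list", G + 1L)

  for (g in 0:G) {
    # (ii) genotyping
    geno <- lapply(pops, function(p) genotypes(p, loci_tab, table))
    # (iii) trait evaluation (environmental noise redrawn per generation,
    # populations in index order)
    tvals <- lapply(seq_len(K), function(i) {
      lapply(seq_along(cfg$traits), function(tn)
        trait_values(pops[[i]], cfg$traits[[tn]], table, Ve = Ve[[tn]]))
    })
    # (iv) fitness evaluation
    fit <- lapply(seq_len(K), function(i) {
      p <- pops[[i]]
      spec <- cfg$fitness
      gl <- NULL
      tv <- NULL
      if (spec$kind == "single_locus") {
        l <- which(loci_tab$chrom == spec$locus$chrom &
                     loci_tab$pos == spec$locus$pos)
        gl <- geno[[i]][, l]
      }
      if (spec$kind %in% c("truncation", "optimum"))
        tv <- tvals[[i]][[match(spec$trait, names(cfg$traits))]]
      compute_fitness(spec, p$size, genotype_at_locus = gl,
                      trait_value = tv, generation = g, population = i)
    })
    if (record_values)
      rec_values[[g + 1L]] <- lapply(seq_len(K), function(i)
        list(traits = tvals[[i]], fitness = fit[[i]]))
    # (v) reporting
    for (i in seq_len(K)) {
      row <- g * K + i
      if (L > 0L)
        rec_freq[row, ] <- if (pops[[i]]$size > 0L)
          colSums(geno[[i]]) / (2 * pops[[i]]$size) else NA_real_
      nch <- unlist(lapply(pops[[i]]$chrom, `[[`, "nch"))
      rec_stats[row, ] <- c(pops[[i]]$size,
                            if (pops[[i]]$size > 0L) mean(fit[[i]]) else
                              NA_real_,
                            if (length(nch)) mean(nch) else NA_real_, g)
      for (tn in seq_len(nt)) {
        tv <- tvals[[i]][[tn]]
        rec_traits[(g * K + i - 1L) * nt + tn, ] <-
          if (length(tv)) c(mean(tv), stats::var(tv), min(tv), max(tv)) else
            rep(NA_real_, 4L)
      }
    }
    if (!is.null(outdir) && g %in% cfg$dump_generations)
      for (i in seq_len(K))
        write_population(pops[[i]],
                         file.path(outdir,
                                   sprintf("population_p%d_gen%d.txt", i, g)))
    if (!is.null(stop_when)) {
      fr <- matrix(rec_freq[g * K + seq_len(K), ], nrow = K)
      if (isTRUE(stop_when(list(generation = g, freqs = fr, pops = pops)))) {
        generations_run <- g
        break
      }
    }
    if (g == G) break

    # (i) generation of new populations
    sizes_next <- population_sizes(dem, g + 1)
    mig <- migration_matrix(dem, g + 1)
    merged <- merge_population_chrom(pops)
    new_pops <- vector("list", K)
    for (i in seq_len(K)) {
      pp <- sample_parent_pairs(sizes, fit, mig[i, ], sizes_next[i],
                                generation = g + 1)
      parents <- matrix(merged$offsets[pp$population] + pp$index - 1L,
                        nrow = 2L)
      child_chrom <- cpp_make_children(merged$chrom, lengths, parents,
                                       cpp_maps)
      new_pops[[i]] <- new_population(i, g + 1L, sizes_next[i], lengths,
                                      child_chrom)
    }
    pops <- new_pops
    sizes <- sizes_next
    # mutation at tracked loci, populations in index order
    if (!is.null(cfg$mutation) && L > 0L) {
      for (i in seq_len(K)) {
        mres <- mutate_population(pops[[i]], loci_tab, cfg$mutation$mu,
                                  table, next_id, origin)
        pops[[i]] <- mres$pop
        table <- mres$table
        next_id <- mres$next_id
        origin <- mres$origin
      }
    }
  }

  used <- seq_len((generations_run + 1L) * K)
  freqs <- if (L > 0L) {
    tibble::tibble(
      generation = rep(0:generations_run, each = K * L),
      population = rep(rep(seq_len(K), each = L), generations_run + 1L),
      locus = rep(seq_len(L), K * (generations_run + 1L)),
      chrom = loci_tab$chrom[rep(seq_len(L), K * (generations_run + 1L))],
      pos = loci_tab$pos[rep(seq_len(L), K * (generations_run + 1L))],
      freq = as.vector(t(rec_freq[used, , drop = FALSE]))
    )
  } else {
    tibble::tibble(generation = integer(0), population = integer(0),
                   locus = integer(0), chrom = integer(0), pos = integer(0),
                   freq = numeric(0))
  }
  stats <- tibble::tibble(
    generation = rep(0:generations_run, each = K),
    population = rep(seq_len(K), generations_run + 1L),
    size = as.integer(rec_stats[used, 1L]),
    mean_fitness = rec_stats[used, 2L],
    mean_chunks = rec_stats[used, 3L]
  )
  traits <- if (nt > 0L) {
    used_t <- seq_len((generations_run + 1L) * K * nt)
    tibble::tibble(
      generation = rep(0:generations_run, each = K * nt),
      population = rep(rep(seq_len(K), each = nt), generations_run + 1L),
      trait = rep(names(cfg$traits), K * (generations_run + 1L)),
      mean = rec_traits[used_t, 1L],
      var = rec_traits[used_t, 2L],
      min = rec_traits[used_t, 3L],
      max = rec_traits[used_t, 4L]
    )
  } else {
    tibble::tibble(generation = integer(0), population = integer(0),
                   trait = character(0), mean = numeric(0),
                   var = numeric(0), min = numeric(0), max = numeric(0))
  }

  res <- structure(
    list(seed = as.integer(seed), config = cfg, freqs = freqs,
         traits = traits, stats = stats, populations = pops,
         allele_table = table, origin = origin, next_id = next_id,
         Ve = Ve, generations_run = generations_run,
         values = if (record_values) rec_values),
    class = "sim_result")
  if (!is.null(outdir)) write_reports(res, outdir)
  res
}

write_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_tsv_plain(res$freqs, file.path(outdir, "allele_frequencies.tsv"))
  write_tsv_plain(res$traits, file.path(outdir, "trait_stats.tsv"))
  write_tsv_plain(res$stats, file.path(outdir, "population_stats.tsv"))
  invisible(outdir)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> seed", x$seed, "—", x$generations_run,
      "generation(s) run,",
      x$config$demography$population_count, "population(s)\n")
  fin <- x$stats[x$stats$generation == x$generations_run, ]
  cat("final sizes:", paste(fin$size, collapse = ", "), "\n")
  if (nrow(x$freqs)) {
    ff <- x$freqs[x$freqs$generation == x$generations_run, ]
    cat("final allele-1 frequencies:",
        paste(format(ff$freq, digits = 3), collapse = ", "), "\n")
  }
  invisible(x)
}
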