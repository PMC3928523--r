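#' Parse a plain-text simulation configuration
#'
#' Configurations are module-based text files.  Each block names a module
#' type and an instance name, followed by indented `key = value` lines
#' and terminated by a blank line; later blocks refer to earlier ones by
#' instance name.  A final `Simulator` block lists the seed, the active
#' module instances and the output directory.  Lines starting with `#`
#' are comments.
#'
#' \preformatted{
#' Chromosomes chroms
#'     lengths = 1000000
#'
#' Trajectory_Constant popsize
#'     value = 100
#'
#' Demography demo
#'     populations = 1
#'     generations = 50
#'     size = popsize
#'     migration = none
#'
#' RecombinationMap_Uniform map
#'     rate = 1
#'
#' Locus locusA
#'     chromosome = 1
#'     position = 500000
#'     frequency = 0.5
#'
#' Simulator sim
#'     seed = 42
#'     chromosomes = chroms
#'     demography = demo
#'     maps = map
#'     loci = locusA
#' }
#'
#' Available block types: `Trajectory_Constant` (value),
#' `Trajectory_Linear` (t0, v0, slope), `Trajectory_Exponential`
#' (t0, v0, rate), `Trajectory_Step` (steps = `g:v g:v ...`),
#' `Distribution_Constant` (value), `Distribution_Uniform` (low, high),
#' `Distribution_Normal` (mean, sd), `Chromosomes` (lengths),
#' `RecombinationMap_Uniform` (rate in cM/Mb),
#' `RecombinationMap_File` (file, a HapMap-style map), `Locus`
#' (chromosome, position, frequency — position and frequency may name a
#' Distribution), `QTL` (locus, effect or values = `w0 w1 w2`; effect
#' may name a Distribution), `Trait` (qtls, heritability or ve),
#' `FitnessFunction_Identity`, `FitnessFunction_SingleLocus`
#' (locus, s, h), `FitnessFunction_Truncation`
#' (trait, proportion, direction), `FitnessFunction_Optimum`
#' (trait, optimum — a number or Trajectory —, width), `Mutation` (mu),
#' `Demography` (populations, generations, size or size_1 ... — numbers
#' or Trajectories —, migration = none/island/stepping_stone/custom,
#' migration_rate, migration_i_j), `Reporter_Population` (generations),
#' and `Simulator` (seed, chromosomes, demography, maps, loci, traits,
#' fitness, mutation, population_dumps, output).
#'
#' @param path Path to a configuration file.
#' @param text Alternative to `path`: the configuration as a single
#'   string or character vector of lines.
#' @return A [simulation_config()] (with the raw blocks attached as
#'   attribute `"blocks"`, used by [write_config()]).
#' @export
parse_config <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  blocks <- scan_blocks(lines)
  build_config(blocks)
}

# split config lines into blocks: list(type, name, keys = named list of
# character values, line = header line number)
scan_blocks <- function(lines) {
  blocks <- list()
  cur <- NULL
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    line <- sub("#.*$", "", raw)
    if (!nzchar(trimws(line))) {
      if (!is.null(cur)) {
        blocks[[length(blocks) + 1L]] <- cur
        cur <- NULL
      }
      next
    }
    indented <- grepl("^\\s", line)
    if (!indented) {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      toks <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(toks) != 2L)
        stop("line ", ln, ": expected '<BlockType> <instance_name>', got: ",
             trimws(raw), call. = FALSE)
      cur <- list(type = toks[1L], name = toks[2L], keys = list(),
                  line = ln)
    } else {
      if (is.null(cur))
        stop("line ", ln, ": indented line outside any block", call. = FALSE)
      m <- regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", line)
      parts <- regmatches(line, m)[[1L]]
      if (length(parts) != 3L)
        stop("line ", ln, ": expected 'key = value', got: ", trimws(raw),
             call. = FALSE)
      cur$keys[[parts[2L]]] <- parts[3L]
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  nm <- vapply(blocks, `[[`, "", "name")
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate instance name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  blocks
}

known_keys <- list(
  Trajectory_Constant = "value",
  Trajectory_Linear = c("t0", "v0", "slope"),
  Trajectory_Exponential = c("t0", "v0", "rate"),
  Trajectory_Step = "steps",
  Distribution_Constant = "value",
  Distribution_Uniform = c("low", "high"),
  Distribution_Normal = c("mean", "sd"),
  Chromosomes = "lengths",
  RecombinationMap_Uniform = "rate",
  RecombinationMap_File = "file",
  Locus = c("chromosome", "position", "frequency"),
  QTL = c("locus", "effect", "values"),
  Trait = c("qtls", "heritability", "ve"),
  FitnessFunction_Identity = character(0),
  FitnessFunction_SingleLocus = c("locus", "s", "h"),
  FitnessFunction_Truncation = c("trait", "proportion", "direction"),
  FitnessFunction_Optimum = c("trait", "optimum", "width"),
  Mutation = "mu",
  Reporter_Population = "generations",
  Demography = c("populations", "generations", "size", "migration",
                 "migration_rate"),
  Simulator = c("seed", "chromosomes", "demography", "maps", "loci",
                "traits", "fitness", "mutation", "population_dumps",
                "output")
)

check_keys <- function(b) {
  allowed <- known_keys[[b$type]]
  if (is.null(allowed))
    stop("block '", b$name, "' (line ", b$line, "): unknown block type ",
         b$type, call. = FALSE)
  extra <- setdiff(names(b$keys), allowed)
  # Demography allows size_<i> and migration_<i>_<j>; tolerate those
  if (b$type == "Demography")
    extra <- extra[!grepl("^size_\\d+$", extra) &
                     !grepl("^migration_\\d+_\\d+$", extra)]
  if (length(extra))
    stop("block '", b$name, "': unknown key(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
}

build_config <- function(blocks) {
  for (b in blocks) check_keys(b)
  by_name <- stats::setNames(blocks, vapply(blocks, `[[`, "", "name"))
  sims <- Filter(function(b) b$type == "Simulator", blocks)
  if (length(sims) != 1L)
    stop("configuration must contain exactly one Simulator block",
         call. = FALSE)
  sim <- sims[[1L]]
  dems <- Filter(function(b) b$type == "Demography", blocks)
  if (length(dems) != 1L)
    stop("configuration must contain exactly one Demography block",
         call. = FALSE)

  ref <- function(name, context, types = NULL) {
    b <- by_name[[name]]
    if (is.null(b))
      stop(context, " refers to undefined instance '", name, "'",
           call. = FALSE)
    if (!is.null(types) && !b$type %in% types)
      stop(context, ": '", name, "' is a ", b$type, ", expected one of ",
           paste(types, collapse = "/"), call. = FALSE)
    b
  }
  num <- function(b, key, default = NULL) {
    v <- b$keys[[key]]
    if (is.null(v)) {
      if (is.null(default))
        stop("block '", b$name, "' is missing key '", key, "'",
             call. = FALSE)
      return(default)
    }
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x))
      stop("block '", b$name, "', key '", key, "': not a number: ", v,
           call. = FALSE)
    x
  }
  nums <- function(b, key) {
    v <- b$keys[[key]]
    if (is.null(v))
      stop("block '", b$name, "' is missing key '", key, "'", call. = FALSE)
    x <- suppressWarnings(as.numeric(strsplit(v, "\\s+")[[1L]]))
    if (anyNA(x))
      stop("block '", b$name, "', key '", key, "': not numbers: ", v,
           call. = FALSE)
    x
  }
  names_of <- function(b, key) {
    v <- b$keys[[key]]
    if (is.null(v)) return(character(0))
    strsplit(v, "\\s+")[[1L]]
  }
  # a value that is either a literal number or a reference to a
  # Distribution / Trajectory block
  num_or <- function(b, key, builder, types, default = NULL) {
    v <- b$keys[[key]]
    if (is.null(v)) {
      if (is.null(default)) stop("block '", b$name, "' is missing key '",
                                 key, "'", call. = FALSE)
      return(default)
    }
    x <- suppressWarnings(as.numeric(v))
    if (!is.na(x)) return(x)
    builder(ref(v, paste0("block '", b$name, "', key '", key, "'"), types))
  }

  build_trajectory <- function(b) {
    switch(b$type,
      Trajectory_Constant = traj_constant(num(b, "value")),
      Trajectory_Linear = traj_linear(num(b, "t0"), num(b, "v0"),
                                      num(b, "slope")),
      Trajectory_Exponential = traj_exponential(num(b, "t0"), num(b, "v0"),
                                                num(b, "rate")),
      Trajectory_Step = {
        steps <- strsplit(names_of(b, "steps"), ":", fixed = TRUE)
        traj_step(vapply(steps, function(s) as.numeric(s[1L]), 1),
                  vapply(steps, function(s) as.numeric(s[2L]), 1))
      })
  }
  traj_types <- paste0("Trajectory_",
                       c("Constant", "Linear", "Exponential", "Step"))
  build_dist <- function(b) {
    switch(b$type,
      Distribution_Constant = dist_constant(num(b, "value")),
      Distribution_Uniform = dist_uniform(num(b, "low"), num(b, "high")),
      Distribution_Normal = dist_normal(num(b, "mean"), num(b, "sd")))
  }
  dist_types <- paste0("Distribution_", c("Constant", "Uniform", "Normal"))

  chrom_b <- ref(sim$keys$chromosomes %||% stop2(sim, "chromosomes"),
                 "Simulator", "Chromosomes")
  chrom <- chrom_config(nums(chrom_b, "lengths"))

  dem_b <- dems[[1L]]
  Kd <- as.integer(num(dem_b, "populations"))
  gen <- as.integer(num(dem_b, "generations"))
  size_of <- function(key) {
    v <- dem_b$keys[[key]]
    x <- suppressWarnings(as.numeric(v))
    if (!is.na(x)) traj_constant(x) else
      build_trajectory(ref(v, paste0("Demography key '", key, "'"),
                           traj_types))
  }
  sizes <- if (!is.null(dem_b$keys$size)) size_of("size") else {
    keys <- paste0("size_", seq_len(Kd))
    missing <- keys[!keys %in% names(dem_b$keys)]
    if (length(missing))
      stop("Demography block '", dem_b$name, "' is missing ",
           paste(missing, collapse = ", "), call. = FALSE)
    lapply(keys, size_of)
  }
  mig_kind <- dem_b$keys$migration %||% "none"
  mig_rate <- NULL
  mig_rates <- NULL
  if (mig_kind %in% c("island", "stepping_stone"))
    mig_rate <- num_or(dem_b, "migration_rate", build_trajectory,
                       traj_types)
  if (mig_kind == "custom") {
    keys <- grep("^migration_\\d+_\\d+$", names(dem_b$keys), value = TRUE)
    mig_rates <- lapply(keys, function(k)
      num_or(dem_b, k, build_trajectory, traj_types))
    names(mig_rates) <- sub("^migration_", "", keys)
  }
  dem <- demography(Kd, gen, sizes, migration = mig_kind,
                    migration_rate = mig_rate, migration_rates = mig_rates)

  map_names <- names_of(sim, "maps")
  if (!length(map_names))
    stop("Simulator block is missing key 'maps'", call. = FALSE)
  if (length(map_names) == 1L && chrom$pair_count > 1L)
    map_names <- rep(map_names, chrom$pair_count)
  if (length(map_names) != chrom$pair_count)
    stop("Simulator 'maps' must list one map (reused) or one per ",
         "chromosome pair", call. = FALSE)
  maps <- lapply(seq_along(map_names), function(k) {
    b <- ref(map_names[k], "Simulator key 'maps'",
             c("RecombinationMap_Uniform", "RecombinationMap_File"))
    if (b$type == "RecombinationMap_Uniform")
      recomb_map_uniform(num(b, "rate"), chrom$lengths[k])
    else
      read_genetic_map(b$keys$file, length = chrom$lengths[k])
  })

  locus_names <- names_of(sim, "loci")
  loci <- list()
  freqs <- list()
  for (nm in locus_names) {
    b <- ref(nm, "Simulator key 'loci'", "Locus")
    pos <- {
      v <- b$keys$position %||%
        stop("Locus '", nm, "' is missing key 'position'", call. = FALSE)
      x <- suppressWarnings(as.numeric(v))
      if (!is.na(x)) as.integer(x) else
        build_dist(ref(v, paste0("Locus '", nm, "', key 'position'"),
                       dist_types))
    }
    loci[[nm]] <- structure(list(chrom = as.integer(num(b, "chromosome")),
                                 pos = pos), class = "locus")
    freqs[[nm]] <- num_or(b, "frequency", build_dist, dist_types,
                          default = 0.5)
  }

  build_qtl <- function(nm, trait_nm) {
    b <- ref(nm, paste0("Trait '", trait_nm, "' key 'qtls'"), "QTL")
    loc_nm <- b$keys$locus %||%
      stop("QTL '", nm, "' is missing key 'locus'", call. = FALSE)
    if (is.null(loci[[loc_nm]]))
      stop("QTL '", nm, "' refers to locus '", loc_nm,
           "' which is not listed in the Simulator 'loci'", call. = FALSE)
    if (!is.null(b$keys$values))
      return(qtl(loci[[loc_nm]], values = nums(b, "values")))
    eff <- num_or(b, "effect", build_dist, dist_types)
    if (inherits(eff, "dist_spec"))
      structure(list(locus = loci[[loc_nm]], values = eff), class = "qtl")
    else qtl(loci[[loc_nm]], effect = eff)
  }
  trait_names <- names_of(sim, "traits")
  traits <- lapply(trait_names, function(nm) {
    b <- ref(nm, "Simulator key 'traits'", "Trait")
    qtls <- lapply(names_of(b, "qtls"), build_qtl, trait_nm = nm)
    h2 <- if (!is.null(b$keys$heritability)) num(b, "heritability")
    ve <- if (!is.null(b$keys$ve)) num(b, "ve")
    quantitative_trait(nm, qtls, h2 = h2, Ve = ve)
  })

  fitness <- fitness_identity()
  if (!is.null(sim$keys$fitness)) {
    b <- ref(sim$keys$fitness, "Simulator key 'fitness'",
             paste0("FitnessFunction_",
                    c("Identity", "SingleLocus", "Truncation", "Optimum")))
    fitness <- switch(b$type,
      FitnessFunction_Identity = fitness_identity(),
      FitnessFunction_SingleLocus = {
        loc_nm <- b$keys$locus %||%
          stop("block '", b$name, "' is missing key 'locus'", call. = FALSE)
        if (is.null(loci[[loc_nm]]))
          stop("fitness function '", b$name, "' refers to locus '", loc_nm,
               "' which is not listed in the Simulator 'loci'",
               call. = FALSE)
        fitness_single_locus(loci[[loc_nm]], num(b, "s"),
                             num(b, "h", default = 0.5))
      },
      FitnessFunction_Truncation = fitness_truncation(
        check_trait_ref(b, trait_names), num(b, "proportion"),
        b$keys$direction %||% "high"),
      FitnessFunction_Optimum = fitness_optimum(
        check_trait_ref(b, trait_names),
        num_or(b, "optimum", build_trajectory, traj_types),
        num(b, "width")))
  }

  mutation <- NULL
  if (!is.null(sim$keys$mutation)) {
    b <- ref(sim$keys$mutation, "Simulator key 'mutation'", "Mutation")
    mutation <- mutation_spec(nums(b, "mu"))
  }

  dumps <- integer(0)
  if (!is.null(sim$keys$population_dumps)) {
    b <- ref(sim$keys$population_dumps, "Simulator key 'population_dumps'",
             "Reporter_Population")
    dumps <- as.integer(nums(b, "generations"))
  }

  cfg <- simulation_config(
    chrom = chrom, demography = dem, maps = maps, loci = loci,
    freq = freqs, traits = traits, fitness = fitness, mutation = mutation,
    dump_generations = dumps,
    seed = as.integer(num(sim, "seed", default = 0)),
    output = sim$keys$output)
  attr(cfg, "blocks") <- blocks
  cfg
}

check_trait_ref <- function(b, trait_names) {
  nm <- b$keys$trait
  if (is.null(nm))
    stop("block '", b$name, "' is missing key 'trait'", call. = FALSE)
  if (!nm %in% trait_names)
    stop("fitness function '", b$name, "' refers to undefined trait '",
         nm, "'", call. = FALSE)
  nm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(b, key) {
  stop("block '", b$name, "' is missing key '", key, "'", call. = FALSE)
}

#' Write a configuration back to text
#'
#' Regenerates the block text of a configuration parsed with
#' [parse_config()]; `parse_config(write_config(cfg))` yields an
#' equivalent configuration (round trip).
#'
#' @param config A `sim_config` produced by [parse_config()].
#' @param path Optional output file.
#' @return The configuration text as a character vector of lines
#'   (invisibly when `path` is given).
#' @export
write_config <- function(config, path = NULL) {
  blocks <- attr(config, "blocks")
  if (is.null(blocks))
    stop("write_config() needs a configuration parsed by parse_config()",
         call. = FALSE)
  lines <- unlist(lapply(blocks, function(b) {
    c(paste(b$type, b$name),
      vapply(names(b$keys), function(k)
        paste0("    ", k, " = ", b$keys[[k]]), ""),
      "")
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
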