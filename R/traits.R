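#' Tracked loci
#'
#' Only loci with fitness effects (or loci the user explicitly wants
#' genotyped) need to be tracked: because every chromosome is a mosaic of
#' founder haplotypes, the allele carried at a locus is fully determined
#' by the founder id there plus the founder allele table.
#'
#' @param chrom 1-based chromosome-pair index.
#' @param pos 0-based position in bp.
#' @return An object of class `locus`.
#' @export
locus <- function(chrom, pos) {
  structure(list(chrom = as.integer(chrom), pos = as.integer(pos)),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus> chrom", x$chrom, "pos", x$pos, "\n")
  invisible(x)
}

# loci as a tibble (chrom, pos); accepts a locus, a list of loci, or a
# data frame with chrom/pos columns
loci_table <- function(loci) {
  if (inherits(loci, "locus")) loci <- list(loci)
  if (is.data.frame(loci)) {
    tab <- tibble::as_tibble(loci[c("chrom", "pos")])
  } else {
    tab <- tibble::tibble(
      chrom = vapply(loci, `[[`, 1L, "chrom"),
      pos = vapply(loci, `[[`, 1L, "pos")
    )
  }
  tab$chrom <- as.integer(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Assign founder alleles at tracked loci
#'
#' Each tracked locus l is given an allele-1 frequency p_l (a fixed
#' number, one per locus, or drawn from a distribution spec); each founder
#' haplotype then carries allele 1 at l independently with probability
#' p_l.
#'
#' @param loci Tracked loci: a list of [locus()] objects or a data frame
#'   with columns `chrom` and `pos`.
#' @param ids Integer vector of founder ids to populate.
#' @param freq Either a single frequency, a numeric vector with one
#'   frequency per locus, or a [dist_constant()]-family spec from which
#'   one frequency per locus is drawn.
#' @return An `allele_table`: a 0/1 integer matrix with one row per
#'   founder id (row `id + 1`) and one column per locus, with the locus
#'   table attached as attribute `loci`.
#' @export
assign_founder_alleles <- function(loci, ids, freq) {
  tab <- loci_table(loci)
  nl <- nrow(tab)
  if (inherits(freq, "dist_spec")) freq <- draw_values(freq, nl)
  if (length(freq) == 1L) freq <- rep(freq, nl)
  if (length(freq) != nl)
    stop("need one founder allele frequency per locus (", nl, " loci, ",
         length(freq), " frequencies)", call. = FALSE)
  if (any(freq < 0 | freq > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  ids <- as.integer(ids)
  nid <- if (length(ids)) max(ids) + 1L else 0L
  alleles <- matrix(NA_integer_, nrow = nid, ncol = nl)
  for (l in seq_len(nl))
    alleles[ids + 1L, l] <- as.integer(stats::runif(length(ids)) < freq[l])
  new_allele_table(alleles, tab)
}

new_allele_table <- function(alleles, loci) {
  structure(alleles, loci = loci, class = c("allele_table", class(alleles)))
}

#' Build an allele table by hand
#'
#' Mostly useful for tests and small worked examples;
#' [assign_founder_alleles()] is the usual constructor.
#'
#' @param alleles 0/1 integer matrix with one row per founder id (row
#'   `id + 1`; rows may be `NA` for unused ids) and one column per locus.
#' @param loci The tracked loci, as in [assign_founder_alleles()].
#' @return An `allele_table`.
#' @export
allele_table <- function(alleles, loci) {
  tab <- loci_table(loci)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != nrow(tab))
    stop("one allele column per locus is required", call. = FALSE)
  if (!all(alleles %in% c(0L, 1L, NA_integer_)))
    stop("alleles must be 0 or 1", call. = FALSE)
  new_allele_table(alleles, tab)
}

#' @export
print.allele_table <- function(x, ...) {
  cat("<allele_table>", nrow(x), "founder ids x",
      ncol(x), "tracked loci\n")
  invisible(x)
}

#' Genotypes of every individual at the tracked loci
#'
#' The genotype at a locus is the number of copies of allele 1 (0, 1 or
#' 2), obtained by looking up the founder id of each chromosome copy at
#' the locus position in the allele table.
#'
#' @param pop A `sim_population`.
#' @param loci Tracked loci (as in [assign_founder_alleles()]); must match
#'   the columns of `table`.
#' @param table An `allele_table` covering every founder id in `pop`.
#' @return Integer matrix, individuals x loci.
#' @export
genotypes <- function(pop, loci, table) {
  tab <- loci_table(loci)
  out <- matrix(0L, nrow = pop$size, ncol = nrow(tab))
  if (pop$size == 0L || nrow(tab) == 0L) return(out)
  for (k in sort(unique(tab$chrom))) {
    cols <- which(tab$chrom == k)
    cd <- pop$chrom[[k]]
    fid <- cpp_founder_ids_at(cd$pos, cd$id, cd$nch, tab$pos[cols])
    if (max(fid) + 1L > nrow(table))
      stop("allele table has no entry for founder id ", max(fid),
           call. = FALSE)
    for (ci in seq_along(cols)) {
      al <- table[fid[, ci] + 1L, cols[ci]]
      if (anyNA(al))
        stop("allele table entry missing for founder id ",
             fid[which(is.na(al))[1L], ci], " at locus (chrom ", k,
             ", pos ", tab$pos[cols[ci]], ")", call. = FALSE)
      odd <- seq(1L, length(al), by = 2L)
      out[, cols[ci]] <- al[odd] + al[odd + 1L]
    }
  }
  out
}

#' Genotype of a single individual at one locus
#'
#' @param ind An `individual` (see [get_individual()]).
#' @param loc A [locus()].
#' @param table An `allele_table`.
#' @return 0, 1 or 2 copies of allele 1.
#' @export
genotype <- function(ind, loc, table) {
  tab <- attr(table, "loci")
  l <- which(tab$chrom == loc$chrom & tab$pos == loc$pos)
  if (length(l) != 1L)
    stop("locus (chrom ", loc$chrom, ", pos ", loc$pos,
         ") is not tracked in the allele table", call. = FALSE)
  pair <- ind[[loc$chrom]]
  ids <- c(founder_id_at(pair[[1L]], loc$pos),
           founder_id_at(pair[[2L]], loc$pos))
  al <- table[ids + 1L, l]
  if (anyNA(al))
    stop("allele table entry missing for founder id ", ids[is.na(al)][1L],
         " at locus (chrom ", loc$chrom, ", pos ", loc$pos, ")",
         call. = FALSE)
  sum(al)
}

#' Quantitative trait loci and traits
#'
#' A QTL attaches genotypic values (w0, w1, w2) to a tracked locus: the
#' trait contributions of carrying 0, 1 or 2 copies of allele 1.  The
#' additive shortcut `effect = a` expands to (0, a, 2a).
#'
#' @param loc A [locus()].
#' @param effect Additive effect size a; genotypic values become
#'   (0, a, 2a).
#' @param values Explicit genotypic values (w0, w1, w2), overriding
#'   `effect` (allows dominance).
#' @return An object of class `qtl`.
#' @export
qtl <- function(loc, effect = NULL, values = NULL) {
  if (is.null(values)) {
    if (is.null(effect)) stop("give either effect or values", call. = FALSE)
    values <- c(0, effect, 2 * effect)
  }
  values <- as.numeric(values)
  if (length(values) != 3L || any(!is.finite(values)))
    stop("genotypic values must be three finite numbers", call. = FALSE)
  structure(list(locus = loc, values = values), class = "qtl")
}

#' @rdname qtl
#'
#' @param name Trait name.
#' @param qtls List of [qtl()] objects.  The trait value of an individual
#'   is the sum of QTL genotypic values (no epistasis) plus Gaussian
#'   environmental noise, redrawn each generation.
#' @param h2 Target narrow-sense heritability in (0, 1]; the environmental
#'   variance is calibrated once from the genetic variance of the founder
#'   generation (see [calibrate_environmental_variance()]) and held fixed.
#' @param Ve Explicit environmental variance (`>= 0`).  Give exactly one
#'   of `h2` and `Ve`.
#' @return `quantitative_trait()` returns an object of class
#'   `quantitative_trait`.
#' @export
quantitative_trait <- function(name, qtls, h2 = NULL, Ve = NULL) {
  if (is.null(h2) == is.null(Ve))
    stop("give exactly one of h2 and Ve", call. = FALSE)
  if (!is.null(h2) && (h2 <= 0 || h2 > 1))
    stop("h2 must lie in (0, 1]", call. = FALSE)
  if (!is.null(Ve) && Ve < 0) stop("Ve must be >= 0", call. = FALSE)
  if (inherits(qtls, "qtl")) qtls <- list(qtls)
  structure(list(name = name, qtls = qtls, h2 = h2, Ve = Ve),
            class = "quantitative_trait")
}

# genotype matrix restricted to a trait's QTL loci
trait_genotypes <- function(pop, trait, table) {
  loci <- lapply(trait$qtls, `[[`, "locus")
  genotypes(pop, loci, table)
}

#' Genetic values of every individual for a trait
#'
#' The genetic value is the sum over QTLs of the genotypic value matching
#' the individual's genotype, with no environmental noise.
#'
#' @inheritParams genotypes
#' @param trait A [quantitative_trait()].
#' @return Numeric vector, one value per individual.
#' @export
genetic_values <- function(pop, trait, table) {
  geno <- trait_genotypes(pop, trait, table)
  vals <- vapply(trait$qtls, `[[`, numeric(3), "values") # 3 x nqtl
  if (pop$size == 0L) return(numeric(0))
  g <- numeric(pop$size)
  for (q in seq_along(trait$qtls)) g <- g + vals[geno[, q] + 1L, q]
  g
}

#' Calibrate environmental variance from a target heritability
#'
#' With narrow-sense heritability defined as h2 = Vg / (Vg + Ve), the
#' environmental variance reproducing a target h2 given the genetic
#' variance Vg of the founder generation is Ve = Vg (1 - h2) / h2.  The
#' calibration is performed once at generation 0 and Ve is held fixed
#' thereafter, so the realized heritability drifts as Vg changes.
#'
#' @param trait A [quantitative_trait()] with `h2` set (if `Ve` is set it
#'   is returned unchanged).
#' @param founder_genetic_values Genetic values of the founder generation
#'   (see [genetic_values()]).
#' @return The environmental variance Ve.
#' @export
calibrate_environmental_variance <- function(trait, founder_genetic_values) {
  if (!is.null(trait$Ve)) return(trait$Ve)
  vg <- stats::var(founder_genetic_values)
  if (!is.finite(vg) || vg == 0) {
    if (trait$h2 == 1) return(0)
    stop("no genetic variance among founders; heritability ", trait$h2,
         " is unattainable", call. = FALSE)
  }
  vg * (1 - trait$h2) / trait$h2
}

#' Trait values of every individual
#'
#' T = sum of QTL genotypic values + environmental noise
#' `epsilon ~ Normal(0, Ve)`, drawn independently per individual.
#'
#' @inheritParams genetic_values
#' @param Ve Environmental variance.  If `NULL`, taken from `trait$Ve`
#'   (which must then be set; heritability-specified traits must be
#'   calibrated first).
#' @return Numeric vector of trait values.
#' @export
trait_values <- function(pop, trait, table, Ve = NULL) {
  if (is.null(Ve)) Ve <- trait$Ve
  if (is.null(Ve))
    stop("environmental variance not resolved; call ",
         "calibrate_environmental_variance() first", call. = FALSE)
  g <- genetic_values(pop, trait, table)
  g + stats::rnorm(length(g), 0, sqrt(Ve))
}
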