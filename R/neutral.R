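#' Read ms-style coalescent output as founder variant data
#'
#' A forward simulation only tracks loci with fitness effects; neutral
#' variation can be added afterwards by simulating founder sequences with
#' a coalescent simulator and painting them onto the haplotype-chunk
#' mosaics of any later generation.  This reader accepts the classic
#' ms output for one replicate: a `segsites:` line, a `positions:` line
#' with site positions as fractions of the chromosome length, and one 0/1
#' row per founder haplotype.  Rows are assigned to founder ids in order
#' of allocation (row r belongs to founder id `r - 1 + id_offset`).
#'
#' @param path Path to an ms-style output file (or a character vector of
#'   its lines via `text`).
#' @param length Chromosome length in bp used to convert fractional
#'   positions (rounded to nearest bp; collisions after rounding are
#'   dropped, keeping the first site).
#' @param text Alternative to `path`: the file content as lines.
#' @param id_offset Founder id of the first haplotype row.
#' @return A `founder_variants` object: list with `positions` (integer
#'   bp), `haplotypes` (0/1 integer matrix, one row per founder
#'   haplotype), `length`, and `id_offset`.
#' @export
read_ms <- function(path = NULL, length, text = NULL, id_offset = 0L) {
  lines <- if (is.null(text)) readLines(path) else text
  seg_i <- grep("^segsites:", lines)
  if (!length(seg_i)) stop("no 'segsites:' line found", call. = FALSE)
  seg_i <- seg_i[1L]
  segsites <- as.integer(sub("^segsites:\\s*", "", lines[seg_i]))
  pos_i <- grep("^positions:", lines)
  pos_i <- pos_i[pos_i > seg_i][1L]
  if (is.na(pos_i)) stop("no 'positions:' line found", call. = FALSE)
  fracs <- as.numeric(strsplit(trimws(sub("^positions:", "", lines[pos_i])),
                               "\\s+")[[1L]])
  if (length(fracs) != segsites)
    stop("positions line lists ", length(fracs), " sites, expected ",
         segsites, call. = FALSE)
  rows <- lines[-seq_len(pos_i)]
  rows <- rows[grepl("^[01]+$", rows)]
  if (!length(rows)) stop("no haplotype rows found", call. = FALSE)
  if (any(nchar(rows) != segsites))
    stop("haplotype rows differ in length from segsites", call. = FALSE)
  hap <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  bp <- as.integer(round(fracs * length))
  bp <- pmin(pmax(bp, 0L), as.integer(length) - 1L)
  keep <- !duplicated(bp)
  structure(list(positions = bp[keep],
                 haplotypes = hap[, keep, drop = FALSE],
                 length = as.integer(length),
                 id_offset = as.integer(id_offset)),
            class = "founder_variants")
}

#' @export
print.founder_variants <- function(x, ...) {
  cat("<founder_variants>", nrow(x$haplotypes), "founder haplotypes x",
      length(x$positions), "sites on", x$length, "bp\n")
  invisible(x)
}

#' Propagate neutral founder variation onto a simulated population
#'
#' For every chromosome copy in the population and every segregating
#' site, the output allele is the founder haplotype's allele at that
#' site, looked up through the copy's mosaic structure:
#' `founders[founder_id_at(copy, site_pos), site]`.  At generation 0 this
#' is the identity; after t generations each output row is a mosaic of
#' founder rows following the chunk structure.
#'
#' @param pop A `sim_population`.
#' @param founders A `founder_variants` object (see [read_ms()]) for one
#'   chromosome pair, covering every founding haplotype.
#' @param pair Which chromosome pair the founder data describes.
#' @param origin Optional integer vector mapping founder ids to founding
#'   ids (`origin[id + 1]`), as produced by [run_simulation()]; derived
#'   ids created by mutation inherit the row of their source haplotype.
#'   By default ids are used as-is.
#' @return 0/1 integer matrix with one row per chromosome copy (copy
#'   `2 * (i - 1) + c` of individual i in row order) and one column per
#'   segregating site.
#' @export
propagate_neutral_variation <- function(pop, founders, pair = 1L,
                                        origin = NULL) {
  cd <- pop$chrom[[pair]]
  if (pop$lengths[pair] != founders$length)
    stop("founder variant data length does not match the chromosome",
         call. = FALSE)
  if (2L * pop$size == 0L || !length(founders$positions))
    return(matrix(0L, nrow = 2L * pop$size,
                  ncol = length(founders$positions)))
  fid <- cpp_founder_ids_at(cd$pos, cd$id, cd$nch, founders$positions)
  if (!is.null(origin)) {
    if (max(fid) + 1L > length(origin))
      stop("origin map has no entry for founder id ", max(fid),
           call. = FALSE)
    fid[] <- origin[fid + 1L]
  }
  row_of <- fid - founders$id_offset + 1L
  if (min(row_of) < 1L || max(row_of) > nrow(founders$haplotypes))
    stop("founder variant data has no row for founder id ",
         fid[which(row_of < 1L | row_of > nrow(founders$haplotypes))[1L]],
         call. = FALSE)
  out <- matrix(founders$haplotypes[cbind(as.vector(row_of),
                                          rep(seq_along(founders$positions),
                                              each = nrow(fid)))],
                nrow = nrow(fid))
  out
}

#' Write decorated haplotypes as a minimal phased VCF
#'
#' Writes a VCF 4.2 file containing only phased GT fields, one sample per
#' diploid individual, one record per segregating site.
#'
#' @param haplotypes 0/1 matrix from [propagate_neutral_variation()]
#'   (rows = chromosome copies, in individual order).
#' @param positions Site positions in bp (0-based; written 1-based).
#' @param path Output path.
#' @param chrom Chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_vcf_gt <- function(haplotypes, positions, path, chrom = "1") {
  n_ind <- nrow(haplotypes) %/% 2L
  samples <- paste0("ind", seq_len(n_ind))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  odd <- seq(1L, nrow(haplotypes), by = 2L)
  records <- vapply(seq_along(positions), function(s) {
    gt <- paste0(haplotypes[odd, s], "|", haplotypes[odd + 1L, s])
    paste(c(chrom, positions[s] + 1L, ".", "A", "T", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}
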