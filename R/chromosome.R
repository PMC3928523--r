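#' Construct a chromosome as a mosaic of founder-haplotype chunks
#'
#' A chromosome copy is stored as a list of haplotype chunks.  Each chunk is
#' a pair (start position, founder id): the 0-based base-pair coordinate
#' where the chunk begins and the identifier of the founding haplotype it
#' descends from.  A chunk covers the half-open interval from its own start
#' to the next chunk's start (or to the chromosome end for the last chunk).
#'
#' @param positions Integer vector of chunk start positions, strictly
#'   increasing, first element 0, all less than `length`.
#' @param ids Integer vector of founder-haplotype ids (non-negative), one
#'   per chunk.
#' @param length Chromosome length in bp (integer, >= 1).
#' @return An object of class `chromosome`: a list with integer fields
#'   `pos`, `id` and `length`.
#' @examples
#' chromosome(c(0, 30, 70), c(7, 11, 7), 100)
#' @export
chromosome <- function(positions, ids, length) {
  chrom <- structure(
    list(pos = as.integer(positions), id = as.integer(ids),
         length = as.integer(length)),
    class = "chromosome"
  )
  validate_chromosome(chrom)
  chrom
}

validate_chromosome <- function(chrom) {
  pos <- chrom$pos
  id <- chrom$id
  len <- chrom$length
  if (length(len) != 1L || is.na(len) || len < 1L)
    stop("chromosome length must be a single integer >= 1", call. = FALSE)
  if (length(pos) == 0L)
    stop("a chromosome must contain at least one chunk", call. = FALSE)
  if (length(pos) != length(id))
    stop("chunk positions and ids differ in length", call. = FALSE)
  if (anyNA(pos) || anyNA(id))
    stop("chunk positions and ids must not contain NA", call. = FALSE)
  if (pos[1L] != 0L)
    stop("first chunk must start at position 0", call. = FALSE)
  if (length(pos) > 1L && any(diff(pos) <= 0L))
    stop("chunk positions must be strictly increasing", call. = FALSE)
  if (pos[length(pos)] >= len)
    stop("chunk positions must be smaller than the chromosome length",
         call. = FALSE)
  if (any(id < 0L))
    stop("founder ids must be non-negative", call. = FALSE)
  invisible(chrom)
}

#' @export
print.chromosome <- function(x, ...) {
  cat("<chromosome> length", x$length, "bp,", length(x$pos), "chunk(s)\n")
  cat(paste0("(", x$pos, ",", x$id, ")", collapse = " "), "\n")
  invisible(x)
}

#' @export
format.chromosome <- function(x, ...) {
  paste0("(", x$pos, ",", x$id, ")", collapse = " ")
}

#' Founder id carried at a position
#'
#' Looks up which founding haplotype a chromosome copy descends from at one
#' or more base-pair positions.  A position on a chunk boundary belongs to
#' the chunk that begins there (half-open intervals).
#'
#' @param chrom A [chromosome()].
#' @param position Integer vector of 0-based positions, each in
#'   `[0, length)`.
#' @return Integer vector of founder ids, one per queried position.
#' @examples
#' ch <- chromosome(c(0, 30, 70), c(7, 11, 7), 100)
#' founder_id_at(ch, c(45, 70)) # 11, 7
#' @export
founder_id_at <- function(chrom, position) {
  position <- as.integer(position)
  if (anyNA(position) || any(position < 0L) || any(position >= chrom$length))
    stop("position out of range [0, ", chrom$length, ")", call. = FALSE)
  chrom$id[findInterval(position, chrom$pos)]
}

#' Merge adjacent chunks that share a founder id
#'
#' Normalization keeps the mosaic representation minimal: consecutive
#' chunks descending from the same founder are merged into one.  The
#' ancestry read off by [founder_id_at()] is unchanged at every position.
#'
#' @param chrom A [chromosome()] whose chunks may contain adjacent
#'   duplicated ids.
#' @return A normalized [chromosome()].
#' @examples
#' normalize_chunks(chromosome(c(0, 10, 20, 30), c(1, 2, 2, 1), 50))
#' @export
normalize_chunks <- function(chrom) {
  keep <- c(TRUE, diff(chrom$id) != 0L)
  chromosome(chrom$pos[keep], chrom$id[keep], chrom$length)
}

#' Chunks of a chromosome as a tibble
#'
#' @param chrom A [chromosome()].
#' @return A tibble with one row per chunk: `start`, `end` (half-open) and
#'   `founder_id`.
#' @export
chunk_table <- function(chrom) {
  tibble::tibble(
    start = chrom$pos,
    end = c(chrom$pos[-1L], chrom$length),
    founder_id = chrom$id
  )
}
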