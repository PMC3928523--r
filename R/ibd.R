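#' Identical-by-descent tracts between two chromosomes
#'
#' Because every chromosome is an explicit mosaic of founder haplotypes,
#' IBD tracts need no inference: two chromosome copies are identical by
#' descent wherever they carry the same founder id.  The tracts are
#' computed by merging the two chunk breakpoint sets — no per-base scan —
#' and reported as maximal half-open intervals sharing one founder id
#' (an interval ends where either the sharing stops or the shared id
#' changes).
#'
#' @param chrom_a,chrom_b [chromosome()] copies of equal length.
#' @return A tibble with columns `start`, `end` (half-open bp interval)
#'   and `founder_id`; intervals are disjoint and sorted.
#' @examples
#' a <- chromosome(c(0, 30), c(7, 11), 100)
#' b <- chromosome(c(0, 50), c(7, 11), 100)
#' pairwise_ibd(a, b) # [0,30) shared id 7; [50,100) shared id 11
#' @export
pairwise_ibd <- function(chrom_a, chrom_b) {
  if (chrom_a$length != chrom_b$length)
    stop("chromosomes differ in length", call. = FALSE)
  bp <- sort(unique(c(chrom_a$pos, chrom_b$pos)))
  ida <- chrom_a$id[findInterval(bp, chrom_a$pos)]
  idb <- chrom_b$id[findInterval(bp, chrom_b$pos)]
  shared <- ida == idb
  # merge adjacent segments with the same shared id
  seg_id <- ifelse(shared, ida, -1L)
  run <- cumsum(c(TRUE, seg_id[-1L] != seg_id[-length(seg_id)]))
  starts <- bp[!duplicated(run)]
  ends <- c(starts[-1L], chrom_a$length)
  ids <- seg_id[!duplicated(run)]
  keep <- ids >= 0L
  tibble::tibble(start = starts[keep], end = ends[keep],
                 founder_id = ids[keep])
}

#' Total IBD length between two chromosomes
#'
#' @inheritParams pairwise_ibd
#' @return Total bp shared identical by descent.  Symmetric in its
#'   arguments; equals the chromosome length when a chromosome is
#'   compared with itself.
#' @export
ibd_length <- function(chrom_a, chrom_b) {
  tr <- pairwise_ibd(chrom_a, chrom_b)
  sum(tr$end - tr$start)
}
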