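#' Locate a karyotype fusion point from PAF alignments
#'
#' The swamp water-buffalo karyotype (2n = 48) carries a chromosome 1
#' formed by fusing river chromosomes 4 and 9 (2n = 50). Given PAF
#' alignments of the fused query chromosome against the two river
#' targets, records are filtered to the query and targets (alignments
#' shorter than `min_block` bp are ignored as spurious), clustered by
#' target, and the cluster with the smaller maximum query end is taken as
#' upstream. The fusion point is the floor midpoint of the gap between
#' the upstream cluster's last aligned base and the downstream cluster's
#' first. Clusters overlapping by more than `overlap_tol * query_len`
#' raise an error; a smaller overlap (ragged alignments near the
#' junction) yields a warning, and the midpoint is still returned.
#'
#' @param paf PAF tibble from [read_paf()].
#' @param query_chrom Fused query chromosome name.
#' @param target_a,target_b The two target chromosome names.
#' @param min_block Minimum alignment length (bp) to keep.
#' @param overlap_tol Tolerated cluster overlap, as a fraction of the
#'   query length.
#' @return One-row tibble: `query_chrom`, `fusion_point` (0-based bp),
#'   `upstream_target`, `upstream_start`, `upstream_end`,
#'   `downstream_target`, `downstream_start`, `downstream_end`,
#'   `gap_len` (may be <= 0).
#' @examples
#' sim <- simulate_fusion_paf(2e6, 9e5, 11e5)
#' find_fusion_point(sim$paf, "chr1", "chr4", "chr9")$fusion_point
#' @export
find_fusion_point <- function(paf, query_chrom, target_a, target_b,
                              min_block = 10000, overlap_tol = 0.01) {
  x <- paf[paf$query_name == query_chrom &
             paf$target_name %in% c(target_a, target_b) &
             (paf$query_end - paf$query_start) >= min_block, , drop = FALSE]
  for (tg in c(target_a, target_b)) {
    if (!any(x$target_name == tg)) {
      abort(sprintf("no alignment of %s against target %s (>= %d bp)",
                    query_chrom, tg, as.integer(min_block)))
    }
  }
  qlen <- x$query_len[1]
  cl <- lapply(split(x, x$target_name), function(r) {
    list(target = r$target_name[1], start = min(r$query_start),
         end = max(r$query_end))
  })
  ord <- order(vapply(cl, function(c) c$end, numeric(1)))
  up <- cl[[ord[1]]]
  dn <- cl[[ord[2]]]
  overlap <- up$end - dn$start
  if (overlap > overlap_tol * qlen) {
    abort(sprintf(
      "alignment clusters interleave by %d bp (> %.0f%% of query length)",
      overlap, 100 * overlap_tol))
  }
  if (overlap > 0) {
    warn(sprintf("clusters overlap by %d bp; returning gap midpoint anyway",
                 overlap))
  }
  tibble::tibble(
    query_chrom = query_chrom,
    fusion_point = floor((up$end + dn$start) / 2),
    upstream_target = up$target, upstream_start = up$start,
    upstream_end = up$end,
    downstream_target = dn$target, downstream_start = dn$start,
    downstream_end = dn$end,
    gap_len = dn$start - up$end)
}

#' Split a fused chromosome at its fusion point
#'
#' Defines the two coordinate segments `<chrom>_a = [0, fusion)` and
#' `<chrom>_b = [fusion, len)` (0-based half-open) whose lengths sum to
#' the original chromosome length. The segment table feeds
#' [lift_coordinate()] and, written as BED, lets external tools cut the
#' sequence.
#'
#' @param chrom_len Chromosome length, bp.
#' @param fusion_point Fusion point, 0 < fusion_point < chrom_len.
#' @param chrom Chromosome name.
#' @return A `chrom_split` tibble: `segment`, `start`, `end`, `length`.
#' @export
split_chromosome <- function(chrom_len, fusion_point, chrom = "chr1") {
  if (fusion_point <= 0 || fusion_point >= chrom_len) {
    abort("fusion point must lie strictly inside the chromosome")
  }
  out <- tibble::tibble(
    segment = paste0(chrom, c("_a", "_b")),
    start = c(0L, as.integer(fusion_point)),
    end = c(as.integer(fusion_point), as.integer(chrom_len)),
    length = c(as.integer(fusion_point),
               as.integer(chrom_len - fusion_point)))
  class(out) <- c("chrom_split", class(out))
  out
}

#' Lift coordinates across a chromosome split
#'
#' `lift_coordinate()` maps 0-based positions on the fused chromosome to
#' (segment, position-within-segment); `unlift_coordinate()` inverts the
#' mapping, so the two compose to the identity.
#'
#' @param pos Integer vector of 0-based positions.
#' @param split A `chrom_split` from [split_chromosome()].
#' @return For `lift_coordinate()`, a tibble `segment`, `pos`; for
#'   `unlift_coordinate()`, an integer vector of original positions.
#' @export
lift_coordinate <- function(pos, split) {
  fusion <- split$end[1]
  len <- split$end[2]
  if (any(pos < 0 | pos >= len)) {
    abort("position outside the chromosome")
  }
  in_b <- pos >= fusion
  tibble::tibble(
    segment = ifelse(in_b, split$segment[2], split$segment[1]),
    pos = as.integer(ifelse(in_b, pos - fusion, pos)))
}

#' @rdname lift_coordinate
#' @param segment Segment names as produced by `lift_coordinate()`.
#' @export
unlift_coordinate <- function(segment, pos, split) {
  fusion <- split$end[1]
  bad <- !segment %in% split$segment
  if (any(bad)) abort("unknown segment name")
  as.integer(ifelse(segment == split$segment[2], pos + fusion, pos))
}
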