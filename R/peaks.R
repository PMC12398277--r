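#' Average standardized scores over fixed-size variant windows
#'
#' Splits the valid, standardized scores of each chromosome (ordered by
#' position) into consecutive non-overlapping windows of exactly
#' `window_size` variants; the trailing remainder shorter than a full
#' window is dropped so window means stay comparable. The mean keeps its
#' sign — the peak caller takes absolute values later.
#'
#' @param scores A standardized `sweep_scan` (see [standardize_scores()]).
#' @param window_size Number of valid variants per window.
#' @return A `sweep_windows` tibble: `chrom`, `window_index`,
#'   `first_site_index`, `last_site_index`, `first_pos`, `last_pos`,
#'   `mean_z`, `n_sites`.
#' @export
window_means <- function(scores, window_size = 100) {
  assert_columns(scores, c("chrom", "pos", "z", "valid"), "scores")
  use <- scores[scores$valid & !is.na(scores$z), , drop = FALSE]
  out <- use |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(window_index =
                    (dplyr::row_number() - 1L) %/% as.integer(window_size)) |>
    dplyr::group_by(.data$chrom, .data$window_index) |>
    dplyr::filter(dplyr::n() == window_size) |>
    dplyr::summarise(first_site_index = dplyr::first(.data$site_index),
                     last_site_index = dplyr::last(.data$site_index),
                     first_pos = dplyr::first(.data$pos),
                     last_pos = dplyr::last(.data$pos),
                     mean_z = mean(.data$z),
                     n_sites = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$window_index)
  class(out) <- c("sweep_windows", class(out))
  out
}

#' Call selection-sweep peaks with a windowed hysteresis rule
#'
#' A window whose `|mean_z|` reaches `seed_threshold` seeds a peak; the
#' peak is extended over consecutive windows to the left and right for as
#' long as `|mean_z|` stays at or above `edge_threshold` (the score
#' "rises above 1.5 and falls back below 0.5"). The two-threshold
#' hysteresis prevents a broad sweep signal from fragmenting into
#' many small peaks. Seeds falling in the same extended span produce one
#' peak; overlapping or adjacent spans are merged. Because absolute
#' values are used, calls are invariant to a global sign flip.
#'
#' @param windows A `sweep_windows` tibble from [window_means()].
#' @param seed_threshold `|mean_z|` needed to seed a peak.
#' @param edge_threshold `|mean_z|` needed to keep extending it.
#' @return A `sweep_peaks` tibble: `chrom`, `start_pos`, `end_pos`
#'   (1-based inclusive bp, first to last variant of member windows),
#'   `first_window`, `last_window`, `seed_window`, `max_abs_mean`,
#'   `n_windows`.
#' @export
call_peaks <- function(windows, seed_threshold = 1.5,
                       edge_threshold = 0.5) {
  stopifnot(seed_threshold > edge_threshold, edge_threshold > 0)
  per_chrom <- function(w) {
    w <- w[order(w$window_index), , drop = FALSE]
    a <- abs(w$mean_z)
    seeds <- which(a >= seed_threshold)
    if (length(seeds) == 0) return(NULL)
    spans <- lapply(seeds, function(s) {
      lo <- s
      while (lo > 1 && a[lo - 1] >= edge_threshold) lo <- lo - 1
      hi <- s
      while (hi < length(a) && a[hi + 1] >= edge_threshold) hi <- hi + 1
      c(lo, hi, s)
    })
    # merge overlapping/adjacent spans from different seeds
    spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
    merged <- list()
    for (sp in spans) {
      last <- if (length(merged) > 0) merged[[length(merged)]] else NULL
      if (!is.null(last) && sp[1] <= last[2] + 1) {
        merged[[length(merged)]] <- c(last[1], max(last[2], sp[2]), last[3])
      } else {
        merged[[length(merged) + 1]] <- sp
      }
    }
    dplyr::bind_rows(lapply(merged, function(sp) {
      rows <- sp[1]:sp[2]
      tibble::tibble(
        chrom = w$chrom[1],
        start_pos = w$first_pos[sp[1]], end_pos = w$last_pos[sp[2]],
        first_window = w$window_index[sp[1]],
        last_window = w$window_index[sp[2]],
        seed_window = w$window_index[sp[3]],
        max_abs_mean = max(a[rows]), n_windows = length(rows))
    }))
  }
  out <- dplyr::bind_rows(lapply(split(windows, windows$chrom), per_chrom))
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start_pos = integer(),
                          end_pos = integer(), first_window = integer(),
                          last_window = integer(), seed_window = integer(),
                          max_abs_mean = numeric(), n_windows = integer())
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start_pos)
  class(out) <- c("sweep_peaks", class(out))
  out
}

#' Merge peak coordinates into unique selection regions
#'
#' Unions peak intervals — typically pooled across metrics and
#' populations — into sorted, disjoint regions, the "unique BED" of
#' selection regions downstream enrichment works on.
#'
#' @param peaks A `sweep_peaks` tibble (or any tibble with `chrom`,
#'   `start_pos`/`start`, `end_pos`/`end`).
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive), disjoint
#'   and sorted; write with [write_bed()].
#' @export
merge_peak_regions <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  start <- peaks[["start_pos"]] %||% peaks[["start"]]
  end <- peaks[["end_pos"]] %||% peaks[["end"]]
  merge_intervals(tibble::tibble(chrom = peaks$chrom, start = start,
                                 end = end))
}

#' Intersect gene models with sweep peaks
#'
#' A gene overlaps a peak iff their 1-based inclusive intervals intersect
#' by at least 1 bp (touching intervals do not intersect). Returns one
#' row per (peak, gene) overlap; count peaks per gene with
#' `dplyr::count(result, gene_id)`.
#'
#' @param peaks A `sweep_peaks` tibble.
#' @param genes Gene models from [read_gff3_genes()].
#' @return Tibble `chrom`, `peak_start`, `peak_end`, `gene_id`,
#'   `gene_start`, `gene_end`.
#' @export
genes_in_peaks <- function(peaks, genes) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  empty <- tibble::tibble(chrom = character(), peak_start = integer(),
                          peak_end = integer(), gene_id = character(),
                          gene_start = integer(), gene_end = integer())
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(empty)
  gp <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start_pos,
                                                peaks$end_pos))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gp, gg, minoverlap = 1L)
  if (length(ov) == 0) return(empty)
  i <- S4Vectors::queryHits(ov)
  j <- S4Vectors::subjectHits(ov)
  tibble::tibble(chrom = peaks$chrom[i], peak_start = peaks$start_pos[i],
                 peak_end = peaks$end_pos[i], gene_id = genes$gene_id[j],
                 gene_start = genes$start[j], gene_end = genes$end[j])
}
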