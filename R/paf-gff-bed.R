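#' Read a PAF alignment file
#'
#' Parses the 12 mandatory columns of minimap2-style PAF (optional SAM-like
#' tags are ignored). Coordinates are 0-based half-open on both query and
#' target, as in the format itself.
#'
#' @param path Path to a `.paf` (or gzipped) file.
#' @return A tibble with columns `query_name`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target_name`, `target_len`, `target_start`,
#'   `target_end`, `n_match`, `aln_len`, `mapq`.
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      query_name = character(), query_len = integer(),
      query_start = integer(), query_end = integer(), strand = character(),
      target_name = character(), target_len = integer(),
      target_start = integer(), target_end = integer(),
      n_match = integer(), aln_len = integer(), mapq = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 12)
  if (length(bad) > 0) {
    abort(sprintf("malformed PAF record at line %d: fewer than 12 columns",
                  bad[1]))
  }
  col <- function(i) vapply(f, `[`, character(1), i)
  int_col <- function(i, name) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v)) {
      abort(sprintf("malformed PAF record at line %d: non-integer %s",
                    which(is.na(v))[1], name))
    }
    v
  }
  out <- tibble::tibble(
    query_name = col(1), query_len = int_col(2, "query length"),
    query_start = int_col(3, "query start"), query_end = int_col(4, "query end"),
    strand = col(5), target_name = col(6),
    target_len = int_col(7, "target length"),
    target_start = int_col(8, "target start"),
    target_end = int_col(9, "target end"),
    n_match = int_col(10, "match count"), aln_len = int_col(11, "block length"),
    mapq = int_col(12, "mapping quality"))
  bad_q <- out$query_start < 0 | out$query_start >= out$query_end |
    out$query_end > out$query_len
  bad_t <- out$target_start < 0 | out$target_start >= out$target_end |
    out$target_end > out$target_len
  if (any(bad_q | bad_t)) {
    abort(sprintf(
      "invalid PAF coordinates at line %d: need 0 <= start < end <= length",
      which(bad_q | bad_t)[1]))
  }
  if (!all(out$strand %in% c("+", "-"))) {
    abort("PAF strand column must be '+' or '-'")
  }
  out
}

#' @rdname read_paf
#' @param x A PAF tibble as returned by `read_paf()`.
#' @export
write_paf <- function(x, path) {
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps rows of type `gene` and extracts the gene identifier from the
#' `ID=` (fallback `gene=`) attribute. Gene rows without an identifier are
#' skipped with a warning; rows of other types are ignored.
#'
#' @param path Path to a GFF3 file (plain or gzip).
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gff3_genes <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(lengths(f) < 9)
  if (length(bad) > 0) {
    abort(sprintf("malformed GFF3 record at line %d: fewer than 9 columns",
                  lineno[bad[1]]))
  }
  type <- vapply(f, `[`, character(1), 3)
  genes <- which(type == "gene")
  out <- lapply(genes, function(i) {
    r <- f[[i]]
    start <- suppressWarnings(as.integer(r[4]))
    end <- suppressWarnings(as.integer(r[5]))
    if (is.na(start) || is.na(end) || start > end) {
      abort(sprintf("invalid gene coordinates at line %d", lineno[i]))
    }
    id <- info_get(gsub(";\\s+", ";", r[9]), "ID")
    if (is.na(id)) id <- info_get(r[9], "gene")
    if (is.na(id)) {
      warn(sprintf("gene row at line %d lacks an ID/gene attribute; skipped",
                   lineno[i]))
      return(NULL)
    }
    tibble::tibble(gene_id = id, chrom = r[1], start = start, end = end)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer())
  }
  out
}

# merge 1-based inclusive intervals into sorted disjoint ones (union);
# adjacent intervals (end + 1 == next start) are merged too
merge_intervals <- function(x) {
  assert_columns(x, c("chrom", "start", "end"), "interval table")
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start, x$end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr)) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write intervals as a BED3 file
#'
#' Takes 1-based inclusive intervals (the package-internal convention),
#' merges overlapping/adjacent ones, sorts by (chrom, start) and writes
#' 0-based half-open BED3.
#'
#' @param x Tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  m <- merge_intervals(x)
  readr::write_tsv(
    tibble::tibble(chrom = m$chrom, start = m$start - 1L, end = m$end),
    path, col_names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `population`, `coverage`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(x, c("sample", "population", "coverage"), "sample metadata")
  x
}
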