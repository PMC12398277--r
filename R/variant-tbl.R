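#' Variant tables
#'
#' `pansweep` represents a VCF as a *variant table*: a tibble with one row
#' per record and list-columns holding per-sample data. Columns are
#' `chrom`, `pos` (1-based bp), `id`, `ref`, `alt`, `qual`, `filter`,
#' `info` (raw semicolon-separated INFO string), `gt` (list of
#' n-sample x 2 integer allele matrices, `NA` = missing), `phased`
#' (list of per-sample logicals) and `gq` (list of per-sample integer
#' genotype qualities, or `NULL` when the record carries no GQ). The
#' ordered sample names are stored in the `samples` attribute and
#' retrieved with `vcf_samples()`.
#'
#' @param chrom,pos,ref,alt Per-record character/integer vectors.
#' @param gt List of integer matrices (one per record, samples x 2).
#' @param samples Character vector of sample ids (column order of `gt`).
#' @param id,qual,filter,info Optional per-record fields (default `.`).
#' @param phased List of per-sample logical vectors (default unphased).
#' @param gq List of per-sample integer vectors or `NULL` entries.
#'
#' @return A `variant_tbl` (a tibble subclass).
#' @examples
#' gt <- list(rbind(c(0L, 1L), c(0L, 0L)))
#' v <- variant_tbl(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
#'                  gt = gt, samples = c("S1", "S2"))
#' vcf_samples(v)
#' @export
variant_tbl <- function(chrom, pos, ref, alt, gt, samples,
                        id = ".", qual = ".", filter = ".", info = NA_character_,
                        phased = NULL, gq = NULL) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(gt) == n)
  if (any(pos < 1L)) abort("variant positions must be >= 1")
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    abort("ref and alt alleles must be non-empty")
  }
  ns <- length(samples)
  for (g in gt) {
    if (!is.matrix(g) || nrow(g) != ns) {
      abort("each gt entry must be an n_samples x 2 integer matrix")
    }
  }
  if (is.null(phased)) {
    phased <- replicate(n, rep(FALSE, ns), simplify = FALSE)
  }
  if (is.null(gq)) gq <- vector("list", n)
  recycle <- function(x) if (length(x) == 1L) rep(x, n) else x
  out <- tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    id = recycle(as.character(id)), ref = as.character(ref),
    alt = as.character(alt), qual = recycle(as.character(qual)),
    filter = recycle(as.character(filter)),
    info = recycle(as.character(info)),
    gt = gt, phased = phased, gq = gq
  )
  new_variant_tbl(out, samples)
}

new_variant_tbl <- function(x, samples) {
  structure(x, samples = as.character(samples),
            class = c("variant_tbl", class(tibble::tibble())))
}

#' @rdname variant_tbl
#' @param x A `variant_tbl`.
#' @export
vcf_samples <- function(x) attr(x, "samples", exact = TRUE)

#' @export
print.variant_tbl <- function(x, ...) {
  s <- vcf_samples(x)
  cat(sprintf("# A variant table: %d record(s), %d sample(s)\n",
              nrow(x), length(s)))
  if (length(s) > 0) {
    cat("# samples: ", paste(head(s, 8), collapse = ", "),
        if (length(s) > 8) ", ..." else "", "\n", sep = "")
  }
  NextMethod()
}

# per-record summaries used by QC and set accounting ------------------------

# fraction of samples with a missing genotype
missing_fraction <- function(x) {
  vapply(x$gt, function(g) mean(gt_missing(g)), numeric(1))
}

# minor allele frequency over non-missing alleles; NA when all missing
minor_allele_freq <- function(x) {
  vapply(x$gt, function(g) {
    a <- g[!is.na(g)]
    if (length(a) == 0) return(NA_real_)
    p <- mean(a == 1L)
    min(p, 1 - p)
  }, numeric(1))
}

# alternate allele frequency over non-missing alleles
alt_allele_freq <- function(x) {
  vapply(x$gt, function(g) {
    a <- g[!is.na(g)]
    if (length(a) == 0) return(NA_real_)
    mean(a == 1L)
  }, numeric(1))
}
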