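#' Mask genotypes with low genotype quality
#'
#' Sets to missing every genotype whose GQ is strictly below `min_gq`
#' (GQ 24 is masked at the default threshold 25; GQ 25 is kept). Records
#' without a GQ field — and samples whose GQ is itself missing — are left
#' untouched.
#'
#' @param x A [variant_tbl()] carrying per-sample GQ.
#' @param min_gq Minimum genotype quality to keep a call.
#' @return `x` with low-quality genotypes set to missing.
#' @export
mask_low_gq <- function(x, min_gq = 25) {
  for (i in seq_len(nrow(x))) {
    q <- x$gq[[i]]
    if (is.null(q)) next
    drop <- !is.na(q) & q < min_gq
    if (any(drop)) {
      g <- x$gt[[i]]
      g[drop, ] <- NA_integer_
      x$gt[[i]] <- g
    }
  }
  x
}

#' Filter variants on missingness and minor allele frequency
#'
#' Keeps a biallelic variant iff its missing-genotype fraction is at most
#' `max_missing` *and* its minor allele frequency (computed over
#' non-missing alleles) is strictly greater than `min_maf` — i.e. a
#' variant sitting exactly at MAF 0.05 is excluded, matching the usual
#' `MAF>0.05` filter expression. Variants with all genotypes missing are
#' dropped (MAF undefined). Idempotent.
#'
#' @param x A [variant_tbl()] of biallelic records.
#' @param max_missing Maximum tolerated missing-genotype fraction.
#' @param min_maf Exclusive lower bound on minor allele frequency.
#' @return The filtered [variant_tbl()].
#' @export
filter_variants <- function(x, max_missing = 0.2, min_maf = 0.05) {
  miss <- missing_fraction(x)
  maf <- minor_allele_freq(x)
  keep <- !is.na(maf) & miss <= max_missing & maf > min_maf
  new_variant_tbl(x[keep, , drop = FALSE], vcf_samples(x))
}

#' Prune related samples, prioritizing coverage
#'
#' Builds the kinship graph whose edges are pairs with kinship strictly
#' above `threshold` (0.0625 = third-degree relatives), then keeps a
#' greedy maximum-coverage independent set: samples are visited by
#' coverage descending (ties broken by sample id ascending) and kept iff
#' no already-kept sample is a neighbor. Isolated samples are always
#' kept; no two kept samples share an edge. This retains every mutually
#' unrelated member of a family cluster rather than a single
#' representative, maximizing cohort size while honoring the threshold.
#'
#' @param kinship Tibble with columns `sample1`, `sample2`, `kinship`.
#' @param metadata Tibble with columns `sample`, `coverage` (mean read
#'   depth); must cover every sample in `kinship`.
#' @param threshold Kinship above which a pair counts as related.
#' @return `metadata` with a logical `kept` column, ordered as input.
#' @examples
#' kin <- tibble::tibble(sample1 = c("A", "B"), sample2 = c("B", "C"),
#'                       kinship = c(0.10, 0.07))
#' meta <- tibble::tibble(sample = c("A", "B", "C", "D"),
#'                        coverage = c(30, 20, 15, 9))
#' prune_related(kin, meta)  # keeps A, C, D; removes B
#' @export
prune_related <- function(kinship, metadata, threshold = 0.0625) {
  assert_columns(kinship, c("sample1", "sample2", "kinship"), "kinship table")
  assert_columns(metadata, c("sample", "coverage"), "metadata")
  nodes <- metadata$sample
  unknown <- setdiff(c(kinship$sample1, kinship$sample2), nodes)
  if (length(unknown) > 0) {
    abort(sprintf("kinship pairs reference sample(s) without coverage: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (anyNA(metadata$coverage)) abort("coverage must be known for all samples")
  if (any(kinship$sample1 == kinship$sample2)) {
    abort("kinship table contains self-pairs")
  }
  rel <- kinship[kinship$kinship > threshold, , drop = FALSE]
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (i in seq_len(nrow(rel))) {
    a <- rel$sample1[i]; b <- rel$sample2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ord <- order(-metadata$coverage, metadata$sample)
  kept <- character(0)
  for (i in ord) {
    s <- nodes[i]
    if (!any(adj[[s]] %in% kept)) kept <- c(kept, s)
  }
  metadata$kept <- metadata$sample %in% kept
  metadata
}

#' Transition/transversion ratio of SNVs
#'
#' Counts transitions (A<->G, C<->T) and transversions among SNV records
#' (non-SNVs are ignored) and returns their ratio — a coarse variant-set
#' quality indicator (~2.1-2.2 for good mammalian whole-genome calls).
#' Returns `NA` when there are no SNVs and `Inf` when there are
#' transitions but no transversions.
#'
#' @param x A [variant_tbl()]; classified with [classify_variants()] if
#'   the `variant_class` column is absent.
#' @return A single numeric ratio.
#' @export
titv_ratio <- function(x) {
  if (!"variant_class" %in% names(x)) x <- classify_variants(x)
  snv <- x[x$variant_class == "SNV", , drop = FALSE]
  if (nrow(snv) == 0) return(NA_real_)
  pair <- paste0(pmin(snv$ref, snv$alt), pmax(snv$ref, snv$alt))
  ti <- sum(pair %in% c("AG", "CT"))
  tv <- nrow(snv) - ti
  if (tv == 0) return(Inf)
  ti / tv
}
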