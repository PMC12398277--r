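#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: with all
#' margins fixed, the probabilities of every table whose hypergeometric
#' probability does not exceed that of the observed table are summed
#' (the convention of the standard exact-test implementations). A zero
#' row or column margin makes the test undefined; p = 1 is returned with
#' a warning.
#'
#' @param a,b,c,d Cell counts (`a` = in-region class X, `b` = in-region
#'   other, `c` = background class X, `d` = background other), or pass a
#'   2x2 matrix as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(0, 5, 5, 0)  # 2/252
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != trunc(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warn("zero margin: Fisher exact p undefined, returning 1")
    return(1)
  }
  m <- a + c          # column-X margin ("white balls")
  n <- b + d          # other column
  k <- a + b          # row-1 draws
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  # relative tolerance guards ties computed in floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

impact_levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# extract the SnpEff-style impact from an INFO string: prefer IMPACT=,
# fall back to the 3rd pipe-field of ANN= entries; most severe retained
impact_from_info <- function(info) {
  vapply(info, function(s) {
    if (is.na(s)) return(NA_character_)
    imp <- info_get(s, "IMPACT")
    if (!is.na(imp) && imp %in% impact_levels) return(imp)
    ann <- info_get(s, "ANN")
    if (is.na(ann)) return(NA_character_)
    found <- vapply(strsplit(ann, ",", fixed = TRUE)[[1]], function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(f) >= 3) f[3] else NA_character_
    }, character(1))
    found <- found[found %in% impact_levels]
    if (length(found) == 0) return(NA_character_)
    impact_levels[min(match(found, impact_levels))]
  }, character(1), USE.NAMES = FALSE)
}

#' Add an impact-class column from INFO annotations
#'
#' @param x A [variant_tbl()] whose INFO carries `IMPACT=` or
#'   SnpEff-style `ANN=` annotations.
#' @return `x` with an `impact` factor column (HIGH, MODERATE, LOW,
#'   MODIFIER; most severe annotation retained).
#' @export
add_impact <- function(x) {
  x$impact <- factor(impact_from_info(x$info), levels = impact_levels)
  x
}

variants_in_regions <- function(x, regions) {
  if (nrow(regions) == 0) return(rep(FALSE, nrow(x)))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gv <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  # seqinfo-merge chatter is expected when the chromosome sets differ
  suppressWarnings(IRanges::overlapsAny(gv, gr))
}

#' Impact-class enrichment of variants inside selection regions
#'
#' For every variant class (SNV, indel, SV) and impact class, builds the
#' 2x2 table \[in-region with impact X, in-region other impacts;
#' out-of-region with X, out-of-region other\] and reports the odds ratio
#' (0.5 added to every cell when any cell is zero) with the two-sided
#' Fisher exact p-value, the in/out proportions, and Benjamini-Hochberg
#' adjusted p across the impact-by-class grid. The background is the
#' variants *outside* the regions, keeping the table cells disjoint.
#'
#' @param x A [variant_tbl()] with `variant_class` (see
#'   [classify_variants()]) and `impact` (see [add_impact()]) columns.
#' @param regions Disjoint regions tibble (`chrom`, `start`, `end`,
#'   1-based inclusive), e.g. from [merge_peak_regions()].
#' @return Tibble with one row per (variant_class, impact): cell counts,
#'   `prop_in`, `prop_out`, `odds_ratio`, `p_value`, `p_adj`.
#' @export
impact_enrichment <- function(x, regions) {
  assert_columns(x, c("chrom", "pos", "variant_class", "impact"),
                 "annotated variants")
  cls <- dplyr::case_when(
    x$variant_class == "SNV" ~ "SNV",
    x$variant_class == "INDEL" ~ "INDEL",
    TRUE ~ "SV")
  inr <- variants_in_regions(x, regions)
  if (!any(inr)) {
    warn("no variants fall inside the regions; p-values are 1 by convention")
  }
  grid <- tidyr::expand_grid(variant_class = unique(cls),
                             impact = impact_levels)
  grid <- grid[grid$impact %in% as.character(unique(x$impact)), ,
               drop = FALSE]
  out <- purrr::pmap_dfr(grid, function(variant_class, impact) {
    sel <- cls == variant_class
    is_x <- sel & as.character(x$impact) == impact & !is.na(x$impact)
    a <- sum(is_x & inr); b <- sum(sel & !is_x & inr)
    cc <- sum(is_x & !inr); dd <- sum(sel & !is_x & !inr)
    or <- if (any(c(a, b, cc, dd) == 0)) {
      ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * dd) / (b * cc)
    }
    p <- suppressWarnings(fisher_exact_two_sided(a, b, cc, dd))
    tibble::tibble(
      variant_class = variant_class, impact = impact,
      n_in_impact = a, n_in_other = b,
      n_out_impact = cc, n_out_other = dd,
      prop_in = if (a + b > 0) a / (a + b) else NA_real_,
      prop_out = if (cc + dd > 0) cc / (cc + dd) else NA_real_,
      odds_ratio = or, p_value = p)
  })
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("impact_enrichment", class(out))
  out
}

#' Alternate allele frequencies per population inside regions
#'
#' For every variant falling inside the regions (all variants when
#' `regions` is `NULL`), computes the alternate allele frequency within
#' each population over non-missing alleles. A population with all
#' genotypes missing at a variant yields `NA`.
#'
#' @param x A [variant_tbl()].
#' @param populations Tibble with columns `sample`, `population`
#'   partitioning the samples.
#' @param regions Optional regions tibble (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @return Long tibble: `chrom`, `pos`, `ref`, `alt`, `population`,
#'   `aaf`, `n_alleles`.
#' @export
population_aaf <- function(x, populations, regions = NULL) {
  assert_columns(populations, c("sample", "population"), "populations")
  samples <- vcf_samples(x)
  unknown <- setdiff(populations$sample, samples)
  if (length(unknown) > 0) {
    abort(sprintf("population sample(s) not in VCF: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  keep <- if (is.null(regions)) rep(TRUE, nrow(x)) else
    variants_in_regions(x, regions)
  idx_by_pop <- split(match(populations$sample, samples),
                      populations$population)
  rows <- lapply(which(keep), function(i) {
    g <- x$gt[[i]]
    purrr::imap_dfr(idx_by_pop, function(idx, pop) {
      a <- g[idx, , drop = FALSE]
      a <- a[!is.na(a)]
      tibble::tibble(chrom = x$chrom[i], pos = x$pos[i], ref = x$ref[i],
                     alt = x$alt[i], population = pop,
                     aaf = if (length(a) == 0) NA_real_ else mean(a == 1L),
                     n_alleles = length(a))
    })
  })
  dplyr::bind_rows(rows)
}
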