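#' Annotate records with assembly support vectors
#'
#' Writes a `SUPP_VEC` bit-string into each record's INFO: bit i is 1 iff
#' sample i's genotype carries at least one alternative allele. A missing
#' genotype contributes 0 — in a multi-assembly graph VCF, missingness
#' means the assembly path is absent. Bit order follows the sample list.
#'
#' @param x A [variant_tbl()] of biallelic records with genotypes.
#' @return `x` with `SUPP_VEC=...` added to the `info` column.
#' @export
compute_support_vectors <- function(x) {
  sv <- vapply(x$gt, function(g) {
    carries <- rowSums(g == 1L, na.rm = TRUE) > 0
    paste(as.integer(carries), collapse = "")
  }, character(1))
  x$info <- info_set(x$info, "SUPP_VEC", sv)
  x
}

support_vectors <- function(x) {
  sv <- info_get(x$info, "SUPP_VEC")
  if (anyNA(sv)) {
    abort("records lack SUPP_VEC; run compute_support_vectors() first")
  }
  sv
}

#' Count structural-variant sets across assemblies (upset counts)
#'
#' Tallies, over records with `|length_delta| >= min_sv_len`, how many
#' structural variants show each exact presence pattern across the
#' assemblies — the numbers behind an upset plot of SV sharing. Patterns
#' are the `SUPP_VEC` bit-strings; counts over all patterns partition the
#' SV records that are present in at least one assembly.
#'
#' @param x A [variant_tbl()] with `SUPP_VEC` annotations (see
#'   [compute_support_vectors()]).
#' @param min_sv_len Minimum `|length_delta|` (bp) to count as an SV.
#' @param top_n Optionally keep only the `top_n` most frequent patterns.
#' @return Tibble `pattern`, `n`, sorted by decreasing `n`.
#' @export
upset_counts <- function(x, min_sv_len = 50, top_n = NULL) {
  if (!"length_delta" %in% names(x)) x <- classify_variants(x)
  sv <- support_vectors(x)
  keep <- abs(x$length_delta) >= min_sv_len
  out <- tibble::tibble(pattern = sv[keep]) |>
    dplyr::count(.data$pattern, sort = TRUE)
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Account nonreference (inserted) sequence length by assembly group
#'
#' For insertions (`length_delta > 0`), sums the inserted bp that each
#' group of assemblies carries: `total_inserted_bp` counts a record once
#' when *any* group member carries it; `exclusive_inserted_bp` counts it
#' only when every carrier lies inside the group. Each record contributes
#' once per group — inserted sequence is a property of the variant path,
#' not of how many samples walk it. Deletions contribute nothing.
#'
#' @param x A [variant_tbl()] with `SUPP_VEC` annotations.
#' @param groups Tibble with columns `sample`, `group` (a sample may
#'   appear in one group only), or a named list of sample vectors.
#' @return Tibble `group`, `total_inserted_bp`, `exclusive_inserted_bp`.
#' @export
nonreference_lengths <- function(x, groups) {
  if (!"length_delta" %in% names(x)) x <- classify_variants(x)
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- tibble::tibble(
      sample = unlist(groups, use.names = FALSE),
      group = rep(names(groups), lengths(groups)))
  }
  assert_columns(groups, c("sample", "group"), "groups")
  samples <- vcf_samples(x)
  unknown <- setdiff(groups$sample, samples)
  if (length(unknown) > 0) {
    abort(sprintf("group sample(s) not in VCF: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  sv <- support_vectors(x)
  ins <- which(x$length_delta > 0)
  bits <- lapply(strsplit(sv[ins], ""), function(b) which(b == "1"))
  len <- x$length_delta[ins]
  dplyr::bind_rows(lapply(split(groups$sample, groups$group), function(g) {
    idx <- match(g, samples)
    in_grp <- vapply(bits, function(b) any(b %in% idx), logical(1))
    excl <- vapply(bits, function(b) length(b) > 0 && all(b %in% idx),
                   logical(1))
    tibble::tibble(total_inserted_bp = sum(len[in_grp]),
                   exclusive_inserted_bp = sum(len[excl]))
  }), .id = "group")
}

#' Classify variant-caller overlap by exact key matching
#'
#' Matches two normalized call sets on the exact key
#' `(chrom, pos, ref, alt)` and classifies every key as called by both,
#' only the first, or only the second caller. This is a deliberate
#' simplification of haplotype-aware matching (as done by vcfeval): a
#' variant represented differently by the two callers counts as two
#' caller-specific keys. Alternate allele frequencies per class (over the
#' respective call set's genotypes) are returned for frequency-spectrum
#' comparisons.
#'
#' @param a,b Two [variant_tbl()]s of biallelic, normalized records.
#' @return Tibble `class` ("both", "only_a", "only_b"), `n`, and `aaf`
#'   (list-column of per-variant alternate allele frequencies).
#' @export
classify_caller_overlap <- function(a, b) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  ka <- key(a); kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    warn("duplicate variant keys present; counting unique keys")
  }
  fa <- alt_allele_freq(a)[!duplicated(ka)]
  fb <- alt_allele_freq(b)[!duplicated(kb)]
  ua <- ka[!duplicated(ka)]; ub <- kb[!duplicated(kb)]
  both <- intersect(ua, ub)
  tibble::tibble(
    class = c("both", "only_a", "only_b"),
    n = c(length(both), sum(!ua %in% ub), sum(!ub %in% ua)),
    aaf = list(fa[ua %in% ub], fa[!ua %in% ub], fb[!ub %in% ua]))
}
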