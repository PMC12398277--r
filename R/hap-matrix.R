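#' Phased haplotype matrices
#'
#' The substrate of all haplotype statistics: an `n_hap x n_site` binary
#' matrix (`0` = ancestral, `1` = derived allele) with strictly increasing
#' physical positions in bp. No missing entries are allowed — sites and
#' samples must be filtered/phased upstream.
#'
#' @param alleles Integer/numeric matrix of 0/1, haplotypes in rows.
#' @param positions Strictly increasing integer vector of bp positions,
#'   one per column of `alleles`.
#' @param chrom Chromosome name (single string).
#' @return A `hap_matrix` object.
#' @examples
#' h <- hap_matrix(matrix(c(0, 1, 0, 1, 1, 0, 0, 1), nrow = 4),
#'                 positions = c(100L, 200L), chrom = "chr1")
#' n_haplotypes(h)
#' @export
hap_matrix <- function(alleles, positions, chrom = "chr1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles)) abort("haplotype matrix must have no missing entries")
  if (!all(alleles %in% c(0L, 1L))) {
    abort("haplotype matrix entries must be 0 or 1")
  }
  if (nrow(alleles) < 4) abort("need at least 4 haplotypes")
  positions <- as.integer(positions)
  if (length(positions) != ncol(alleles)) {
    abort("positions must have one entry per site")
  }
  if (ncol(alleles) > 1 && any(diff(positions) <= 0)) {
    abort("positions must be strictly increasing")
  }
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom)[1]),
            class = "hap_matrix")
}

#' @rdname hap_matrix
#' @param x A `hap_matrix`.
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' @rdname hap_matrix
#' @export
n_sites <- function(x) ncol(x$alleles)

#' @rdname hap_matrix
#' @export
derived_freq <- function(x) colMeans(x$alleles)

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes x %d sites on %s (%d-%d bp)\n",
              n_haplotypes(x), n_sites(x), x$chrom,
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Convert between phased variant tables and haplotype matrices
#'
#' `vcf_to_hap()` stacks the two phased alleles of every sample into rows
#' `<sample>_1`, `<sample>_2`. All records must be biallelic, phased and
#' fully called. `hap_to_vcf()` is the inverse, emitting phased biallelic
#' SNV-style records (REF `A`, ALT `T` placeholders) suitable for writing
#' with [write_vcf()].
#'
#' @param x A [variant_tbl()] (for `vcf_to_hap`) or a [hap_matrix()]
#'   (for `hap_to_vcf`).
#' @return A [hap_matrix()] or a [variant_tbl()] respectively.
#' @export
vcf_to_hap <- function(x) {
  samples <- vcf_samples(x)
  if (length(samples) == 0) abort("variant table has no samples")
  if (length(unique(x$chrom)) != 1) {
    abort("vcf_to_hap() expects records from a single chromosome")
  }
  G <- vapply(x$gt, function(g) as.vector(t(g)), integer(2 * length(samples)))
  if (anyNA(G)) abort("missing genotypes: filter or impute before phasing")
  if (!all(vapply(x$phased, all, logical(1)))) {
    abort("all genotypes must be phased")
  }
  H <- matrix(as.integer(G), nrow = 2 * length(samples))
  rownames(H) <- paste0(rep(samples, each = 2), "_", 1:2)
  hap_matrix(H, x$pos, chrom = x$chrom[1])
}

#' @rdname vcf_to_hap
#' @export
hap_to_vcf <- function(x) {
  nh <- n_haplotypes(x)
  if (nh %% 2 != 0) abort("haplotype count must be even to pair into samples")
  samples <- sprintf("S%03d", seq_len(nh / 2))
  gt <- lapply(seq_len(n_sites(x)), function(j) {
    matrix(x$alleles[, j], ncol = 2, byrow = TRUE)
  })
  phased <- replicate(n_sites(x), rep(TRUE, nh / 2), simplify = FALSE)
  variant_tbl(chrom = rep(x$chrom, n_sites(x)), pos = x$positions,
              ref = rep("A", n_sites(x)), alt = rep("T", n_sites(x)),
              gt = gt, samples = samples, phased = phased)
}
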