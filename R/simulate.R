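# Seeded generators for every input the pipeline consumes. These are
# first-class, tested code: the founder-mosaic panel is a stylized
# stand-in for a phased cohort (it creates linkage blocks without a full
# coalescent), and the other generators carry explicit truth tables so
# downstream modules can be checked against known answers.

#' Simulate a neutral founder-mosaic haplotype panel
#'
#' Founder haplotypes are drawn i.i.d. Bernoulli(0.5) per site; each
#' sampled haplotype walks along the sites copying one founder and
#' switches founder with probability `recomb_prob` per site, then flips
#' alleles with probability `mut_prob` per site. Positions are cumulative
#' geometric gaps (mean `mean_spacing` bp, minimum 1). Allele 0 is the
#' ancestral state. Deterministic given `seed`.
#'
#' @param n_hap Number of haplotypes (>= 4).
#' @param n_site Number of segregating sites.
#' @param n_founders Number of founder haplotypes (>= 2).
#' @param recomb_prob Per-site probability of switching founder.
#' @param mut_prob Per-site probability of flipping the copied allele.
#' @param mean_spacing Mean gap between adjacent sites, bp.
#' @param chrom Chromosome name for the panel.
#' @param seed Integer seed (optional; the caller may also set the RNG).
#' @return A [hap_matrix()].
#' @examples
#' p <- simulate_panel(20, 50, seed = 1)
#' p
#' @export
simulate_panel <- function(n_hap, n_site, n_founders = 8,
                           recomb_prob = 0.01, mut_prob = 0.002,
                           mean_spacing = 1000, chrom = "chr1",
                           seed = NULL) {
  stopifnot(n_hap >= 4, n_founders >= 2,
            recomb_prob >= 0, recomb_prob <= 1,
            mut_prob >= 0, mut_prob <= 1, mean_spacing >= 1)
  if (!is.null(seed)) set.seed(seed)
  founders <- matrix(rbinom(n_founders * n_site, 1L, 0.5),
                     nrow = n_founders)
  H <- matrix(0L, nrow = n_hap, ncol = n_site)
  for (i in seq_len(n_hap)) {
    f <- sample.int(n_founders, 1L)
    switch_at <- runif(n_site) < recomb_prob
    for (j in seq_len(n_site)) {
      if (switch_at[j]) f <- sample.int(n_founders, 1L)
      H[i, j] <- founders[f, j]
    }
    flips <- runif(n_site) < mut_prob
    H[i, flips] <- 1L - H[i, flips]
  }
  gaps <- 1L + rgeom(n_site, prob = 1 / mean_spacing)
  h <- hap_matrix(H, cumsum(gaps), chrom = chrom)
  h$founders <- founders
  h
}

#' Implant a hard selective sweep into a panel
#'
#' `round(target_daf * n_hap)` haplotypes are chosen as derived-allele
#' carriers (first indices after a seeded shuffle). On the window
#' `core_index +/- halfwidth` their alleles are replaced by founder 1's
#' alleles, flipped per site with probability `template_noise` — a long
#' shared haplotype, the signature iHS/nSL detect. The core column itself
#' is forced to 1 for carriers and 0 otherwise, so the core DAF is exact.
#' Columns outside the window are untouched.
#'
#' @param panel A [hap_matrix()] from [simulate_panel()] (needs the
#'   stored founder matrix).
#' @param core_index Site index (1-based) of the selected allele.
#' @param target_daf Derived allele frequency at the core.
#' @param halfwidth Half-width of the swept window, in sites.
#' @param template_noise Per-site flip probability on the swept segment.
#' @param seed Optional integer seed.
#' @return The modified [hap_matrix()], with attributes `sweep_core`,
#'   `sweep_window` (site-index range) and `sweep_carriers`.
#' @export
implant_sweep <- function(panel, core_index, target_daf = 0.8,
                          halfwidth = 150, template_noise = 0.01,
                          seed = NULL) {
  stopifnot(inherits(panel, "hap_matrix"), target_daf > 0, target_daf < 1)
  if (is.null(panel$founders)) {
    abort("panel lacks a founder matrix; generate it with simulate_panel()")
  }
  ns <- n_sites(panel)
  lo <- core_index - halfwidth
  hi <- core_index + halfwidth
  if (lo < 1 || hi > ns) {
    abort("sweep window extends outside the panel")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_haplotypes(panel)
  n_car <- round(target_daf * n)
  carriers <- sample.int(n)[seq_len(n_car)]
  template <- panel$founders[1, lo:hi]
  for (i in carriers) {
    seg <- template
    flips <- runif(length(seg)) < template_noise
    seg[flips] <- 1L - seg[flips]
    panel$alleles[i, lo:hi] <- seg
  }
  panel$alleles[, core_index] <- 0L
  panel$alleles[carriers, core_index] <- 1L
  panel$sweep_core <- core_index
  panel$sweep_window <- c(lo, hi)
  panel$sweep_carriers <- sort(carriers)
  panel
}

#' Simulate a toy multi-assembly pangenome VCF with known truth
#'
#' Each variant receives a presence bit-pattern over the assemblies: with
#' probability `singleton_weight` a single random assembly, otherwise a
#' pattern drawn uniformly from all non-empty patterns. Presence is
#' emitted as genotype `1/1` and absence as `0/0`, matching the
#' haplotype-assembly semantics of a graph VCF. Allele-length differences
#' are log-uniform; a fraction `sv_fraction` is forced to `|delta| >= 50`
#' bp (structural variants), the rest to 1-49 bp (indels). Insertions
#' outnumber deletions roughly 4:1 (`p_insertion`), echoing typical
#' assembly-based SV sets.
#'
#' @param n_assemblies Number of assemblies (>= 2).
#' @param n_variants Number of variant records.
#' @param singleton_weight Probability mass on single-assembly patterns.
#' @param sv_fraction Fraction of variants with `|length_delta| >= 50`.
#' @param max_ins_len Maximum allele-length difference, bp.
#' @param p_insertion Probability a variant is an insertion.
#' @param seed Optional integer seed.
#' @return List with `vcf` (a [variant_tbl()]) and `truth` (tibble:
#'   `variant`, `pattern`, `length_delta`).
#' @export
simulate_toy_pangenome <- function(n_assemblies, n_variants,
                                   singleton_weight = 0.6,
                                   sv_fraction = 0.3, max_ins_len = 10000,
                                   p_insertion = 0.7, seed = NULL) {
  stopifnot(n_assemblies >= 2, n_variants >= 1)
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("ASM%02d", seq_len(n_assemblies))

  patterns <- character(n_variants)
  for (v in seq_len(n_variants)) {
    bits <- integer(n_assemblies)
    if (runif(1) < singleton_weight) {
      bits[sample.int(n_assemblies, 1L)] <- 1L
    } else {
      repeat {
        bits <- rbinom(n_assemblies, 1L, 0.5)
        if (sum(bits) > 0) break
      }
    }
    patterns[v] <- paste(bits, collapse = "")
  }

  is_sv <- runif(n_variants) < sv_fraction
  log_u <- function(lo, hi, n) {
    round(exp(runif(n, log(lo), log(hi))))
  }
  len <- integer(n_variants)
  len[is_sv] <- pmax(50L, log_u(50, max_ins_len, sum(is_sv)))
  len[!is_sv] <- pmin(49L, pmax(1L, log_u(1, 49, sum(!is_sv))))
  sign <- ifelse(runif(n_variants) < p_insertion, 1L, -1L)
  delta <- len * sign

  bases <- c("A", "C", "G", "T")
  seqs <- vapply(len, function(L) {
    paste(sample(bases, L, replace = TRUE), collapse = "")
  }, character(1))
  ref <- ifelse(delta > 0, "A", paste0("A", seqs))
  alt <- ifelse(delta > 0, paste0("A", seqs), "A")

  gt <- lapply(patterns, function(p) {
    bits <- as.integer(strsplit(p, "")[[1]])
    cbind(bits, bits, deparse.level = 0)
  })
  vcf <- variant_tbl(chrom = rep("chr1", n_variants),
                     pos = cumsum(sample.int(2000L, n_variants,
                                             replace = TRUE)),
                     ref = ref, alt = alt, gt = gt, samples = samples)
  truth <- tibble::tibble(variant = seq_len(n_variants),
                          pattern = patterns, length_delta = delta)
  list(vcf = vcf, truth = truth)
}

#' Simulate a kinship cohort with family clusters
#'
#' Samples are organised into clusters; every within-cluster pair draws a
#' kinship coefficient from `within_kinship_range` and every cross-cluster
#' pair from `between_kinship_range`. The defaults straddle the
#' third-degree threshold 0.0625 (within strictly above, between at or
#' below), so each cluster behaves as a related clique. Per-sample mean
#' coverage is uniform on `coverage_range`.
#'
#' @param n_clusters Number of family clusters.
#' @param cluster_size_range Integer range of cluster sizes.
#' @param within_kinship_range,between_kinship_range Kinship ranges.
#' @param coverage_range Mean-coverage range (x-fold).
#' @param n_singletons Additional unrelated samples.
#' @param seed Optional integer seed.
#' @return List with `kinship` (tibble: `sample1`, `sample2`, `kinship`),
#'   `metadata` (tibble: `sample`, `cluster`, `coverage`).
#' @export
simulate_kin_cohort <- function(n_clusters, cluster_size_range = c(2, 5),
                                within_kinship_range = c(0.07, 0.25),
                                between_kinship_range = c(0, 0.05),
                                coverage_range = c(5, 40),
                                n_singletons = 0, seed = NULL) {
  stopifnot(n_clusters >= 1,
            within_kinship_range[1] > 0.0625,
            between_kinship_range[2] <= 0.0625)
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(cluster_size_range[1]:cluster_size_range[2],
                  n_clusters, replace = TRUE)
  cluster <- c(rep(seq_len(n_clusters), sizes),
               rep(0L, n_singletons))  # 0 = singleton
  n <- length(cluster)
  ids <- sprintf("B%03d", seq_len(n))
  meta <- tibble::tibble(
    sample = ids, cluster = cluster,
    coverage = round(runif(n, coverage_range[1], coverage_range[2]), 1))

  pairs <- utils::combn(n, 2)
  same <- cluster[pairs[1, ]] == cluster[pairs[2, ]] &
    cluster[pairs[1, ]] > 0L
  phi <- numeric(ncol(pairs))
  phi[same] <- runif(sum(same), within_kinship_range[1],
                     within_kinship_range[2])
  phi[!same] <- runif(sum(!same), between_kinship_range[1],
                      between_kinship_range[2])
  kin <- tibble::tibble(sample1 = ids[pairs[1, ]],
                        sample2 = ids[pairs[2, ]], kinship = phi)
  list(kinship = kin, metadata = meta)
}

#' Simulate PAF alignments of a fused chromosome
#'
#' Emulates a swamp-buffalo chromosome 1 (the river 4/9 fusion) aligned
#' against the two river chromosomes it fuses: the query interval
#' `[0, block1_end)` aligns to `target_a` and `[block2_start, chr1_len)`
#' to `target_b`. Each block may be cut into sub-alignments separated by
#' small unaligned gaps. The true fusion point is
#' `floor((block1_end + block2_start) / 2)`.
#'
#' @param chr1_len Fused-query chromosome length, bp.
#' @param block1_end End (0-based exclusive) of the upstream aligned block.
#' @param block2_start Start of the downstream aligned block
#'   (`block1_end <= block2_start`).
#' @param n_subblocks Number of sub-alignments each block is cut into.
#' @param query_chrom,target_a,target_b Sequence names.
#' @param seed Optional integer seed (used only to place sub-block cuts).
#' @return List with `paf` (tibble as from [read_paf()]) and
#'   `fusion_point` (the truth, 0-based bp).
#' @export
simulate_fusion_paf <- function(chr1_len, block1_end, block2_start,
                                n_subblocks = 1, query_chrom = "chr1",
                                target_a = "chr4", target_b = "chr9",
                                seed = NULL) {
  stopifnot(block1_end > 0, block1_end <= block2_start,
            block2_start < chr1_len)
  if (!is.null(seed)) set.seed(seed)
  # cuts are evenly spaced with bounded jitter so every sub-alignment
  # keeps a length comparable to the block (no sliver alignments)
  cut_block <- function(from, to, k) {
    L <- to - from
    if (k <= 1 || L < 2 * k) return(cbind(from, to))
    base <- from + round(seq_len(k - 1) * L / k)
    jitter <- round(runif(k - 1, -L / (4 * k), L / (4 * k)))
    cuts <- sort(pmin(to - 1, pmax(from + 1, base + jitter)))
    cbind(c(from, cuts), c(cuts, to))
  }
  up <- cut_block(0L, block1_end, n_subblocks)
  dn <- cut_block(block2_start, chr1_len, n_subblocks)
  mk <- function(seg, target, tlen) {
    tibble::tibble(
      query_name = query_chrom, query_len = as.integer(chr1_len),
      query_start = as.integer(seg[, 1]), query_end = as.integer(seg[, 2]),
      strand = "+", target_name = target, target_len = as.integer(tlen),
      target_start = as.integer(seg[, 1] - min(seg[, 1])),
      target_end = as.integer(seg[, 2] - min(seg[, 1])),
      n_match = as.integer(seg[, 2] - seg[, 1]),
      aln_len = as.integer(seg[, 2] - seg[, 1]), mapq = 60L)
  }
  paf <- dplyr::bind_rows(
    mk(up, target_a, block1_end),
    mk(dn, target_b, chr1_len - block2_start))
  list(paf = paf, fusion_point = floor((block1_end + block2_start) / 2))
}
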