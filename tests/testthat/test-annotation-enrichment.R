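test_that("Fisher exact matches enumeration on canonical tables", {
  expect_equal(fisher_exact_two_sided(0, 5, 5, 0), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(0, 5, 5, 0), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  expect_warning(p <- fisher_exact_two_sided(0, 0, 3, 4), "zero margin")
  expect_equal(p, 1)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  withr::local_seed(19)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab),
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("impact extraction prefers IMPACT= and takes the most severe ANN", {
  info <- c("IMPACT=HIGH;DP=3",
            "ANN=T|missense_variant|MODERATE|g1,T|stop_gained|HIGH|g1",
            "ANN=T|intron_variant|MODIFIER|g2",
            "DP=9", NA)
  expect_equal(pansweep:::impact_from_info(info),
               c("HIGH", "HIGH", "MODIFIER", NA, NA))
})

ann_variants <- function(n, chrom = "chr1", p_high_in = 0.3,
                         p_high_out = 0.1, region_end = 5000L) {
  pos <- sort(sample.int(20000L, n))
  inr <- pos <= region_end
  imp <- ifelse(runif(n) < ifelse(inr, p_high_in, p_high_out),
                "HIGH", "MODIFIER")
  v <- variant_tbl(chrom = rep(chrom, n), pos = pos,
                   ref = rep("A", n), alt = rep("T", n),
                   gt = replicate(n, matrix(0L, 1, 2), simplify = FALSE),
                   samples = "S1")
  v <- classify_variants(v)
  v$impact <- factor(imp, levels = pansweep:::impact_levels)
  v
}

test_that("impact enrichment builds disjoint tables and detects excess", {
  withr::local_seed(29)
  regions <- tibble::tibble(chrom = "chr1", start = 1L, end = 5000L)
  v <- ann_variants(2000, p_high_in = 0.3, p_high_out = 0.1)
  enr <- impact_enrichment(v, regions)
  high <- enr[enr$impact == "HIGH", ]
  expect_gt(high$odds_ratio, 1)
  expect_lt(high$p_value, 0.01)
  # cells partition the stratum
  expect_equal(high$n_in_impact + high$n_in_other +
                 high$n_out_impact + high$n_out_other, 2000)

  # identical in/out composition: OR ~ 1, p = 1 on a balanced toy
  v2 <- variant_tbl(chrom = rep("chr1", 8), pos = c(1:4 * 10L, 6000L + 1:4),
                    ref = rep("A", 8), alt = rep("T", 8),
                    gt = replicate(8, matrix(0L, 1, 2), simplify = FALSE),
                    samples = "S1")
  v2 <- classify_variants(v2)
  v2$impact <- factor(rep(c("HIGH", "HIGH", "MODIFIER", "MODIFIER"), 2),
                      levels = pansweep:::impact_levels)
  enr2 <- impact_enrichment(v2, regions)
  expect_equal(enr2$odds_ratio[enr2$impact == "HIGH"], 1)
  expect_equal(enr2$p_value[enr2$impact == "HIGH"], 1)

  # no variants in regions -> warning and p = 1 by convention
  far <- tibble::tibble(chrom = "chr9", start = 1L, end = 10L)
  expect_warning(enr3 <- impact_enrichment(v2, far), "no variants")
  expect_true(all(enr3$p_value == 1))
})

test_that("enrichment p decreases with sample size at fixed effect", {
  withr::local_seed(37)
  p_small <- impact_enrichment(
    ann_variants(300), tibble::tibble(chrom = "chr1", start = 1L,
                                      end = 5000L))
  p_large <- impact_enrichment(
    ann_variants(5000), tibble::tibble(chrom = "chr1", start = 1L,
                                       end = 5000L))
  expect_lt(p_large$p_value[p_large$impact == "HIGH"],
            p_small$p_value[p_small$impact == "HIGH"])
})

test_that("population aAF counts alt alleles over non-missing ones", {
  gt <- list(rbind(c(1L, 1L), c(1L, 1L), c(0L, 1L), c(0L, 0L), c(0L, 0L)))
  v <- variant_tbl("chr1", 100L, "A", "T", gt, paste0("S", 1:5))
  pops <- tibble::tibble(sample = paste0("S", 1:5), population = "P1")
  expect_equal(population_aaf(v, pops)$aaf, 0.5)

  hom <- variant_tbl("chr1", 5L, "A", "T",
                     list(matrix(1L, 3, 2)), paste0("S", 1:3))
  p3 <- tibble::tibble(sample = paste0("S", 1:3), population = "P")
  expect_equal(population_aaf(hom, p3)$aaf, 1)

  miss <- variant_tbl("chr1", 5L, "A", "T",
                      list(matrix(NA_integer_, 3, 2)), paste0("S", 1:3))
  expect_true(is.na(population_aaf(miss, p3)$aaf))

  # invariant to sample order; complements the ancestral frequency
  shuf <- pops[sample(5), ]
  expect_equal(population_aaf(v, shuf)$aaf, 0.5)
  anc <- mean(gt[[1]] == 0L)
  expect_equal(population_aaf(v, pops)$aaf, 1 - anc)

  # restricted to regions
  regions <- tibble::tibble(chrom = "chr1", start = 500L, end = 900L)
  expect_equal(nrow(population_aaf(v, pops, regions)), 0)
})
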