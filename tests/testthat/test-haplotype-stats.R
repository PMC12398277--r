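hm <- function(rows, positions = NULL, chrom = "chr1") {
  H <- do.call(rbind, rows)
  if (is.null(positions)) positions <- seq_len(ncol(H)) * 100L
  hap_matrix(H, positions, chrom)
}

test_that("EHH matches hand-computed homozygosity fractions", {
  # all four carriers identical everywhere -> EHH 1 at every site
  h <- hm(list(rep(1L, 5), rep(1L, 5), rep(1L, 5), rep(1L, 5)))
  cv <- ehh_curve(h, 3, 1, cutoff = 0, clip = TRUE)
  expect_true(all(cv$ehh == 1))

  # two carriers differing at the next site -> EHH 0 there (C(1,2) = 0)
  h2 <- hm(list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L), c(0L, 1L, 1L)))
  cv2 <- ehh_curve(h2, 1, 1)
  right <- cv2[cv2$arm == "right", ]
  expect_equal(right$ehh[right$site_index == 2], 0)

  # four carriers splitting 2/2 -> EHH = (1 + 1) / 6
  h3 <- hm(list(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L),
                c(0L, 0L), c(0L, 1L)))
  cv3 <- ehh_curve(h3, 1, 1, cutoff = 0)
  expect_equal(cv3$ehh[cv3$arm == "right" & cv3$site_index == 2], 1 / 3)

  expect_error(ehh_curve(hm(list(c(1L, 0L), c(0L, 0L), c(0L, 1L),
                                 c(0L, 0L))), 1, 1), "fewer than 2")
})

test_that("iHH is the trapezoidal area of the decay curve", {
  curve <- tibble::tibble(arm = c("right", "right"), site_index = 1:2,
                          pos = c(0L, 100L), distance_bp = c(0, 100),
                          ehh = c(1, 0.5))
  expect_equal(ihh(curve), 75)

  flat <- tibble::tibble(arm = "right", site_index = 1:11,
                         pos = seq(0L, 1000L, 100L),
                         distance_bp = seq(0, 1000, 100), ehh = rep(1, 11))
  expect_equal(ihh(flat), 1000)

  single <- tibble::tibble(arm = "left", site_index = 1, pos = 0L,
                           distance_bp = 0, ehh = 1)
  expect_equal(ihh(single), 0)
})

test_that("EHH and SL agree exactly with pair-enumeration oracles", {
  withr::local_seed(17)
  for (rep in 1:60) {
    h <- random_hap_matrix(sample(4:6, 1), sample(2:10, 1))
    core <- sample(n_sites(h), 1)
    for (allele in 0:1) {
      if (sum(h$alleles[, core] == allele) < 2) next
      for (dir in c(-1L, 1L)) {
        got <- pansweep:::ehh_arm_cpp(h$alleles, core - 1L, allele, dir,
                                      0, FALSE)
        want <- oracle_ehh_arm(h$alleles, core, allele, dir)
        expect_identical(got$site + 1L, want$site)
        expect_identical(got$ehh, want$ehh)
      }
      expect_identical(sl_statistic(h, core, allele),
                       oracle_sl(h$alleles, core, allele))
    }
  }
})

test_that("EHH is non-increasing away from the core", {
  withr::local_seed(23)
  for (rep in 1:20) {
    h <- random_hap_matrix(6, 10)
    core <- sample(10, 1)
    for (allele in 0:1) {
      if (sum(h$alleles[, core] == allele) < 2) next
      cv <- ehh_curve(h, core, allele, cutoff = 0, clip = TRUE)
      for (a in c("left", "right")) {
        e <- cv$ehh[cv$arm == a][order(cv$distance_bp[cv$arm == a])]
        expect_true(all(diff(e) <= 0))
      }
    }
  }
})

test_that("SL counts shared segments inclusive of the core", {
  # two carriers identical across all 5 sites -> SL = 5
  h <- hm(list(c(1L, 1L, 1L, 0L, 1L), c(1L, 1L, 1L, 0L, 1L),
               c(0L, 0L, 0L, 1L, 0L), c(0L, 1L, 0L, 0L, 0L)))
  expect_equal(sl_statistic(h, 3, 1), 5)

  # identical only at the core -> SL = 1
  h2 <- hm(list(c(0L, 1L, 1L), c(1L, 1L, 0L), c(0L, 0L, 1L),
                c(1L, 0L, 0L)))
  expect_equal(sl_statistic(h2, 2, 1), 1)

  # three carriers -> mean of the three pairwise lengths
  h3 <- hm(list(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L), c(0L, 1L, 1L, 0L),
                c(0L, 0L, 0L, 1L)))
  expect_equal(sl_statistic(h3, 2, 1), oracle_sl(h3$alleles, 2, 1))
  # pairs: (1,2) share sites 1-2 -> 2; (1,3) core only -> 1; (2,3) 2-3 -> 2
  expect_equal(sl_statistic(h3, 2, 1), mean(c(2, 1, 2)))
})

sym_matrix <- function(n_half, n_site, seed) {
  withr::with_seed(seed, {
    A <- matrix(rbinom(n_half * n_site, 1L, 0.5), nrow = n_half)
    hap_matrix(rbind(A, 1L - A), seq_len(n_site) * 50L)
  })
}

test_that("allele-symmetric panels score zero; relabeling negates scores", {
  h <- sym_matrix(4, 9, seed = 5)
  core <- 5
  s_ihs <- scan_haplotypes(h, "ihs", truncation = "clip")
  s_nsl <- scan_haplotypes(h, "nsl")
  expect_equal(s_ihs$raw[core], 0)
  expect_equal(s_nsl$raw[core], 0)

  withr::local_seed(41)
  for (rep in 1:10) {
    h <- random_hap_matrix(6, 8)
    flipped <- hap_matrix(1L - h$alleles, h$positions, h$chrom)
    a <- scan_haplotypes(h, "ihs", truncation = "clip")
    b <- scan_haplotypes(flipped, "ihs", truncation = "clip")
    ok <- a$valid & b$valid
    expect_equal(a$raw[ok], -b$raw[ok], tolerance = 1e-12)
    an <- scan_haplotypes(h, "nsl")
    bn <- scan_haplotypes(flipped, "nsl")
    ok <- an$valid & bn$valid
    expect_equal(an$raw[ok], -bn$raw[ok], tolerance = 1e-12)
  }
})

test_that("scan skips sites outside the MAF band and degenerate classes", {
  h <- hm(list(c(1L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 0L)))
  s <- scan_haplotypes(h, "ihs", maf_floor = 0.3)
  expect_false(s$valid[1])       # DAF 0.25 below floor
  expect_true(is.na(s$raw[1]))
  # single ancestral carrier -> nSL invalid even inside the band
  h2 <- hm(list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, 0L)))
  s2 <- scan_haplotypes(h2, "nsl", maf_floor = 0.2)
  expect_false(s2$valid[1])
})

test_that("implanted sweeps push the core iHS and nSL negative", {
  for (r in 1:3) {
    p <- simulate_panel(80, 800, seed = 50 + r)
    sw <- implant_sweep(p, core_index = 400, halfwidth = 100,
                        template_noise = 0, seed = 60 + r)
    si <- scan_haplotypes(sw, "ihs")
    sn <- scan_haplotypes(sw, "nsl")
    expect_true(si$valid[400])
    expect_lt(si$raw[400], 0)
    expect_lt(sn$raw[400], 0)
    # derived-template hitchhikers score negative as a group
    win <- (400 - 100):(400 + 100)
    tmpl1 <- win[sw$alleles[sw$sweep_carriers[1], win] == 1L]
    expect_lt(mean(si$raw[tmpl1], na.rm = TRUE), -0.5)
  }
})

test_that("standardization centers and scales within DAF bins", {
  scores <- tibble::tibble(chrom = "chr1", site_index = 1:2, pos = c(1L, 2L),
                           daf = c(0.4, 0.45), raw = c(1, 3),
                           metric = "ihs", valid = TRUE)
  out <- standardize_scores(scores, n_daf_bins = 1, min_bin_count = 1)
  expect_equal(out$z, c(-1, 1))

  same <- dplyr::mutate(scores, raw = 2)
  expect_equal(standardize_scores(same, 1, 1)$z, c(0, 0))

  p <- simulate_panel(60, 1500, seed = 77)
  s <- standardize_scores(scan_haplotypes(p, "ihs"))
  mom <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(s, !is.na(z)), bin_index),
    m = mean(z), s2 = mean((z - mean(z))^2), n = dplyr::n())
  nondeg <- mom[mom$s2 > 0, ]
  expect_true(all(abs(nondeg$m) < 1e-9))
  expect_true(all(abs(sqrt(nondeg$s2) - 1) < 1e-9))
  # every merged bin reaches the floor (or a single bin remains)
  expect_true(all(mom$n >= 20) || nrow(mom) == 1)
})
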