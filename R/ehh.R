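#' Extended haplotype homozygosity decay curve
#'
#' EHH at an extension site t is the probability that two randomly chosen
#' haplotypes carrying `allele` at the core are identical over every site
#' from the core out to t: `sum_h C(c_h, 2) / C(n, 2)` over the distinct
#' extended haplotypes h. EHH is 1 at distance 0 and non-increasing
#' outwards. Each arm is truncated after the first site whose EHH drops
#' below `cutoff` (that site is retained as the curve's edge) or at the
#' chromosome end; with `clip = TRUE` the walk continues to the edge.
#'
#' @param hap A [hap_matrix()].
#' @param core_index Core site (1-based column index).
#' @param allele Core allele, 0 (ancestral) or 1 (derived).
#' @param cutoff EHH truncation threshold.
#' @param clip Integrate/extend to the chromosome edge instead of
#'   truncating at the cutoff.
#' @return Tibble with columns `arm` ("left"/"right"), `site_index`,
#'   `pos`, `distance_bp`, `ehh`; attributes `decayed_left`,
#'   `decayed_right` record whether each arm fell below the cutoff.
#' @export
ehh_curve <- function(hap, core_index, allele, cutoff = 0.05,
                      clip = FALSE) {
  stopifnot(inherits(hap, "hap_matrix"),
            core_index >= 1, core_index <= n_sites(hap),
            allele %in% c(0L, 1L))
  core0 <- as.integer(core_index) - 1L
  arms <- lapply(c(left = -1L, right = 1L), function(dir) {
    ehh_arm_cpp(hap$alleles, core0, as.integer(allele), dir, cutoff, clip)
  })
  curve <- dplyr::bind_rows(lapply(names(arms), function(nm) {
    a <- arms[[nm]]
    idx <- a$site + 1L
    tibble::tibble(arm = nm, site_index = idx, pos = hap$positions[idx],
                   distance_bp = abs(hap$positions[idx] -
                                       hap$positions[core_index]),
                   ehh = a$ehh)
  }))
  attr(curve, "decayed_left") <- arms$left$decayed
  attr(curve, "decayed_right") <- arms$right$decayed
  attr(curve, "n_carriers") <- arms$left$n_carriers
  curve
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of the EHH curve against physical distance (bp),
#' summed over the left and right arms. A single-point arm (no possible
#' extension) contributes 0.
#'
#' @param curve A curve from [ehh_curve()].
#' @return The area (bp-scaled homozygosity).
#' @export
ihh <- function(curve) {
  area_arm <- function(d, e) {
    if (length(d) < 2) return(0)
    sum(0.5 * (e[-1] + e[-length(e)]) * abs(diff(d)))
  }
  sum(vapply(split(curve, curve$arm), function(a) {
    a <- a[order(a$distance_bp), ]
    area_arm(a$distance_bp, a$ehh)
  }, numeric(1)))
}

#' Mean pairwise shared-segment length (SL)
#'
#' For every pair of haplotypes carrying `allele` at the core, counts the
#' consecutive sites (inclusive of the core, so L >= 1) over which the
#' pair is identical, extending left and right until the first mismatch
#' or the chromosome edge; returns the mean over pairs. This is the
#' segment-length analogue of iHH measured in segregating sites, the
#' building block of nSL.
#'
#' @inheritParams ehh_curve
#' @return Mean shared length in sites (NA with < 2 carriers).
#' @export
sl_statistic <- function(hap, core_index, allele) {
  stopifnot(inherits(hap, "hap_matrix"), allele %in% c(0L, 1L))
  sl_mean_cpp(hap$alleles, as.integer(core_index) - 1L, as.integer(allele))
}

#' Scan a haplotype panel with iHS or nSL
#'
#' Computes the unstandardized per-site statistic at every site whose
#' derived allele frequency lies inside `(maf_floor, 1 - maf_floor)`:
#' `raw = ln(iHH_ancestral / iHH_derived)` for iHS, and
#' `ln(SL_ancestral / SL_derived)` for nSL. For iHS under the default
#' `truncation = "skip"`, a site is invalid if any of its four EHH arms
#' fails to fall below `cutoff` before the chromosome end, or either iHH
#' is 0 — the convention of the standard scan tools; `"clip"` integrates
#' to the edge instead, which suits short synthetic chromosomes. Negative
#' scores mark unusually long homozygosity around the *derived* allele,
#' the classic hard-sweep signature.
#'
#' @param hap A [hap_matrix()].
#' @param metric `"ihs"` or `"nsl"`.
#' @param maf_floor Minor-allele-frequency floor for scorable sites.
#' @param cutoff EHH truncation threshold (iHS only).
#' @param truncation `"skip"` or `"clip"` (iHS only).
#' @return A `sweep_scan` tibble: `chrom`, `site_index`, `pos`, `daf`,
#'   `raw`, `metric`, `valid`. Sites outside the MAF band are included
#'   with `valid = FALSE`.
#' @seealso [standardize_scores()], [window_means()], [call_peaks()]
#' @examples
#' p <- simulate_panel(40, 300, seed = 7)
#' s <- scan_haplotypes(p, "ihs")
#' dplyr::count(s, valid)
#' @export
scan_haplotypes <- function(hap, metric = c("ihs", "nsl"),
                            maf_floor = 0.05, cutoff = 0.05,
                            truncation = c("skip", "clip")) {
  metric <- match.arg(metric)
  truncation <- match.arg(truncation)
  stopifnot(inherits(hap, "hap_matrix"))
  ns <- n_sites(hap)
  daf <- derived_freq(hap)
  scorable <- daf > maf_floor & daf < 1 - maf_floor
  raw <- rep(NA_real_, ns)
  valid <- rep(FALSE, ns)
  clip <- truncation == "clip"
  for (j in which(scorable)) {
    if (metric == "ihs") {
      r <- ihs_site_cpp(hap$alleles, hap$positions, j - 1L, cutoff, clip)
      raw[j] <- r[["raw"]]
      valid[j] <- r[["valid"]] == 1
    } else {
      sl_a <- sl_mean_cpp(hap$alleles, j - 1L, 0L)
      sl_d <- sl_mean_cpp(hap$alleles, j - 1L, 1L)
      if (!is.na(sl_a) && !is.na(sl_d) && sl_a > 0 && sl_d > 0) {
        raw[j] <- log(sl_a / sl_d)
        valid[j] <- TRUE
      }
    }
  }
  out <- tibble::tibble(chrom = hap$chrom, site_index = seq_len(ns),
                        pos = hap$positions, daf = daf, raw = raw,
                        metric = metric, valid = valid)
  class(out) <- c("sweep_scan", class(out))
  out
}

#' Standardize scan scores within derived-allele-frequency bins
#'
#' Unstandardized iHS/nSL depends strongly on allele frequency, so scores
#' are z-standardized within DAF bins: valid scores are cut into
#' `n_daf_bins` equal-width bins on (0, 1); bins holding fewer than
#' `min_bin_count` scores are merged with their nearest neighbor until
#' every bin meets the floor (or one bin remains); then
#' `z = (raw - bin mean) / bin sd` with the population (divide-by-n)
#' standard deviation. A zero-variance bin yields z = 0. Within every
#' non-degenerate bin the resulting z has mean 0 and sd 1 by
#' construction.
#'
#' @param scores A `sweep_scan` tibble from [scan_haplotypes()].
#' @param n_daf_bins Number of equal-width frequency bins.
#' @param min_bin_count Minimum valid scores per bin before merging.
#' @return `scores` with `bin_index` and `z` columns added (NA for
#'   invalid sites).
#' @export
standardize_scores <- function(scores, n_daf_bins = 50,
                               min_bin_count = 20) {
  assert_columns(scores, c("daf", "raw", "valid"), "scores")
  v <- which(scores$valid & !is.na(scores$raw))
  if (length(v) < 2) abort("need at least 2 valid scores to standardize")
  bin0 <- pmin(pmax(ceiling(scores$daf[v] * n_daf_bins), 1L), n_daf_bins)

  # group contiguous fine bins until every group reaches the floor
  groups <- as.list(seq_len(n_daf_bins))
  counts <- vapply(groups, function(g) sum(bin0 %in% g), numeric(1))
  while (length(groups) > 1 && any(counts < min_bin_count)) {
    i <- which(counts < min_bin_count)
    i <- i[which.min(counts[i])][1]
    j <- if (i == 1) 2L
         else if (i == length(groups)) i - 1L
         else if (counts[i - 1] <= counts[i + 1]) i - 1L
         else i + 1L
    keep <- sort(c(i, j))
    groups[[keep[1]]] <- c(groups[[keep[1]]], groups[[keep[2]]])
    groups[[keep[2]]] <- NULL
    counts <- vapply(groups, function(g) sum(bin0 %in% g), numeric(1))
  }
  lookup <- integer(n_daf_bins)
  for (gi in seq_along(groups)) lookup[groups[[gi]]] <- gi

  grp <- lookup[bin0]
  z <- rep(NA_real_, length(v))
  for (gi in unique(grp)) {
    sel <- grp == gi
    r <- scores$raw[v[sel]]
    mu <- mean(r)
    sd_pop <- sqrt(mean((r - mu)^2))
    z[sel] <- if (sd_pop == 0) 0 else (r - mu) / sd_pop
  }
  scores$bin_index <- NA_integer_
  scores$bin_index[v] <- grp
  scores$z <- NA_real_
  scores$z[v] <- z
  scores
}
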