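# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: EHH/SL are computed by exhaustive pair enumeration, peaks by
# a run-based re-reading of the hysteresis rule, and the Fisher p by
# explicit enumeration of all tables with the observed margins.

# EHH decay curve for one arm by pairwise identity counting. Mirrors the
# package truncation convention: the first site with EHH below `cutoff`
# is kept and ends the walk; EHH = 0 always ends the walk.
oracle_ehh_arm <- function(H, core, allele, dir, cutoff = 0) {
  carriers <- which(H[, core] == allele)
  n <- length(carriers)
  stopifnot(n >= 2)
  den <- choose(n, 2)
  sites <- core
  ehh <- 1
  t <- core + dir
  while (t >= 1 && t <= ncol(H)) {
    pairs <- utils::combn(carriers, 2)
    span <- if (dir > 0) core:t else t:core
    ident <- sum(apply(pairs, 2, function(p) {
      all(H[p[1], span] == H[p[2], span])
    }))
    e <- sum(ident) / den
    sites <- c(sites, t)
    ehh <- c(ehh, e)
    if (e < cutoff || e == 0) break
    t <- t + dir
  }
  list(site = sites, ehh = ehh)
}

# mean pairwise shared-segment length, pair-by-pair scan
oracle_sl <- function(H, core, allele) {
  carriers <- which(H[, core] == allele)
  if (length(carriers) < 2) return(NA_real_)
  pairs <- utils::combn(carriers, 2)
  L <- apply(pairs, 2, function(p) {
    l <- 1
    t <- core - 1
    while (t >= 1 && H[p[1], t] == H[p[2], t]) { l <- l + 1; t <- t - 1 }
    t <- core + 1
    while (t <= ncol(H) && H[p[1], t] == H[p[2], t]) { l <- l + 1; t <- t + 1 }
    l
  })
  sum(L) / choose(length(carriers), 2)
}

# Hysteresis peak oracle: maximal runs of windows with |mean| >= edge
# that contain at least one window with |mean| >= seed. Returns a matrix
# of (start, end) indices into the means vector, or NULL.
oracle_peak_spans <- function(means, seed_thr = 1.5, edge_thr = 0.5) {
  a <- abs(means)
  above <- a >= edge_thr
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  spans <- lapply(keep, function(k) {
    if (any(a[starts[k]:ends[k]] >= seed_thr)) c(starts[k], ends[k])
  })
  spans <- Filter(Negate(is.null), spans)
  if (length(spans) == 0) return(NULL)
  do.call(rbind, spans)
}

# exact two-sided Fisher p by enumerating all tables with the observed
# margins; probabilities via products of choose() (not dhyper)
oracle_fisher <- function(a, b, c, d) {
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# random binary hap matrix guaranteeing >= 2 carriers of each allele at
# the chosen core (returns NULL if the draw cannot satisfy it)
random_hap_matrix <- function(n_hap, n_site, chrom = "chrT") {
  H <- matrix(rbinom(n_hap * n_site, 1L, runif(1, 0.3, 0.7)), nrow = n_hap)
  hap_matrix(H, positions = cumsum(1L + rgeom(n_site, 1 / 500)),
             chrom = chrom)
}

# small random variant table for round-trip tests
random_variant_tbl <- function(n_rec = 5, n_samp = 3) {
  bases <- c("A", "C", "G", "T")
  samples <- paste0("S", seq_len(n_samp))
  gt <- replicate(n_rec, {
    g <- matrix(sample(c(0L, 1L, NA), n_samp * 2, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), ncol = 2)
    g[rowSums(is.na(g)) == 1, ] <- NA_integer_  # whole-genotype missing only
    g
  }, simplify = FALSE)
  ref <- sample(bases, n_rec, replace = TRUE)
  alt <- vapply(seq_len(n_rec), function(i) {
    repeat {
      a <- paste(sample(bases, sample(1:30, 1), replace = TRUE),
                 collapse = "")
      if (a != ref[i]) return(a)
    }
  }, character(1))
  variant_tbl(
    chrom = sample(c("chr1", "chr2"), n_rec, replace = TRUE),
    pos = sort(sample.int(1e5, n_rec)),
    ref = ref, alt = alt, gt = gt, samples = samples)
}

# write a VCF text fixture and return its path
write_vcf_text <- function(lines, path = withr::local_tempfile(
                             fileext = ".vcf", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "0/0", "1|1"), collapse = "\t"),
    paste(c("chr1", "250", "rs2", "AC", "A", "50", "PASS", "DP=10", "GT",
            "./.", "0/1", "0/0"), collapse = "\t"))
}
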