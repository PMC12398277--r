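# shared small fixtures built in code

# one-record table with a given per-sample GQ vector
make_gq_tbl <- function(gqs) {
  n <- length(gqs)
  variant_tbl("chr1", 100L, "A", "G",
              gt = list(matrix(c(0L, 1L), n, 2, byrow = TRUE)),
              samples = paste0("S", seq_len(n)),
              gq = list(as.integer(gqs)))
}

# one biallelic record with an exact alt-allele count / missing count
maf_tbl <- function(n_alt, n_dip = 10, n_missing = 0) {
  g <- matrix(0L, n_dip, 2)
  if (n_alt > 0) g[seq_len(ceiling(n_alt / 2)), ] <-
      matrix(c(rep(1L, n_alt), rep(0L, 2 * ceiling(n_alt / 2) - n_alt)),
             ncol = 2, byrow = TRUE)
  if (n_missing > 0) g[(n_dip - n_missing + 1):n_dip, ] <- NA_integer_
  variant_tbl("chr1", 50L, "A", "G", gt = list(g),
              samples = paste0("S", seq_len(n_dip)))
}

# score tables / window tracks with prescribed values
fake_scores <- function(z, chrom = "chr1") {
  n <- length(z)
  tibble::tibble(chrom = chrom, site_index = seq_len(n),
                 pos = seq_len(n) * 10L, daf = 0.5, raw = z,
                 metric = "ihs", valid = !is.na(z), z = z)
}

fake_windows <- function(means, chrom = "chr1") {
  n <- length(means)
  out <- tibble::tibble(chrom = chrom, window_index = seq_len(n) - 1L,
                        first_site_index = (seq_len(n) - 1L) * 100L + 1L,
                        last_site_index = seq_len(n) * 100L,
                        first_pos = (seq_len(n) - 1L) * 1000L + 1L,
                        last_pos = seq_len(n) * 1000L,
                        mean_z = means, n_sites = 100L)
  class(out) <- c("sweep_windows", class(out))
  out
}
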