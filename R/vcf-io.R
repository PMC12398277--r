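#' Read a VCF file into a variant table
#'
#' Parses a VCF v4.x text file (plain or gzip) into a [variant_tbl()].
#' Multiallelic records are preserved as-is (comma-separated `alt`) and can
#' be split afterwards with [split_multiallelic()]. Per-sample GT and GQ
#' fields are extracted; all other FORMAT fields are ignored. Symbolic ALT
#' alleles (`<DEL>`, `<INS>`, ...) are rejected: the pangenome-style VCFs
#' this package targets carry explicit sequences.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return A [variant_tbl()] with records in file order.
#' @seealso [write_vcf()], [split_multiallelic()], [classify_variants()]
#' @export
read_vcf <- function(path) {
  lines <- readr::read_lines(path)
  is_meta <- startsWith(lines, "##")
  header_idx <- which(startsWith(lines, "#CHROM"))
  if (length(header_idx) != 1) {
    abort("malformed VCF: expected exactly one #CHROM header line")
  }
  header <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  if (length(header) < 8) {
    abort(sprintf("malformed VCF header at line %d: fewer than 8 columns",
                  header_idx))
  }
  samples <- if (length(header) > 9) header[-(1:9)] else character(0)
  ns <- length(samples)

  body_idx <- which(!is_meta & !startsWith(lines, "#") & nzchar(lines))
  body_idx <- body_idx[body_idx > header_idx]

  n <- length(body_idx)
  chrom <- character(n); pos <- integer(n); id <- character(n)
  ref <- character(n); alt <- character(n); qual <- character(n)
  filter <- character(n); info <- character(n)
  gt <- vector("list", n); phased <- vector("list", n); gq <- vector("list", n)

  min_cols <- if (ns > 0) 9 + ns else 8
  for (k in seq_len(n)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < min_cols) {
      abort(sprintf("malformed VCF record at line %d: %d column(s), expected >= %d",
                    ln, length(f), min_cols))
    }
    p <- suppressWarnings(as.integer(f[2]))
    if (is.na(p)) {
      abort(sprintf("malformed VCF record at line %d: non-integer POS '%s'",
                    ln, f[2]))
    }
    if (grepl("^<", f[5])) {
      abort(sprintf("symbolic ALT allele '%s' at line %d is not supported",
                    f[5], ln))
    }
    chrom[k] <- f[1]; pos[k] <- p; id[k] <- f[3]
    ref[k] <- f[4]; alt[k] <- f[5]; qual[k] <- f[6]
    filter[k] <- f[7]; info[k] <- f[8]

    if (ns > 0) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      gt_i <- match("GT", fmt)
      gq_i <- match("GQ", fmt)
      if (is.na(gt_i)) {
        abort(sprintf("malformed VCF record at line %d: FORMAT lacks GT", ln))
      }
      calls <- strsplit(f[10:(9 + ns)], ":", fixed = TRUE)
      gstr <- vapply(calls, `[`, character(1), gt_i)
      g <- matrix(NA_integer_, nrow = ns, ncol = 2)
      ph <- grepl("|", gstr, fixed = TRUE)
      al <- strsplit(gstr, "[/|]")
      for (s in seq_len(ns)) {
        a <- al[[s]]
        a[a == "."] <- NA
        a <- suppressWarnings(as.integer(a))
        if (length(a) >= 1) g[s, 1] <- a[1]
        if (length(a) >= 2) g[s, 2] <- a[2]
      }
      gt[[k]] <- g; phased[[k]] <- ph
      if (!is.na(gq_i)) {
        q <- vapply(calls, function(x) {
          if (length(x) >= gq_i) x[gq_i] else "."
        }, character(1))
        q[q == "."] <- NA
        gq[[k]] <- suppressWarnings(as.integer(q))
      }
    } else {
      gt[[k]] <- matrix(NA_integer_, nrow = 0, ncol = 2)
      phased[[k]] <- logical(0)
    }
  }

  na_dot <- function(x) ifelse(x == ".", NA_character_, x)
  variant_tbl(chrom, pos, ref, alt, gt, samples, id = id, qual = qual,
              filter = filter, info = na_dot(info), phased = phased, gq = gq)
}

#' Write a variant table to a VCF file
#'
#' Emits a minimal VCF v4.2: `##INFO` declarations for every key observed
#' in the `info` column (`SUPP_VEC` as `Type=String`), a `##FORMAT` line
#' for GT (and GQ when any record carries it) and one `##contig` line per
#' chromosome. Genotype separators follow the stored `phased` flags.
#'
#' @param x A [variant_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  samples <- vcf_samples(x)
  ns <- length(samples)
  inf <- x$info[!is.na(x$info)]
  keys <- unique(unlist(regmatches(
    inf, gregexpr("(?:^|;)([A-Za-z_][A-Za-z0-9_.]*)=", inf)
  )))
  keys <- gsub("[;=]", "", keys)
  hdr <- c("##fileformat=VCFv4.2")
  for (k in keys) {
    hdr <- c(hdr, sprintf(
      '##INFO=<ID=%s,Number=%s,Type=String,Description="%s">',
      k, if (k == "SUPP_VEC") "1" else ".", k))
  }
  has_gq <- any(!vapply(x$gq, is.null, logical(1)))
  if (ns > 0) {
    hdr <- c(hdr, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    if (has_gq) {
      hdr <- c(hdr,
        '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
    }
  }
  for (ch in unique(x$chrom)) hdr <- c(hdr, sprintf("##contig=<ID=%s>", ch))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (ns > 0) cols <- c(cols, "FORMAT", samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))

  dot <- function(v) ifelse(is.na(v) | v == "", ".", v)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    fields <- c(x$chrom[i], x$pos[i], dot(x$id[i]), x$ref[i], x$alt[i],
                dot(x$qual[i]), dot(x$filter[i]), dot(x$info[i]))
    if (ns > 0) {
      g <- x$gt[[i]]
      sep <- ifelse(x$phased[[i]], "|", "/")
      a1 <- ifelse(is.na(g[, 1]), ".", g[, 1])
      a2 <- ifelse(is.na(g[, 2]), ".", g[, 2])
      gstr <- paste0(a1, sep, a2)
      q <- x$gq[[i]]
      if (!is.null(q)) {
        fields <- c(fields, "GT:GQ",
                    paste0(gstr, ":", ifelse(is.na(q), ".", q)))
      } else {
        fields <- c(fields, "GT", gstr)
      }
    }
    paste(fields, collapse = "\t")
  }, character(1))
  readr::write_lines(c(hdr, rows), path)
  invisible(path)
}

# trim shared trailing then leading bases, keeping >= 1 base on each side
trim_alleles <- function(ref, alt, pos) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(ref = ref, alt = alt, pos = pos)
}

#' Split multiallelic records into biallelic ones
#'
#' Each record listing k ALT alleles becomes k biallelic records. For the
#' record representing alt allele k, sample alleles equal to k are recoded
#' to 1, reference alleles stay 0, and alleles belonging to a *different*
#' alt become missing — the recoding does not invent genotypes it cannot
#' represent. Shared leading/trailing bases between REF and the retained
#' ALT are trimmed (trailing first, then leading with a position shift).
#' Already-biallelic records pass through unchanged.
#'
#' @param x A [variant_tbl()].
#' @return A [variant_tbl()] of biallelic records.
#' @export
split_multiallelic <- function(x) {
  samples <- vcf_samples(x)
  pieces <- lapply(seq_len(nrow(x)), function(i) {
    alts <- strsplit(x$alt[i], ",", fixed = TRUE)[[1]]
    if (any(alts == x$ref[i])) {
      abort(sprintf("record %s:%d has ALT identical to REF", x$chrom[i],
                    x$pos[i]))
    }
    if (length(alts) == 1) return(x[i, , drop = FALSE])
    g0 <- x$gt[[i]]
    out <- lapply(seq_along(alts), function(k) {
      tr <- trim_alleles(x$ref[i], alts[k], x$pos[i])
      g <- g0
      g[g0 == k] <- 1L
      g[g0 != 0L & g0 != k] <- NA_integer_
      row <- x[i, , drop = FALSE]
      row$ref <- tr$ref; row$alt <- tr$alt; row$pos <- tr$pos
      row$gt <- list(g)
      row
    })
    dplyr::bind_rows(out)
  })
  new_variant_tbl(dplyr::bind_rows(pieces), samples)
}

#' Classify biallelic variants as SNV, indel or structural variant
#'
#' Adds `length_delta` (`nchar(alt) - nchar(ref)`, bp) and `variant_class`
#' columns. A variant is an SNV when both alleles have length 1, a
#' structural variant (`SV_INS`/`SV_DEL`) when `|length_delta| >= sv_min`,
#' and an `INDEL` otherwise. The default 50 bp threshold is the community
#' convention separating indels from SVs.
#'
#' @param x A [variant_tbl()] of biallelic records.
#' @param sv_min Minimum `|length_delta|` (bp) for the SV classes.
#' @return `x` with `length_delta` and `variant_class` columns added.
#' @export
classify_variants <- function(x, sv_min = 50L) {
  if (any(grepl(",", x$alt, fixed = TRUE))) {
    abort("multiallelic records present; run split_multiallelic() first")
  }
  if (any(grepl("^<", x$alt))) {
    abort("symbolic ALT alleles are not supported")
  }
  ld <- nchar(x$alt) - nchar(x$ref)
  cls <- dplyr::case_when(
    nchar(x$ref) == 1L & nchar(x$alt) == 1L ~ "SNV",
    ld >= sv_min ~ "SV_INS",
    ld <= -sv_min ~ "SV_DEL",
    TRUE ~ "INDEL"
  )
  x$length_delta <- as.integer(ld)
  x$variant_class <- cls
  x
}
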