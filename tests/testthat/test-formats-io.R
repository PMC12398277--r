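test_that("read_vcf parses records, samples and missing genotypes", {
  path <- write_vcf_text(toy_vcf_lines())
  v <- read_vcf(path)
  expect_s3_class(v, "variant_tbl")
  expect_equal(nrow(v), 2)
  expect_equal(vcf_samples(v), c("S1", "S2", "S3"))
  expect_equal(v$pos, c(100L, 250L))
  expect_equal(v$gt[[1]][1, ], c(0L, 1L))
  expect_true(v$phased[[1]][3])             # 1|1
  expect_true(all(is.na(v$gt[[2]][1, ])))   # ./.
  expect_equal(v$info[2], "DP=10")
})

test_that("malformed VCF records raise line-numbered parse errors", {
  lines <- toy_vcf_lines()
  lines[5] <- paste(strsplit(lines[5], "\t")[[1]][1:7], collapse = "\t")
  expect_error(read_vcf(write_vcf_text(lines)), "line 5")
  lines <- toy_vcf_lines()
  lines[6] <- sub("250", "notanumber", lines[6])
  expect_error(read_vcf(write_vcf_text(lines)), "line 6.*POS")
  lines <- toy_vcf_lines()
  lines[5] <- sub("\tG\t", "\t<INS>\t", lines[5])
  expect_error(read_vcf(write_vcf_text(lines)), "symbolic")
})

test_that("write_vcf/read_vcf round-trips random toy tables", {
  withr::local_seed(42)
  for (rep in 1:20) {
    v <- random_variant_tbl(n_rec = sample(1:8, 1), n_samp = sample(1:4, 1))
    path <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(v, path)
    v2 <- read_vcf(path)
    expect_equal(v2$chrom, v$chrom)
    expect_equal(v2$pos, v$pos)
    expect_equal(v2$ref, v$ref)
    expect_equal(v2$alt, v$alt)
    expect_equal(v2$gt, v$gt)
    expect_equal(vcf_samples(v2), vcf_samples(v))
  }
})

test_that("written VCFs agree with an independent VCF reader", {
  withr::local_seed(7)
  v <- random_variant_tbl(n_rec = 6, n_samp = 3)
  v <- compute_support_vectors(v)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path)
  ext <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(as.integer(ext@fix[, "POS"]), v$pos)
  expect_equal(unname(ext@fix[, "REF"]), v$ref)
  expect_equal(unname(ext@fix[, "ALT"]), v$alt)
  expect_equal(unname(vcfR::extract.info(ext, "SUPP_VEC")),
               unname(pansweep:::info_get(v$info, "SUPP_VEC")))
})

test_that("split_multiallelic recodes genotypes per retained alt", {
  gt <- list(rbind(c(1L, 2L), c(0L, 2L), c(0L, 0L)))
  v <- variant_tbl("chr1", 500L, "A", "G,T", gt, c("S1", "S2", "S3"))
  out <- split_multiallelic(v)
  expect_equal(nrow(out), 2)
  expect_equal(out$alt, c("G", "T"))
  # alt G: allele 1 -> 1, allele 2 (other alt) -> missing
  expect_equal(out$gt[[1]][1, ], c(1L, NA))
  expect_equal(out$gt[[1]][2, ], c(0L, NA))
  expect_equal(out$gt[[1]][3, ], c(0L, 0L))
  # alt T: allele 2 -> 1, allele 1 -> missing
  expect_equal(out$gt[[2]][1, ], c(NA, 1L))
  expect_equal(out$gt[[2]][2, ], c(0L, 1L))
})

test_that("split_multiallelic trims shared bases and rejects ref==alt", {
  gt <- list(rbind(c(0L, 1L), c(0L, 2L)))
  v <- variant_tbl("chr1", 100L, "ATT", "GTT,ACT", gt, c("S1", "S2"))
  out <- split_multiallelic(v)
  expect_equal(out$ref, c("A", "T"))   # ATT>GTT trims to A>G at 100
  expect_equal(out$alt, c("G", "C"))   # ATT>ACT trims to T>C at 101
  expect_equal(out$pos, c(100L, 101L))

  bad <- variant_tbl("chr1", 1L, "AC", "AC",
                     list(rbind(c(0L, 1L))), "S1")
  expect_error(split_multiallelic(bad), "identical")

  bi <- random_variant_tbl(3, 2)
  expect_equal(split_multiallelic(bi)$gt, bi$gt)
})

test_that("variant classification follows the 50 bp SV boundary", {
  v <- variant_tbl(
    chrom = rep("chr1", 4), pos = c(10L, 20L, 30L, 40L),
    ref = c("A", "A", "A", paste0("A", strrep("C", 50))),
    alt = c("G", paste0("A", strrep("T", 49)),
            paste0("A", strrep("T", 50)), "A"),
    gt = replicate(4, matrix(0L, 1, 2), simplify = FALSE), samples = "S1")
  out <- classify_variants(v)
  expect_equal(out$variant_class, c("SNV", "INDEL", "SV_INS", "SV_DEL"))
  expect_equal(out$length_delta, c(0L, 49L, 50L, -50L))
  # every biallelic record maps to exactly one class, SV iff |delta| >= 50
  withr::local_seed(3)
  r <- classify_variants(random_variant_tbl(50, 1))
  expect_true(all(r$variant_class %in% c("SNV", "INDEL", "SV_INS", "SV_DEL")))
  expect_equal(abs(r$length_delta) >= 50,
               r$variant_class %in% c("SV_INS", "SV_DEL"))
})

test_that("read_paf parses mandatory columns and validates coordinates", {
  line <- paste(c("chr1", "1000", "0", "500", "+", "chr4", "600", "50",
                  "550", "450", "500", "60", "tp:A:P"), collapse = "\t")
  p <- read_paf(write_vcf_text(line))
  expect_equal(nrow(p), 1)
  expect_equal(p$query_end, 500L)
  expect_equal(p$target_name, "chr4")

  bad <- paste(c("chr1", "1000", "600", "500", "+", "chr4", "600", "50",
                 "550", "450", "500", "60"), collapse = "\t")
  expect_error(read_paf(write_vcf_text(bad)), "0 <= start < end")
  expect_equal(nrow(read_paf(write_vcf_text(character(0)))), 0)
})

test_that("read_gff3_genes keeps gene rows only and validates them", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gene1;Name=G1",
           "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=gene1",
           "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=t1",
           "chr2\tsrc\tgene\t10\t90\t.\t-\t.\tgene=gene2")
  g <- read_gff3_genes(write_vcf_text(gff))
  expect_equal(g$gene_id, c("gene1", "gene2"))
  expect_equal(g$chrom, c("chr1", "chr2"))

  bad <- c("chr1\tsrc\tgene\t500\t100\t.\t+\t.\tID=g")
  expect_error(read_gff3_genes(write_vcf_text(bad)), "coordinates")
  noid <- c("chr1\tsrc\tgene\t1\t10\t.\t+\t.\tNote=x")
  expect_warning(out <- read_gff3_genes(write_vcf_text(noid)), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("write_bed converts to 0-based half-open, merges and sorts", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(tibble::tibble(chrom = "1", start = 101L, end = 200L), path)
  expect_equal(readLines(path), "1\t100\t200")

  write_bed(tibble::tibble(chrom = c("1", "1"), start = c(5L, 1L),
                           end = c(20L, 10L)), path)
  expect_equal(readLines(path), "1\t0\t20")

  write_bed(tibble::tibble(chrom = character(), start = integer(),
                           end = integer()), path)
  expect_equal(length(readLines(path)), 0)

  # property: output intervals pairwise disjoint and sorted
  withr::local_seed(9)
  x <- tibble::tibble(chrom = sample(c("a", "b"), 30, TRUE),
                      start = sample.int(500, 30))
  x$end <- x$start + sample.int(50, 30)
  write_bed(x, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         show_col_types = FALSE)
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, ]
    expect_true(all(diff(b$start) > 0))
    expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})
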