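test_that("annotating the source VCF with its own archive recovers every value", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  s <- annotate_vcf(fx$vcf, fx$zip, out_path = NULL)
  rec <- attr(s, "records")
  expect_identical(s$variants_read, nrow(fx$truth))
  expect_identical(s$variants_written, nrow(fx$truth))

  orc <- oracle_annotate(fx$truth, fx$truth, test_configs())
  expect_true(all(orc$found))
  expect_identical(rec$g_ac, orc$g_ac)
  expect_identical(rec$g_csq, orc$g_csq)
  # float fidelity: quantization is the only loss
  src <- ifelse(is.na(fx$truth$AF), -1, fx$truth$AF)
  real <- src != -1
  expect_true(all(abs(rec$g_af[real] - src[real]) <= 0.5 / 1e6))
  expect_identical(rec$g_af[!real], rep(-1, sum(!real)))
})

test_that("variants absent from the archive receive the configured defaults", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  qv <- tempfile(fileext = ".vcf")
  # positions far outside the archive's span, plus a symbolic and multi-allelic ALT
  write_query_vcf(qv, chrom = rep("1", 4), pos = c(9e6, 9e6 + 5, 9e6 + 9, 9e6 + 12),
                  ref = c("A", "T", "G", "C"), alt = c("C", "<DEL>", "A,T", "CTTTTT"))
  s <- annotate_vcf(qv, fx$zip, out_path = NULL)
  rec <- attr(s, "records")
  expect_identical(rec$g_af, rep(-1, 4))
  expect_identical(rec$g_ac, rep(-1, 4))
  expect_identical(rec$g_csq, rep(".", 4))
  expect_identical(s$variants_written, 4L)  # unannotated records still pass through
})

test_that("filtered output equals the brute-force oracle for all three filter forms", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  filters <- c("g_af < 0.01",
               "g_ac / (g_ac + 2) < 0.9",
               "g_af > 0.2 || g_ac > 30 || g_csq == 'stop_gained'")
  for (f in filters) {
    s <- annotate_vcf(fx$vcf, fx$zip, filter = f, out_path = NULL)
    orc <- oracle_annotate(fx$truth, fx$truth, test_configs(), filter = f)
    rec <- attr(s, "records")
    expect_identical(rec$pass, orc$pass, label = f)
    expect_identical(s$variants_written, sum(orc$pass), label = f)
  }
})

test_that("filter referencing an unknown alias fails before any record is processed", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  expect_error(annotate_vcf(fx$vcf, fx$zip, filter = "nope < 1", out_path = NULL),
               "unknown field 'nope'")
})

test_that("two archives merge their field sets; a duplicated alias is overwritten", {
  dirn <- tempdir()
  v1 <- file.path(dirn, "arch_a.vcf")
  v2 <- file.path(dirn, "arch_b.vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               '##INFO=<ID=AC,Number=1,Type=Integer,Description="x">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\t.\tA\tC\t.\t.\tAC=1",
               "1\t200\t.\tG\tT\t.\t.\tAC=2"), v1)
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               '##INFO=<ID=AC,Number=1,Type=Integer,Description="x">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t200\t.\tG\tT\t.\t.\tAC=7"), v2)
  za <- file.path(dirn, "a.zip")
  zb <- file.path(dirn, "b.zip")
  build_archive(v1, '[{"field":"AC","alias":"a_ac"}]', za)
  build_archive(v2, '[{"field":"AC","alias":"b_ac"}]', zb)

  qv <- file.path(dirn, "q.vcf")
  write_query_vcf(qv, "1", c(100, 200), c("A", "G"), c("C", "T"))
  s <- annotate_vcf(qv, c(za, zb), out_path = NULL)
  rec <- attr(s, "records")
  expect_identical(rec$a_ac, c(1, 2))   # disjoint aliases: both field sets present
  expect_identical(rec$b_ac, c(-1, 7))

  # same alias in both: the later archive wins, with a warning
  zdup <- file.path(dirn, "dup.zip")
  build_archive(v2, '[{"field":"AC","alias":"a_ac"}]', zdup)
  expect_warning(s2 <- annotate_vcf(qv, c(za, zdup), out_path = NULL), "later archive")
  rec2 <- attr(s2, "records")
  expect_identical(rec2$a_ac, c(-1, 7))
})

test_that("single-slot bin cache loads once per (chrom, bin) run-length", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  ar <- open_archive(fx$zip)
  b <- bin_of(fx$truth$pos)
  # two consecutive queries in one bin: one read
  load_bin_if_needed(ar, fx$truth$chrom[1], b$bin[1])
  load_bin_if_needed(ar, fx$truth$chrom[1], b$bin[1])
  expect_identical(ar$n_bin_loads, 1L)
  # alternating bins A,B,A,B: four reads through a fresh single-slot cache
  ar_alt <- open_archive(fx$zip)
  load_bin_if_needed(ar_alt, "1", 0)
  load_bin_if_needed(ar_alt, "1", 1)
  load_bin_if_needed(ar_alt, "1", 0)
  load_bin_if_needed(ar_alt, "1", 1)
  expect_identical(ar_alt$n_bin_loads, 4L)
  # a full sorted pass loads each (chrom,bin) run exactly once
  ar2 <- open_archive(fx$zip)
  s <- annotate_vcf(fx$vcf, list(ar2), out_path = NULL)
  key <- paste(norm_chrom(fx$truth$chrom), b$bin)
  expect_identical(ar2$n_bin_loads, length(rle(key)$values))
})

test_that("query order does not change the annotations, only the load count", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  set.seed(99)
  perm <- sample(nrow(fx$truth))
  qv <- tempfile(fileext = ".vcf")
  shuf <- fx$truth[perm, ]
  write_query_vcf(qv, shuf$chrom, shuf$pos, shuf$ref, shuf$alt)
  s <- annotate_vcf(qv, fx$zip, out_path = NULL)
  rec <- attr(s, "records")
  sorted <- attr(annotate_vcf(fx$vcf, fx$zip, out_path = NULL), "records")
  expect_identical(rec$g_ac, sorted$g_ac[perm])
  expect_identical(rec$g_af, sorted$g_af[perm])
  expect_identical(rec$g_csq, sorted$g_csq[perm])
})

test_that("annotated VCF output is well-formed and carries the new INFO headers", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  out <- tempfile(fileext = ".vcf")
  annotate_vcf(fx$vcf, fx$zip, filter = "g_af < 0.01", out_path = out)
  v <- read_vcf(out)
  expect_identical(unname(v$info_types[c("g_af", "g_ac", "g_csq")]),
                   c("Float", "Integer", "String"))
  vals <- as.numeric(info_extract(v$records$info, "g_af"))
  expect_true(all(vals < 0.01))
  # surviving set is exactly the subset on which the filter is true
  unfiltered <- attr(annotate_vcf(fx$vcf, fx$zip, out_path = NULL), "records")
  keep <- unfiltered[unfiltered$g_af < 0.01, ]
  expect_identical(nrow(v$records), nrow(keep))
})

test_that("BCF output round-trips through bcftools", {
  fx <- make_pipeline_fixture(seed = 7, n = 2000)
  out <- tempfile(fileext = ".bcf")
  s <- annotate_vcf(fx$vcf, fx$zip, out_path = out)
  v <- read_vcf(out)
  expect_identical(nrow(v$records), s$variants_written)
})
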