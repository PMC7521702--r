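test_that("VCF ingestion keeps SNVs, drops indels and hom-ref records", {
  recs <- c(
    vcf_rec("chr1", 100, "A", "G", "0/1", 50, "30,20"),
    vcf_rec("chr1", 200, "C", "T", "1/1", 40, "0,40"),
    vcf_rec("chr1", 300, "G", "GA", "0/1", 30, "15,15"),   # insertion
    vcf_rec("chr1", 400, "TTA", "T", "0/1", 30, "15,15"),  # deletion
    vcf_rec("chr1", 500, "T", "A", "1|0", 60, "33,27"),
    vcf_rec("chr1", 600, "A", "C", "0/0", 50, "50,0"),     # hom-ref
    vcf_rec("chr1", 700, "G", "T", "./.", 50, NULL),       # no-call
    vcf_rec("chr1", 800, "C", "A", "0/1", 44, "22,22"),
    vcf_rec("chr1", 900, "A", "T", "0/1", 20, "9,11"),
    vcf_rec("chr2", 100, "G", "C", "1/1", 80, "2,78"))
  path <- write_toy_vcf(recs)
  cs <- suppressMessages(read_vcf(path, method = "WGS"))
  expect_s3_class(cs, "callset")
  expect_equal(nrow(cs$calls), 6)   # 10 records - 2 indels - homref - nocall
  expect_equal(cs$calls$genotype[cs$calls$pos == 100 &
                                   cs$calls$chrom == "chr1"], "het")
  r100 <- cs$calls[cs$calls$pos == 100 & cs$calls$chrom == "chr1", ]
  expect_equal(r100$ref_reads, 30L)
  expect_equal(r100$alt_reads, 20L)
  expect_equal(r100$depth, 50L)
  # phased 1|0 maps to het
  expect_equal(cs$calls$genotype[cs$calls$pos == 500], "het")
  expect_equal(cs$calls$genotype[cs$calls$chrom == "chr2"], "hom_alt")
})

test_that("multi-allelic records decompose into biallelic het calls", {
  path <- write_toy_vcf(vcf_rec("chr1", 100, "A", "G,T", "1/2", 60,
                                "5,30,25"))
  cs <- suppressMessages(read_vcf(path))
  expect_equal(nrow(cs$calls), 2)
  expect_setequal(cs$calls$alt, c("G", "T"))
  expect_true(all(cs$calls$genotype == "het"))
  expect_equal(cs$calls$alt_reads[cs$calls$alt == "G"], 30L)
  expect_equal(cs$calls$alt_reads[cs$calls$alt == "T"], 25L)
  expect_true(all(cs$calls$ref_reads == 5L))
})

test_that("a VCF without genotypes is rejected; missing AD is tolerated", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("chr1", 100, ".", "A", "G", ".", "PASS", ".", "DP", "50",
          sep = "\t")), path)
  expect_error(suppressWarnings(read_vcf(path)), "GT")

  # record with GT but no DP/AD: retained, fields unknown, never HQFE
  path2 <- write_toy_vcf(vcf_rec("chr1", 100, "A", "G", "0/1"))
  cs <- suppressMessages(read_vcf(path2))
  expect_equal(nrow(cs$calls), 1)
  expect_true(is.na(cs$calls$depth))
  expect_false(hqfe_filter(cs$calls, "WGS", quality_criteria()))
})

test_that("FILTER screening is off by default and opt-in", {
  recs <- c(vcf_rec("chr1", 100, "A", "G", "0/1", 50, "25,25"),
            vcf_rec("chr1", 200, "C", "T", "0/1", 50, "25,25",
                    filter = "LowQual"))
  path <- write_toy_vcf(recs)
  expect_equal(nrow(suppressMessages(read_vcf(path))$calls), 2)
  expect_equal(nrow(suppressMessages(
    read_vcf(path, pass_only = TRUE))$calls), 1)
})

test_that("VCF write/read round trip is the identity on retained fields", {
  set.seed(5)
  cs <- make_callset(pos = c(5L, 40L, 77L, 120L),
                     genotype = c("het", "hom_alt", "het", "hom_alt"),
                     depth = c(30L, 44L, 12L, 90L),
                     alt_reads = c(14L, 44L, 5L, 88L),
                     ref_reads = c(16L, 0L, 7L, 2L))
  path <- tempfile(fileext = ".vcf")
  write_vcf(cs, path)
  cs2 <- suppressMessages(read_vcf(path, method = cs$method))
  expect_equal(cs2$calls, cs$calls)
  expect_equal(cs2$sample, cs$sample)
})

test_that("allele balance is the minor-allele fraction, bounded by 0.5", {
  expect_equal(allele_balance(60, 40), 0.4)
  expect_equal(allele_balance(0, 80), 0)
  expect_equal(allele_balance(2, 98), 0.02)
  # symmetry in ref/alt and bound
  set.seed(9)
  r <- sample.int(100, 50)
  a <- sample.int(100, 50)
  expect_equal(allele_balance(r, a), allele_balance(a, r))
  expect_true(all(allele_balance(r, a) <= 0.5))
  expect_true(is.na(allele_balance(0, 0)))
  expect_true(is.na(allele_balance(NA, 10)))
})

test_that("restriction keeps exactly the calls inside the region", {
  cs <- make_callset(pos = c(5L, 11L, 19L, 25L))
  r <- region_set("chr1", 10, 20)
  res <- restrict_calls(cs, r)
  expect_equal(res$calls$pos, c(11L, 19L))
  # idempotent, and an empty region empties the callset
  expect_equal(restrict_calls(res, r)$calls, res$calls)
  expect_equal(nrow(restrict_calls(cs, region_set())$calls), 0)
  # agreement with the per-call membership oracle
  set.seed(21)
  for (rep in 1:10) {
    rr <- normalize_regions(random_intervals(6, chroms = "chr1",
                                             max_pos = 50))
    cs2 <- make_callset(pos = sample.int(60, 12))
    keep <- paste("chr1", cs2$calls$pos - 1, sep = ":") %in% base_set(rr)
    expect_equal(restrict_calls(cs2, rr)$calls$pos, cs2$calls$pos[keep])
  }
})

test_that("callset validation enforces the call invariants", {
  expect_error(make_callset(1L, ref = "A", alt = "A"),
               "single-nucleotide")
  expect_error(callset(make_calls(c(10L, 10L)), "M", "S"), "duplicate")
  bad <- make_calls(1L, depth = 10L, ref_reads = 8L, alt_reads = 5L)
  expect_error(callset(bad, "M", "S"), "depth")
})
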