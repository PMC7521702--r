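test_that("depth summaries match direct computation", {
  tr <- depth_track(c(5, 15, 15, 15), region_set("chr1", 0, 4))
  s <- summarize_depth(tr, cutoff = 10)
  expect_equal(s$mean, 12.5)
  expect_equal(s$median, 15)
  expect_equal(s$low_fraction, 0.25)

  tr2 <- depth_track(rep(50, 30), region_set("chr1", 0, 30))
  expect_equal(summarize_depth(tr2, cutoff = 40)$low_fraction, 0)

  set.seed(4)
  d <- rpois(1000, 30)
  tr3 <- depth_track(d, region_set("chr1", 0, 1000))
  s3 <- summarize_depth(tr3, cutoff = 25)
  expect_equal(s3$mean, mean(d))
  expect_equal(s3$median, median(d))
  expect_equal(s3$low_fraction, mean(d < 25))
  expect_equal(sum(s3$histogram$count), 1000)
  expect_equal(s3$histogram$count[s3$histogram$depth == 30], sum(d == 30))

  expect_error(summarize_depth(depth_track(numeric(), region_set()), 10),
               "empty")
})

test_that("low fraction is monotone in the cutoff", {
  set.seed(8)
  tr <- depth_track(rpois(500, 20), region_set("chr1", 0, 500))
  lf <- vapply(1:60, function(k) summarize_depth(tr, k)$low_fraction,
               numeric(1))
  expect_true(all(diff(lf) >= 0))
})

test_that("per-gene low-coverage fractions count bases below cutoff", {
  # gene spanning 10 bases, 3 below cutoff
  tr <- depth_track(c(rep(50, 7), rep(5, 3)), region_set("chr1", 0, 10))
  genes <- gene_models("G1", region_set("chr1", 0, 10))
  pg <- per_gene_low_fraction(tr, genes, cutoff = 10)
  expect_equal(pg$low_fraction, 0.30)

  # CTF1-like gene: 63% of its bases below 40x flags it at the 10% level
  n <- 200
  d <- c(rep(10, 126), rep(100, 74))
  tr2 <- depth_track(d, region_set("chr1", 0, n))
  genes2 <- gene_models("CTF1", region_set("chr1", 0, n))
  pg2 <- per_gene_low_fraction(tr2, genes2, cutoff = 40)
  expect_equal(pg2$low_fraction, 0.63)
  expect_true(pg2$low_fraction > 0.10)

  # gene bases outside the track territory count as uncovered (depth 0)
  genes3 <- gene_models("G3", region_set("chr1", 5, 15))
  tr3 <- depth_track(rep(50, 10), region_set("chr1", 0, 10))
  pg3 <- per_gene_low_fraction(tr3, genes3, cutoff = 10)
  expect_equal(pg3$low_fraction, 0.5)
})

test_that("per-gene fractions equal brute-force per-base counting", {
  set.seed(12)
  regions <- normalize_regions(random_intervals(8, chroms = "chr1",
                                                max_pos = 80))
  d <- rpois(total_bases(regions), 15)
  tr <- depth_track(d, regions)
  # brute-force: explicit per-base depth lookup over the genome
  genome_depth <- setNames(rep(0, 120), paste0("chr1:", 0:119))
  genome_depth[base_set(regions)] <- d
  for (rep in 1:5) {
    g_iv <- random_intervals(3, chroms = "chr1", max_pos = 80)
    genes <- gene_models("G", normalize_regions(g_iv))
    pg <- per_gene_low_fraction(tr, genes, cutoff = 14)
    gb <- genome_depth[base_set(normalize_regions(g_iv))]
    expect_equal(pg$low_fraction, mean(gb < 14))
    expect_equal(pg$mean_depth, mean(gb))
    expect_equal(pg$n_bases, length(gb))
  }
})

test_that("depth TSV round trip restores the track (zeros implicit)", {
  set.seed(2)
  regions <- normalize_regions(random_intervals(6, chroms = "chr1",
                                                max_pos = 50))
  d <- rpois(total_bases(regions), 8)
  tr <- depth_track(d, regions, method = "WGS", sample = "S01")
  path <- tempfile(fileext = ".tsv")
  write_depth_tsv(tr, path)
  tr2 <- read_depth_tsv(path, regions, method = "WGS", sample = "S01")
  expect_equal(tr2$depths, tr$depths)
})

test_that("GC content counts G+C over unambiguous bases", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGCCATGCAA"))
  expect_equal(gc_content(region_set("chr1", 0, 4), ref), 1.0)
  expect_equal(gc_content(region_set("chr1", 4, 8), ref), 0.5)
  # weighted-mean property: GC of a union is the base-weighted mean of parts
  a <- region_set("chr1", 0, 4)
  b <- region_set("chr1", 4, 10)
  gc_u <- gc_content(region_union(a, b), ref)
  expect_equal(gc_u, (4 * gc_content(a, ref) + 6 * gc_content(b, ref)) / 10)
  expect_error(gc_content(region_set("chr1", 0, 100), ref), "beyond")
  expect_error(gc_content(region_set("chrX", 0, 2), ref), "not in reference")

  set.seed(33)
  chars <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  ref2 <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""),
                                            "chr1"))
  for (rep in 1:5) {
    iv <- random_intervals(4, chroms = "chr1", max_pos = 150, max_len = 30)
    rs <- normalize_regions(iv)
    covered <- as.integer(sub("chr1:", "", base_set(rs))) + 1
    expect_equal(gc_content(rs, ref2), mean(chars[covered] %in% c("C", "G")))
  }
})

test_that("GC-rich windows recover a planted high-GC block", {
  all_gc <- Biostrings::DNAStringSet(c(chr1 = strrep("GC", 250)))
  expect_equal(total_bases(gc_windows(all_gc, window = 100)), 500)
  all_at <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 250)))
  expect_equal(total_bases(gc_windows(all_at, window = 100)), 0)

  # planted 300-base GC-rich block inside an AT background
  set.seed(6)
  bg <- sample(c("A", "T"), 1000, replace = TRUE)
  block <- sample(c("G", "C", "A", "T"), 300, replace = TRUE,
                  prob = c(0.4, 0.4, 0.1, 0.1))
  seqc <- c(bg[1:400], block, bg[401:700])
  ref <- Biostrings::DNAStringSet(setNames(paste(seqc, collapse = ""),
                                           "chr1"))
  found <- gc_windows(ref, window = 100, threshold = 0.6)
  df <- as.data.frame(found)
  expect_equal(nrow(df), 1)
  expect_lte(abs(df$start - 400), 100)
  expect_lte(abs(df$end - 700), 100)
})
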