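test_that("pairwise comparison partitions keys into shared and exclusive", {
  region <- region_set("chr1", 0, 1000)
  x <- make_callset(c(10L, 20L, 30L), method = "WGS")
  y <- make_callset(c(20L, 30L, 40L), method = "WES")
  pc <- pairwise_compare(x, y, region)
  expect_length(pc$shared, 2)
  expect_equal(pc$fe_x$pos, 10L)
  expect_equal(pc$fe_y$pos, 40L)
  # partition identity: shared + FE = total calls in region, per method
  expect_equal(length(pc$shared) + nrow(pc$fe_x), nrow(x$calls))
  expect_equal(length(pc$shared) + nrow(pc$fe_y), nrow(y$calls))

  # identical callsets leave no exclusive variants
  pc2 <- pairwise_compare(x, make_callset(c(10L, 20L, 30L), method = "WES"),
                          region)
  expect_equal(nrow(pc2$fe_x), 0)
  expect_equal(nrow(pc2$fe_y), 0)

  expect_error(pairwise_compare(x, make_callset(5L, method = "WES",
                                                sample = "S99"), region),
               "different samples")
})

test_that("the same locus with discordant genotypes is shared, not FE", {
  region <- region_set("chr1", 0, 100)
  x <- make_callset(10L, method = "WGS", genotype = "het")
  y <- make_callset(10L, method = "HES", genotype = "hom_alt",
                    alt_reads = 50L, ref_reads = 0L)
  pc <- pairwise_compare(x, y, region)
  expect_length(pc$shared, 1)
  expect_equal(nrow(pc$fe_x) + nrow(pc$fe_y), 0)
})

test_that("quality filtering applies depth and heterozygous allele balance", {
  qc <- quality_criteria()
  pass <- function(...) hqfe_filter(make_calls(1L, ...), method, qc)
  method <- "WGS"
  # het, depth 12, AD (7,5): AB = 0.417 -> passes the 10x tier
  expect_true(pass(genotype = "het", depth = 12L, ref_reads = 7L,
                   alt_reads = 5L))
  method <- "WES"
  # depth 39 fails the 40x tier regardless of AB
  expect_false(pass(genotype = "het", depth = 39L, ref_reads = 20L,
                    alt_reads = 19L))
  method <- "HES"
  # AB = 30/200 = 0.15 fails the balance window
  expect_false(pass(genotype = "het", depth = 200L, ref_reads = 170L,
                    alt_reads = 30L))
  # bounds are inclusive: AB exactly 0.2 and 0.5, depth exactly at cutoff
  method <- "WES"
  expect_true(pass(genotype = "het", depth = 40L, ref_reads = 32L,
                   alt_reads = 8L))    # AB = 0.2
  expect_true(pass(genotype = "het", depth = 40L, ref_reads = 20L,
                   alt_reads = 20L))   # AB = 0.5
  # homozygous calls pass on depth alone (AB criterion is heterozygous-only)
  expect_true(pass(genotype = "hom_alt", depth = 60L, ref_reads = 1L,
                   alt_reads = 59L))
  # unknown depth/AD can never be HQFE
  method <- "WGS"
  expect_false(pass(genotype = "het", depth = NA, ref_reads = NA,
                    alt_reads = NA))
})

test_that("three-way report equals a per-key truth-table oracle", {
  # all 7 non-empty presence patterns, once each
  pats <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE),
                                c(FALSE, TRUE)))[-1, ]
  run_oracle_check <- function(present) {
    cs <- callsets_from_presence(present)
    rep3 <- three_way(cs, region = region_set("chr1", 0, 10000))
    oracle <- threeway_oracle(present)
    got <- as.matrix(rep3$counts[, colnames(oracle)])
    expect_equal(unname(got), unname(oracle))
    # Table-2 identity on every method
    expect_equal(rep3$counts$total_detected,
                 rep3$counts$confirmed_by_all + rep3$counts$fe)
    expect_equal(rep3$counts$fe,
                 rep3$counts$fe_confirmed + rep3$counts$fe_not_confirmed)
  }
  run_oracle_check(pats)
  # random presence matrices over 20 keys
  set.seed(14)
  for (rep in 1:20) {
    present <- matrix(runif(60) < 0.6, ncol = 3)
    present <- present[rowSums(present) > 0, , drop = FALSE]
    if (!nrow(present)) next
    run_oracle_check(present)
  }
})

test_that("sensitivity follows the confirmed / (confirmed + missed) formula", {
  expect_equal(sensitivity(2252, 24, 2), 99.9)
  expect_equal(sensitivity(10, 0, 0), 100)
  expect_equal(sensitivity(0, 5, 5), 50)
  expect_true(is.na(sensitivity(0, 0, 0)))
  expect_equal(sensitivity(100, 0, 1, digits = NULL), 100 * 100 / 101)
})

test_that("three identical callsets give zero FE/MV and 100% sensitivity", {
  cs <- lapply(c("WGS", "WES", "HES"), function(m)
    make_callset(c(10L, 20L, 30L, 40L), method = m, depth = 100L))
  rep3 <- three_way(cs, region = region_set("chr1", 0, 100))
  expect_true(all(rep3$counts$fe == 0))
  expect_true(all(rep3$counts$missed == 0))
  expect_true(all(rep3$counts$sensitivity_pct == 100))
  expect_true(all(rep3$counts$hqfe_sensitivity_pct == 100))
})

test_that("relabelling methods permutes the report consistently", {
  set.seed(19)
  present <- matrix(runif(45) < 0.6, ncol = 3)
  present <- present[rowSums(present) > 0, , drop = FALSE]
  region <- region_set("chr1", 0, 10000)
  cs <- callsets_from_presence(present)
  rep1 <- three_way(cs, region)
  perm <- c(3, 1, 2)
  cs_perm <- callsets_from_presence(present[, perm],
                                    methods = c("WGS", "WES", "HES"))
  rep2 <- three_way(cs_perm, region)
  cols <- setdiff(names(rep1$counts), "method")
  expect_equal(rep2$counts[, cols], rep1$counts[perm, cols],
               ignore_attr = TRUE)
})

test_that("missed variants are FE-confirmed calls of the other methods", {
  set.seed(23)
  present <- matrix(runif(90) < 0.5, ncol = 3)
  present <- present[rowSums(present) > 0, , drop = FALSE]
  cs <- callsets_from_presence(present)
  rep3 <- three_way(cs, region = region_set("chr1", 0, 10000))
  # every MV of method m is a key absent from m and present in exactly the
  # other two -> it appears as an fe_confirmed call of both others
  for (m in 1:3) {
    mv <- sum(!present[, m] & rowSums(present[, -m, drop = FALSE]) == 2)
    expect_equal(rep3$counts$missed[m], mv)
  }
  expect_equal(sum(rep3$counts$missed) * 2, sum(rep3$counts$fe_confirmed))
})

test_that("cohort medians and percentages follow the reporting convention", {
  region <- region_set("chr1", 0, 10000)
  # two samples; the first method has 2 exclusive calls in the second one
  xs <- list(make_callset(seq(10L, 100L, 10L), method = "WGS", sample = "S01"),
             make_callset(seq(10L, 120L, 10L), method = "WGS", sample = "S02"))
  ys <- list(make_callset(seq(10L, 100L, 10L), method = "WES", sample = "S01"),
             make_callset(seq(10L, 100L, 10L), method = "WES", sample = "S02"))
  pc <- pairwise_cohort(xs, ys, region)
  sa <- pc$summary[pc$summary$method == "WGS", ]
  expect_equal(sa$median_snv, 11)   # even-length median: mean of 10 and 12
  expect_equal(sa$median_fe, 1)     # per-sample FE counts 0, 2
  expect_equal(pc$per_sample$n_fe[pc$per_sample$method == "WGS"], c(0, 2))

  expect_equal(exclusive_percent(6, 402), 1.5)
  expect_equal(exclusive_percent(17, 636), 2.7)
  expect_equal(exclusive_percent(3, 226), 1.3)
  expect_true(is.na(exclusive_percent(0, 0)))
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.15, 1), 0.2)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(99.85, 1), 99.9)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("genotype discordance reports keys with unequal labels", {
  mk <- function(method, genotype)
    callset(make_calls(c(10L, 20L), genotype = genotype,
                       alt_reads = c(25L, 25L), ref_reads = c(25L, 25L),
                       depth = 50L),
            method = method, sample = "S01")
  cs <- list(mk("WGS", c("het", "het")),
             mk("WES", c("het", "het")),
             mk("HES", c("hom_alt", "het")))
  d <- genotype_discordance(cs)
  expect_equal(nrow(d), 1)
  expect_equal(d$pos, 10L)
  expect_equal(d$WGS, "het")
  expect_equal(d$HES, "hom_alt")

  # all labels equal -> nothing reported
  cs2 <- list(mk("WGS", "het"), mk("WES", "het"), mk("HES", "het"))
  expect_equal(nrow(genotype_discordance(cs2)), 0)
})

test_that("discordance agrees with a per-key brute-force check", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40
    pos <- seq_len(n) * 5L
    gts <- matrix(sample(c("het", "hom_alt", NA), n * 3, replace = TRUE,
                         prob = c(0.45, 0.35, 0.2)), ncol = 3)
    cs <- lapply(1:3, function(m) {
      sel <- !is.na(gts[, m])
      callset(make_calls(pos[sel], genotype = gts[sel, m], depth = 100L,
                         alt_reads = 50L, ref_reads = 50L),
              method = c("WGS", "WES", "HES")[m], sample = "S01")
    })
    d <- genotype_discordance(cs)
    expected <- vapply(seq_len(n), function(i) {
      called <- gts[i, !is.na(gts[i, ])]
      length(called) >= 2 && length(unique(called)) > 1
    }, logical(1))
    expect_equal(sort(d$pos), pos[expected])
  }
})

test_that("FE annotation tags repeat and GC-rich membership", {
  calls <- make_calls(c(10L, 30L, 50L))
  calls$method <- "WGS"
  repeats <- region_set("chr1", 25, 35)
  gc_rich <- region_set("chr1", 45, 55)
  ann <- annotate_fe(calls, repeats, gc_rich)
  expect_equal(ann$calls$in_repeat, c(FALSE, TRUE, FALSE))
  expect_equal(ann$calls$in_gc_rich, c(FALSE, FALSE, TRUE))
  expect_equal(ann$summary$frac_in_repeat, 1 / 3)
  # empty annotation sets leave every tag false
  ann0 <- annotate_fe(calls, NULL, NULL)
  expect_false(any(ann0$calls$in_repeat))
  expect_false(any(ann0$calls$in_gc_rich))
  # random placement: fractions equal direct counting
  set.seed(41)
  pos <- sample.int(200, 40)
  rc <- make_calls(sort(pos))
  rc$method <- "M"
  rs <- normalize_regions(random_intervals(6, chroms = "chr1",
                                           max_pos = 180, max_len = 20))
  ann2 <- annotate_fe(rc, rs, NULL)
  expect_equal(ann2$summary$frac_in_repeat,
               mean(paste("chr1", rc$pos - 1, sep = ":") %in% base_set(rs)))
})
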