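test_that("reference generation is deterministic and capture sets nest", {
  r1 <- make_reference(seed = 42)
  r2 <- make_reference(seed = 42)
  expect_equal(as.character(r1$sequence), as.character(r2$sequence))
  expect_equal(as.data.frame(r1$captures$WES), as.data.frame(r2$captures$WES))
  expect_equal(r1$genes$symbol, r2$genes$symbol)

  # WES design is a subset of the whole-genome territory; the triple
  # intersection is contained in every capture
  expect_equal(total_bases(region_subtract(r1$captures$WES,
                                           r1$captures$WGS)), 0)
  triple <- Reduce(region_intersect, r1$captures)
  for (cap in r1$captures)
    expect_equal(total_bases(region_subtract(triple, cap)), 0)
  # WES omits exons, HES has them all
  expect_lt(total_bases(r1$captures$WES), total_bases(r1$captures$HES))
})

test_that("planted high-GC genes realize their GC targets", {
  ref <- make_reference(seed = 8)
  expect_length(ref$gc_gene_targets, 4)
  for (g in names(ref$gc_gene_targets)) {
    realized <- gc_content(ref$cds[[g]], ref$sequence)
    expect_lt(abs(realized - ref$gc_gene_targets[[g]]), 0.02)
  }
  # background genes sit near the background GC
  bg <- setdiff(ref$genes$symbol, names(ref$gc_gene_targets))[1]
  expect_lt(abs(gc_content(ref$cds[[bg]], ref$sequence) - 0.42), 0.08)
  # repeats are planted inside the panel capture so they can host calls
  expect_gt(total_bases(region_intersect(ref$repeats, ref$captures$HES)), 0)
})

test_that("truth simulation honours density, het fraction, and seed", {
  ref <- make_reference(n_genes = 100, intergenic = 4000, seed = 2)
  expect_gt(ref$chrom_len, 590000)
  tr <- simulate_truth(ref, n_samples = 2, snv_density = 0.001, seed = 3)
  # Poisson expectation: ~1 locus per kb of territory
  lambda <- 0.001 * ref$chrom_len
  expect_lt(abs(nrow(tr$loci) - lambda), 4 * sqrt(lambda))
  expect_true(all(tr$loci$ref != tr$loci$alt))
  # reference bases in the loci table match the sequence
  chars <- strsplit(as.character(ref$sequence[[1]]), "")[[1]]
  expect_equal(tr$loci$ref, chars[tr$loci$pos])

  tr2 <- simulate_truth(ref, n_samples = 2, snv_density = 0.001, seed = 3)
  expect_equal(tr$loci, tr2$loci)
  expect_equal(tr$genotypes, tr2$genotypes)

  tr3 <- simulate_truth(ref, n_samples = 3, het_fraction = 1, seed = 5)
  expect_false(any(tr3$genotypes == "hom_alt"))
})

test_that("the noiseless limit reproduces the truth exactly", {
  ref <- make_reference(seed = 4)
  tr <- simulate_truth(ref, n_samples = 2, snv_density = 0.002, seed = 6)
  prof <- neutral_profiles()$WGS
  sim <- simulate_platform(tr, prof, "S01", seed = 7)
  g <- tr$genotypes[, "S01"]
  expected <- tr$loci[g != "hom_ref", ]
  expect_equal(sim$callset$calls$pos, expected$pos)
  expect_equal(sim$callset$calls$chrom, expected$chrom)
  expect_equal(sim$callset$calls$ref, expected$ref)
  expect_equal(sim$callset$calls$alt, expected$alt)
  expect_equal(sim$callset$calls$genotype, unname(g[g != "hom_ref"]))
  expect_true(all(sim$track$depths == 100))
})

test_that("platform simulation is reproducible and depth laws match targets", {
  ref <- make_reference(seed = 12)
  tr <- simulate_truth(ref, n_samples = 1, seed = 13)
  profs <- default_profiles()
  s1 <- simulate_platform(tr, profs$WGS, "S01", seed = 99)
  s2 <- simulate_platform(tr, profs$WGS, "S01", seed = 99)
  expect_equal(s1$callset$calls, s2$callset$calls)
  expect_equal(s1$track$depths, s2$track$depths)

  # WGS: symmetric around 37; WES/HES: right-skewed (mean > median)
  expect_lt(abs(mean(s1$track$depths) - 37), 0.5)
  expect_lt(abs(median(s1$track$depths) - 37), 1)
  wes <- simulate_platform(tr, profs$WES, "S01", seed = 100)
  hes <- simulate_platform(tr, profs$HES, "S01", seed = 101)
  expect_gt(mean(wes$track$depths), median(wes$track$depths))
  expect_gt(mean(hes$track$depths), median(hes$track$depths))
  expect_lt(abs(median(hes$track$depths) / 431 - 1), 0.1)
})

test_that("homozygous minor-read fraction matches its closed form", {
  # fraction with >= 1 minor read should match E[1 - (1-eps)^D] under the
  # depth law (computed by direct numerical expectation)
  ref <- make_reference(n_genes = 10, intergenic = 500, seed = 21)
  tr <- simulate_truth(ref, n_samples = 1, snv_density = 0.5,
                       het_fraction = 0, carrier_rate = 1, seed = 22)
  prof <- default_profiles()$WGS
  sim <- simulate_platform(tr, prof, "S01", seed = 23)
  hom <- sim$callset$calls[sim$callset$calls$genotype == "hom_alt", ]
  n <- nrow(hom)
  expect_gt(n, 5000)
  eps <- prof$minor_read_rate
  d <- 0:120
  pd <- dnorm(d, 37, 10) / sum(dnorm(d, 37, 10))
  expected <- sum(pd * (1 - (1 - eps)^d))
  observed <- hom_minor_fraction(sim$callset)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 4 * se + 0.002)
})

test_that("GC dropout attenuates coverage of GC-rich capture territory", {
  ref <- make_reference(seed = 31)
  tr <- simulate_truth(ref, n_samples = 1, seed = 32)
  prof <- default_profiles()$HES
  prof$gc_dropout$dropout_prob <- 1   # force dropout in every GC-rich window
  sim <- simulate_platform(tr, prof, "S01", seed = 33)
  gc_cap <- region_intersect(ref$gc_rich, ref$captures$HES)
  expect_gt(total_bases(gc_cap), 0)
  in_gc <- region_contains(gc_cap, rep(ref$chrom, length(sim$track$depths)),
                           unlist(lapply(seq_len(nrow(as.data.frame(
                             ref$captures$HES))), function(k) {
                               df <- as.data.frame(ref$captures$HES)
                               seq.int(df$start[k] + 1, df$end[k])
                             })))
  expect_lt(mean(sim$track$depths[in_gc]),
            0.3 * mean(sim$track$depths[!in_gc]))
})

test_that("cohort fixtures are deterministic and substreams are stable", {
  c1 <- make_cohort_fixture(seed = 5, n_samples = 3)
  c2 <- make_cohort_fixture(seed = 5, n_samples = 3)
  expect_equal(c1$callsets$WGS$S02$calls, c2$callsets$WGS$S02$calls)
  expect_equal(c1$tracks$HES$S03$depths, c2$tracks$HES$S03$depths)
  # adding a sample must not perturb earlier samples' draws
  c3 <- make_cohort_fixture(seed = 5, n_samples = 4)
  expect_equal(c3$callsets$WGS$S02$calls, c1$callsets$WGS$S02$calls)
  expect_equal(c3$callsets$HES$S01$calls, c1$callsets$HES$S01$calls)
})

test_that("planted genotype flips are recovered exactly by the discordance report", {
  co <- make_cohort_fixture(seed = 11, n_samples = 5, genotype_flips = 5)
  expect_equal(nrow(co$flips), 5)
  for (s in co$truth$samples) {
    trio <- lapply(co$callsets, `[[`, s)
    d <- genotype_discordance(trio,
                              region = Reduce(region_intersect,
                                              co$reference$captures))
    planted <- co$flips[co$flips$sample == s, ]
    expect_setequal(paste(d$chrom, d$pos), paste(planted$chrom, planted$pos))
  }
})
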