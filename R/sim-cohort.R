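#' Simulate a full three-platform cohort
#'
#' Builds a synthetic reference, a truth set, and per-(platform, sample)
#' callsets and depth tracks — a complete, deterministic test bundle for the
#' end-to-end comparison pipeline. Randomness is split into independent
#' substreams per (platform, sample) derived from the master seed, so adding
#' a sample or platform never perturbs the draws of another.
#'
#' Optionally plants `genotype_flips` genotype errors: heterozygous truth
#' sites called by all platforms whose call in the last platform (the
#' panel-enrichment-like one) is relabelled homozygous-alternate with its
#' allele depths collapsed — emulating allelic capture bias — and recorded
#' so that discordance reports can be checked against the planted truth.
#'
#' @param seed master integer seed.
#' @param n_samples number of samples (default 10).
#' @param n_genes number of genes in the synthetic reference (default 20).
#' @param profiles named list of three [platform_profile()]s
#'   (default [default_profiles()]).
#' @param snv_density,het_fraction,carrier_rate passed to
#'   [simulate_truth()].
#' @param genotype_flips number of genotype errors to plant (default 0).
#' @param reference optional pre-built [make_reference()] object.
#' @param ... further arguments to [make_reference()].
#' @return An object of class `snv_cohort`: list with `reference`, `truth`,
#'   `profiles`, `callsets` and `tracks` (nested lists
#'   `[[platform]][[sample]]`), `records`, `flips` (data frame of planted
#'   genotype errors), and `seed`.
#' @export
make_cohort_fixture <- function(seed = 1, n_samples = 10, n_genes = 20,
                                profiles = default_profiles(),
                                snv_density = 0.001, het_fraction = 0.6,
                                carrier_rate = 0.8, genotype_flips = 0,
                                reference = NULL, ...) {
  stopifnot(length(profiles) == 3)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) p$name, character(1))
  reference <- reference %||%
    make_reference(n_genes = n_genes, seed = substream_seed(seed, 0L, 0L),
                   ...)
  truth <- simulate_truth(reference, n_samples = n_samples,
                          snv_density = snv_density,
                          het_fraction = het_fraction,
                          carrier_rate = carrier_rate,
                          seed = substream_seed(seed, 0L, 1L))
  callsets <- list()
  tracks <- list()
  records <- list()
  for (p in seq_along(profiles)) {
    pname <- names(profiles)[p]
    callsets[[pname]] <- list()
    tracks[[pname]] <- list()
    records[[pname]] <- list()
    for (s in seq_along(truth$samples)) {
      sid <- truth$samples[s]
      sim <- simulate_platform(truth, profiles[[p]], sid,
                               seed = substream_seed(seed, p, s))
      callsets[[pname]][[sid]] <- sim$callset
      tracks[[pname]][[sid]] <- sim$track
      records[[pname]][[sid]] <- sim$record
    }
  }

  flips <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      method = character(), stringsAsFactors = FALSE)
  if (genotype_flips > 0) {
    flip_method <- names(profiles)[3]
    triple <- Reduce(region_intersect, reference$captures)
    candidates <- list()
    for (sid in truth$samples) {
      keys <- lapply(callsets, function(pl) call_keys(pl[[sid]]))
      shared <- Reduce(intersect, keys)
      cs3 <- callsets[[flip_method]][[sid]]
      k3 <- call_keys(cs3)
      het3 <- k3 %in% shared & cs3$calls$genotype == "het" &
        region_contains(triple, cs3$calls$chrom, cs3$calls$pos)
      ## only flip where the other two methods called het, so the flip is
      ## the unique source of discordance at the locus
      for (other in setdiff(names(profiles), flip_method)) {
        co <- callsets[[other]][[sid]]
        m <- match(k3, call_keys(co))
        het3 <- het3 & !is.na(m) & co$calls$genotype[m] == "het"
      }
      if (any(het3))
        candidates[[sid]] <- data.frame(sample = sid,
                                        idx = which(het3),
                                        stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, candidates)
    if (is.null(cand) || nrow(cand) < genotype_flips)
      stopf("only %d flip candidates available; asked for %d",
            if (is.null(cand)) 0L else nrow(cand), genotype_flips)
    pick <- with_seed(substream_seed(seed, 9L, 9L),
                      cand[sample.int(nrow(cand), genotype_flips), ,
                           drop = FALSE])
    for (r in seq_len(nrow(pick))) {
      sid <- pick$sample[r]
      i <- pick$idx[r]
      cs <- callsets[[flip_method]][[sid]]
      cs$calls$genotype[i] <- "hom_alt"
      d <- cs$calls$depth[i]
      if (!is.na(d)) {
        cs$calls$alt_reads[i] <- d
        cs$calls$ref_reads[i] <- 0L
      }
      flips <- rbind(flips, data.frame(
        sample = sid, chrom = cs$calls$chrom[i], pos = cs$calls$pos[i],
        ref = cs$calls$ref[i], alt = cs$calls$alt[i], method = flip_method,
        stringsAsFactors = FALSE))
      callsets[[flip_method]][[sid]] <- cs
    }
    flips <- flips[order(flips$sample, flips$chrom, flips$pos), ,
                   drop = FALSE]
    rownames(flips) <- NULL
  }

  structure(list(reference = reference, truth = truth, profiles = profiles,
                 callsets = callsets, tracks = tracks, records = records,
                 flips = flips, seed = seed),
            class = "snv_cohort")
}

#' @export
print.snv_cohort <- function(x, ...) {
  n_calls <- vapply(x$callsets, function(pl)
    sum(vapply(pl, length, integer(1))), numeric(1))
  cat(sprintf("snv_cohort: %d samples x %d platforms (%s), seed %d\n",
              length(x$truth$samples), length(x$profiles),
              paste(sprintf("%s: %d calls", names(n_calls), n_calls),
                    collapse = "; "), x$seed))
  invisible(x)
}

#' Write a simulated cohort to disk as standard files
#'
#' Writes the reference FASTA, capture/gene/repeat/GC-rich BEDs, one VCF and
#' one depth TSV per (platform, sample), and the truth tables, and returns a
#' run configuration pointing at the files — the on-disk interface consumed
#' by [run_full_analysis()].
#'
#' @param cohort an `snv_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a `run_config`-style list of file paths and labels.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "snv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(cohort$reference$sequence, p("reference.fa"))
  write_gene_bed(cohort$reference$genes, p("genes.bed"))
  write_bed(cohort$reference$repeats, p("repeats.bed"))
  methods <- names(cohort$profiles)
  capture_bed <- stats::setNames(p(sprintf("capture_%s.bed", methods)),
                                 methods)
  for (m in methods)
    write_bed(cohort$reference$captures[[m]], capture_bed[[m]])
  samples <- cohort$truth$samples
  vcf <- list()
  depth_tsv <- list()
  for (m in methods) {
    vcf[[m]] <- stats::setNames(p(sprintf("%s_%s.vcf", m, samples)),
                                samples)
    depth_tsv[[m]] <- stats::setNames(p(sprintf("%s_%s_depth.tsv",
                                                m, samples)), samples)
    for (s in samples) {
      write_vcf(cohort$callsets[[m]][[s]], vcf[[m]][[s]])
      write_depth_tsv(cohort$tracks[[m]][[s]], depth_tsv[[m]][[s]])
    }
  }
  truth_df <- cbind(cohort$truth$loci, cohort$truth$genotypes)
  utils::write.table(truth_df, p("truth_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(cohort$flips))
    utils::write.table(cohort$flips, p("planted_flips.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  config <- list(methods = methods, samples = samples, vcf = vcf,
                 capture_bed = as.list(capture_bed),
                 depth_tsv = depth_tsv, gene_bed = p("genes.bed"),
                 repeat_bed = p("repeats.bed"),
                 reference_fasta = p("reference.fa"),
                 criteria = quality_criteria(
                   min_depth = stats::setNames(c(10, 40, 40)[
                     seq_along(methods)], methods)),
                 low_cutoffs = stats::setNames(c(10, 40, 40)[
                   seq_along(methods)], methods),
                 outdir = p("results"), seed = cohort$seed)
  invisible(config)
}
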