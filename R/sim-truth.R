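#' Simulate a ground-truth variant set
#'
#' Plants SNV loci uniformly over a territory (default: the union of the
#' reference's capture designs, i.e. the whole synthetic chromosome) at a
#' given per-base density, and draws a diploid genotype for every
#' (sample, locus) pair: carrier with probability `carrier_rate`, and among
#' carriers heterozygous with probability `het_fraction` (otherwise
#' homozygous for the alternate allele). The locus count is Poisson with
#' mean `density * territory bases`.
#'
#' @param reference a [make_reference()] object.
#' @param n_samples number of samples (default 10).
#' @param snv_density expected SNVs per base of territory (default 0.001,
#'   i.e. 1 per kilobase).
#' @param het_fraction probability a carrier genotype is heterozygous
#'   (default 0.6).
#' @param carrier_rate probability a sample carries a given locus
#'   (default 0.8).
#' @param territory optional `region_set` in which loci are placed.
#' @param seed integer seed.
#' @return An object of class `truth_set`: list with `reference`, `samples`
#'   (ids), `loci` (data frame `chrom`, `pos` 1-based, `ref`, `alt`), and
#'   `genotypes` (matrix loci x samples with values `"hom_ref"`, `"het"`,
#'   `"hom_alt"`).
#' @export
simulate_truth <- function(reference, n_samples = 10, snv_density = 0.001,
                           het_fraction = 0.6, carrier_rate = 0.8,
                           territory = NULL, seed = 1) {
  stopifnot(inherits(reference, "synthetic_reference"))
  if (snv_density <= 0) stopf("snv_density must be positive")
  if (is.null(territory)) {
    territory <- Reduce(region_union, reference$captures)
    territory$label <- "territory"
  }
  with_seed(seed, {
    n_bases <- total_bases(territory)
    n_loci <- stats::rpois(1, snv_density * n_bases)
    n_loci <- min(n_loci, n_bases)
    ## offsets within the territory -> genomic positions
    df <- as.data.frame(territory)
    width <- df$end - df$start
    offs <- sort(sample.int(n_bases, n_loci))
    cum0 <- c(0, cumsum(width))
    iv <- findInterval(offs - 1, cum0)          # interval index, 1..K
    pos <- df$start[iv] + (offs - cum0[iv])     # 1-based genomic position
    chrom <- df$chrom[iv]

    seqs <- reference$sequence
    ref_base <- character(n_loci)
    for (cn in unique(chrom)) {
      chars <- strsplit(as.character(seqs[[cn]]), "", fixed = TRUE)[[1]]
      sel <- chrom == cn
      ref_base[sel] <- chars[pos[sel]]
    }
    ## alternate allele: one of the three other bases, uniformly
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3, n_loci, replace = TRUE)
    alt_base <- bases[(match(ref_base, bases) - 1 + shift) %% 4 + 1]

    g <- matrix("hom_ref", nrow = n_loci, ncol = n_samples)
    # one draw block per sample, so adding a sample never perturbs the
    # genotypes of the samples before it
    for (s in seq_len(n_samples)) {
      if (!n_loci) break
      carrier <- stats::runif(n_loci) < carrier_rate
      het <- stats::runif(n_loci) < het_fraction
      g[carrier & het, s] <- "het"
      g[carrier & !het, s] <- "hom_alt"
    }
    samples <- sprintf("S%02d", seq_len(n_samples))
    colnames(g) <- samples

    structure(list(reference = reference, samples = samples,
                   loci = data.frame(chrom = chrom, pos = pos,
                                     ref = ref_base, alt = unname(alt_base),
                                     stringsAsFactors = FALSE),
                   genotypes = g, territory = territory, seed = seed),
              class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d loci x %d samples over %s bases\n",
              nrow(x$loci), length(x$samples),
              format(total_bases(x$territory), big.mark = ",")))
  invisible(x)
}
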