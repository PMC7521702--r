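## map offsets (1..total_bases) within a region set to (chrom, pos 1-based)
offsets_to_positions <- function(rs, offs) {
  df <- as.data.frame(rs)
  width <- df$end - df$start
  cum0 <- c(0, cumsum(width))
  iv <- findInterval(offs - 1, cum0)
  data.frame(chrom = df$chrom[iv], pos = df$start[iv] + (offs - cum0[iv]),
             stringsAsFactors = FALSE)
}

## reference base at 1-based positions
ref_base_at <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    chars <- strsplit(as.character(reference$sequence[[cn]]), "",
                      fixed = TRUE)[[1]]
    sel <- chrom == cn
    out[sel] <- chars[pos[sel]]
  }
  out
}

#' Simulate one platform's callset and depth track for one sample
#'
#' Generates a per-base depth track over the platform's capture design and a
#' callset derived from the truth set under the profile's error model:
#' \enumerate{
#'   \item per-base depth is drawn from the profile's depth law, rounded and
#'     truncated at 0; GC-rich windows (GC > threshold) lose coverage with
#'     probability `dropout_prob`, multiplying their depth by `attenuation`;
#'   \item at each true variant site in the capture, alternate reads are
#'     binomial on the site depth — success probability
#'     `allele_bias / (1 + allele_bias)` for heterozygotes and
#'     `1 - minor_read_rate` for homozygotes;
#'   \item a true site is uncalled when its depth falls below
#'     `depth_fn_cutoff`, with probability `fn_base_rate` otherwise, or when
#'     the simulated caller cannot label it (alternate reads in the
#'     minority and below the het cutoff);
#'   \item the caller labels a site heterozygous when the minor-allele
#'     fraction reaches `het_call_cutoff`, homozygous-alternate otherwise;
#'   \item false positives are Poisson over the captured megabases at
#'     `fp_rate` (times `repeat_fp_multiplier` inside repeats), placed at
#'     non-truth positions with few supporting alternate reads, so that a
#'     realistic fraction fails downstream quality filtering.
#' }
#'
#' @param truth a [simulate_truth()] object.
#' @param profile a [platform_profile()]; its `name` selects the capture
#'   design from the truth set's reference.
#' @param sample sample id (one of `truth$samples`).
#' @param seed integer seed; defaults to a substream derived from the truth
#'   set's seed, the platform, and the sample, so streams are independent.
#' @return A list of class `platform_sim` with `callset` (a `callset`),
#'   `track` (a `depth_track`), and `record` (per true-variant bookkeeping:
#'   was it called, with which genotype; plus false-positive rows).
#' @export
simulate_platform <- function(truth, profile, sample, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"),
            inherits(profile, "platform_profile"))
  reference <- truth$reference
  capture <- reference$captures[[profile$name]]
  if (is.null(capture))
    stopf("reference has no capture design named '%s'", profile$name)
  if (!sample %in% truth$samples) stopf("unknown sample '%s'", sample)
  if (is.null(seed))
    seed <- substream_seed(truth$seed,
                           match(profile$name, names(reference$captures),
                                 nomatch = 9L),
                           match(sample, truth$samples))
  with_seed(seed, {
    n <- total_bases(capture)
    dl <- profile$depth_law
    depths <- switch(dl$type,
      normal = stats::rnorm(n, dl$mean, dl$sd),
      lognormal = stats::rlnorm(n, dl$meanlog, dl$sdlog),
      stopf("unknown depth law '%s'", dl$type))
    depths <- pmax(round(depths), 0)

    ## GC-driven capture dropout, decided per GC-rich window
    gd <- profile$gc_dropout
    if (gd$dropout_prob > 0 && total_bases(reference$gc_rich) > 0) {
      gc_cap <- region_intersect(reference$gc_rich, capture)
      gdf <- as.data.frame(gc_cap)
      if (nrow(gdf)) {
        dummy <- structure(list(regions = capture), class = "depth_track")
        for (k in seq_len(nrow(gdf))) {
          if (stats::runif(1) < gd$dropout_prob) {
            p <- seq.int(gdf$start[k] + 1, gdf$end[k])
            idx <- track_index(dummy, rep(gdf$chrom[k], length(p)), p)
            idx <- idx[!is.na(idx)]
            depths[idx] <- round(depths[idx] * gd$attenuation)
          }
        }
      }
    }
    track <- depth_track(depths, capture, method = profile$name,
                         sample = sample)

    ## true variant sites inside the capture
    loci <- truth$loci
    g <- truth$genotypes[, sample]
    sel <- which(g != "hom_ref" &
                   region_contains(capture, loci$chrom, loci$pos))
    chrom <- loci$chrom[sel]
    pos <- loci$pos[sel]
    refb <- loci$ref[sel]
    altb <- loci$alt[sel]
    gt <- g[sel]
    d <- track$depths[track_index(track, chrom, pos)]

    p_alt <- ifelse(gt == "het",
                    profile$allele_bias / (1 + profile$allele_bias),
                    1 - profile$minor_read_rate)
    alt_reads <- stats::rbinom(length(sel), d, p_alt)
    ref_reads <- d - alt_reads
    minor_frac <- ifelse(d > 0, pmin(ref_reads, alt_reads) / d, 0)
    label <- ifelse(minor_frac >= profile$het_call_cutoff, "het",
                    ifelse(alt_reads > ref_reads, "hom_alt", "hom_ref"))
    uncalled <- d < profile$depth_fn_cutoff |
      stats::runif(length(sel)) < profile$fn_base_rate |
      label == "hom_ref"
    record <- data.frame(chrom = chrom, pos = pos, ref = refb, alt = altb,
                         true_genotype = gt, depth = d,
                         called = !uncalled,
                         call_genotype = ifelse(uncalled, NA_character_,
                                                label),
                         is_fp = logical(length(chrom)),
                         stringsAsFactors = FALSE)
    calls <- data.frame(chrom = chrom, pos = pos, ref = refb, alt = altb,
                        genotype = label, depth = d, ref_reads = ref_reads,
                        alt_reads = alt_reads,
                        stringsAsFactors = FALSE)[!uncalled, , drop = FALSE]

    ## false positives, with a repeat-region excess
    fp_calls <- NULL
    if (profile$fp_rate > 0) {
      parts <- list(
        list(rs = region_subtract(capture, reference$repeats),
             rate = profile$fp_rate),
        list(rs = region_intersect(capture, reference$repeats,
                                   label = "rep"),
             rate = profile$fp_rate * profile$repeat_fp_multiplier))
      fp_rows <- list()
      for (part in parts) {
        nb <- total_bases(part$rs)
        if (nb == 0) next
        n_fp <- stats::rpois(1, part$rate * nb / 1e6)
        if (n_fp == 0) next
        offs <- sample.int(nb, min(n_fp, nb))
        gp <- offsets_to_positions(part$rs, offs)
        keep <- !(vkey(gp$chrom, gp$pos, "", "") %in%
                    vkey(loci$chrom, loci$pos, "", ""))
        gp <- gp[keep, , drop = FALSE]
        if (!nrow(gp)) next
        rb <- ref_base_at(reference, gp$chrom, gp$pos)
        bases <- c("A", "C", "G", "T")
        shift <- sample.int(3, nrow(gp), replace = TRUE)
        ab <- bases[(match(rb, bases) - 1 + shift) %% 4 + 1]
        dfp <- track$depths[track_index(track, gp$chrom, gp$pos)]
        ok <- dfp > 0
        if (!any(ok)) next
        p_fp <- stats::runif(sum(ok), 0.08, 0.35)
        alt_fp <- pmax(stats::rbinom(sum(ok), dfp[ok], p_fp), 1)
        fp_rows[[length(fp_rows) + 1L]] <- data.frame(
          chrom = gp$chrom[ok], pos = gp$pos[ok], ref = rb[ok],
          alt = ab[ok],
          genotype = ifelse(alt_fp >= dfp[ok], "hom_alt", "het"),
          depth = dfp[ok], ref_reads = dfp[ok] - alt_fp,
          alt_reads = alt_fp, stringsAsFactors = FALSE)
      }
      if (length(fp_rows)) {
        fp_calls <- do.call(rbind, fp_rows)
        fp_calls <- fp_calls[!duplicated(
          vkey(fp_calls$chrom, fp_calls$pos, fp_calls$ref, fp_calls$alt)),
          , drop = FALSE]
        record <- rbind(record, data.frame(
          chrom = fp_calls$chrom, pos = fp_calls$pos, ref = fp_calls$ref,
          alt = fp_calls$alt, true_genotype = "hom_ref",
          depth = fp_calls$depth, called = TRUE,
          call_genotype = fp_calls$genotype, is_fp = TRUE,
          stringsAsFactors = FALSE))
      }
    }
    all_calls <- rbind(calls, fp_calls)
    all_calls <- all_calls[!duplicated(
      vkey(all_calls$chrom, all_calls$pos, all_calls$ref, all_calls$alt)),
      , drop = FALSE]
    cs <- callset(all_calls, method = profile$name, sample = sample,
                  capture = capture)
    structure(list(callset = cs, track = track, record = record,
                   profile = profile, seed = seed),
              class = "platform_sim")
  })
}
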