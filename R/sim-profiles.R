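#' Sequencing-platform simulation profiles
#'
#' A `platform_profile` collects the parameters governing how one sequencing
#' method is simulated:
#' \describe{
#'   \item{depth_law}{per-base depth distribution: `list(type = "normal",
#'     mean, sd)` or `list(type = "lognormal", meanlog, sdlog)` (for
#'     lognormal, `exp(meanlog)` is the median). Draws are rounded and
#'     truncated at 0.}
#'   \item{gc_dropout}{capture dropout in GC-rich territory: windows whose GC
#'     fraction exceeds `threshold` lose coverage with probability
#'     `dropout_prob`, multiplying depth by `attenuation`.}
#'   \item{fn_base_rate}{probability a true variant with adequate depth is
#'     nevertheless uncalled (caller/chemistry false negatives).}
#'   \item{depth_fn_cutoff}{depth below which a true variant is always
#'     uncalled.}
#'   \item{fp_rate}{expected false-positive calls per megabase of captured
#'     territory, multiplied by `repeat_fp_multiplier` inside repeats.}
#'   \item{allele_bias}{relative capture efficiency of the alternate allele
#'     (1 = unbiased); at heterozygous sites alternate reads are
#'     binomial with success probability `allele_bias / (1 + allele_bias)`.}
#'   \item{minor_read_rate}{per-read probability of an erroneous
#'     minor-allele read at homozygous sites.}
#'   \item{het_call_cutoff}{minor-allele fraction at or above which the
#'     simulated caller labels a site heterozygous.}
#' }
#'
#' @param name platform label.
#' @param depth_law,gc_dropout see above.
#' @param fn_base_rate,depth_fn_cutoff,fp_rate,repeat_fp_multiplier see
#'   above.
#' @param allele_bias,minor_read_rate,het_call_cutoff see above.
#' @return An object of class `platform_profile`.
#' @seealso [default_profiles()], [neutral_profiles()], [simulate_platform()]
#' @export
platform_profile <- function(name,
                             depth_law = list(type = "normal", mean = 37,
                                              sd = 10),
                             gc_dropout = list(threshold = 0.60,
                                               dropout_prob = 0,
                                               attenuation = 0.1),
                             fn_base_rate = 0,
                             depth_fn_cutoff = 4,
                             fp_rate = 0,
                             repeat_fp_multiplier = 1,
                             allele_bias = 1,
                             minor_read_rate = 0,
                             het_call_cutoff = 0.2) {
  probs <- c(gc_dropout$dropout_prob, fn_base_rate, minor_read_rate,
             het_call_cutoff)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (gc_dropout$attenuation <= 0 || gc_dropout$attenuation > 1)
    stopf("attenuation must lie in (0, 1]")
  if (depth_law$type == "normal" && depth_law$mean <= 0)
    stopf("depth mean must be positive")
  if (allele_bias < 0) stopf("allele_bias must be >= 0")
  structure(list(name = name, depth_law = depth_law,
                 gc_dropout = gc_dropout, fn_base_rate = fn_base_rate,
                 depth_fn_cutoff = depth_fn_cutoff, fp_rate = fp_rate,
                 repeat_fp_multiplier = repeat_fp_multiplier,
                 allele_bias = allele_bias,
                 minor_read_rate = minor_read_rate,
                 het_call_cutoff = het_call_cutoff),
            class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  dl <- x$depth_law
  law <- if (dl$type == "normal")
    sprintf("normal(mean %s, sd %s)", dl$mean, dl$sd)
  else sprintf("lognormal(median %s, sdlog %s)",
               round(exp(dl$meanlog), 1), dl$sdlog)
  cat(sprintf("platform_profile '%s': depth %s; fn %.2g; fp %.2g/Mb; eps %.2g\n",
              x$name, law, x$fn_base_rate, x$fp_rate, x$minor_read_rate))
  invisible(x)
}

#' Default three-platform simulation profiles
#'
#' Profiles calibrated to the phenomenology of the three assays compared in
#' this package's validation studies:
#' \itemize{
#'   \item \strong{WGS} (PCR-free whole genome): symmetric depth,
#'     normal(37, 10) — mean equals median at 37 and about 0.3% of bases
#'     fall below 10x; no capture dropout; minor-read rate
#'     7.4e-4, putting the expected fraction of homozygous calls with a
#'     minor-allele read near 2.7% at this depth.
#'   \item \strong{WES} (exome capture): right-skewed depth,
#'     lognormal(median 265, sdlog 0.672), mean about 332; GC-rich windows
#'     drop out with probability 0.2; minor-read rate 4.2e-4 (about 10.5%
#'     of homozygous calls with a minor read at this depth law).
#'   \item \strong{HES} (targeted panel enrichment): lognormal(median 431,
#'     sdlog 0.473), mean about 482; stronger GC dropout (0.5) and a higher
#'     false-negative rate (0.9%); extra false positives in repeats;
#'     mild allelic capture bias; minor-read rate 5.5e-4 (about 21.2%
#'     hom-minor fraction at this depth law).
#' }
#' Depth-law dispersions and dropout probabilities are calibration choices
#' (the target statistics constrain only means, medians and rates); they are
#' documented in the package vignette.
#'
#' @return Named list of three [platform_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    WGS = platform_profile(
      "WGS",
      depth_law = list(type = "normal", mean = 37, sd = 10),
      gc_dropout = list(threshold = 0.60, dropout_prob = 0,
                        attenuation = 0.1),
      fn_base_rate = 0.0009, depth_fn_cutoff = 4,
      fp_rate = 9, repeat_fp_multiplier = 1,
      allele_bias = 1, minor_read_rate = 7.4e-4),
    WES = platform_profile(
      "WES",
      depth_law = list(type = "lognormal", meanlog = log(265),
                       sdlog = 0.672),
      gc_dropout = list(threshold = 0.60, dropout_prob = 0.2,
                        attenuation = 0.1),
      fn_base_rate = 0.0018, depth_fn_cutoff = 4,
      fp_rate = 0.5, repeat_fp_multiplier = 1,
      allele_bias = 1, minor_read_rate = 4.2e-4),
    HES = platform_profile(
      "HES",
      depth_law = list(type = "lognormal", meanlog = log(431),
                       sdlog = 0.473),
      gc_dropout = list(threshold = 0.60, dropout_prob = 0.5,
                        attenuation = 0.1),
      fn_base_rate = 0.009, depth_fn_cutoff = 4,
      fp_rate = 7, repeat_fp_multiplier = 3,
      allele_bias = 0.85, minor_read_rate = 5.5e-4))
}

#' Noise-free simulation profiles
#'
#' Profiles with every error and bias parameter at its neutral value
#' (no false negatives or positives, no minor-allele error reads, unbiased
#' alleles, no GC dropout) and constant depth far above every cutoff. An
#' end-to-end run on callsets simulated with these profiles must produce
#' zero exclusive variants, zero missed variants, no discordant genotypes,
#' and 100% sensitivity for every method — the simulator's noiseless-limit
#' contract.
#'
#' @param names platform labels (default `c("WGS", "WES", "HES")`).
#' @param depth constant per-base depth (default 100).
#' @return Named list of [platform_profile()] objects.
#' @export
neutral_profiles <- function(names = c("WGS", "WES", "HES"), depth = 100) {
  out <- lapply(names, function(nm) platform_profile(
    nm,
    depth_law = list(type = "normal", mean = depth, sd = 0),
    gc_dropout = list(threshold = 0.60, dropout_prob = 0, attenuation = 1),
    fn_base_rate = 0, depth_fn_cutoff = 1, fp_rate = 0,
    repeat_fp_multiplier = 1, allele_bias = 1, minor_read_rate = 0))
  names(out) <- names
  out
}
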