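#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero,
#' the convention used for all printed percentages in this package (base R's
#' `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.25, 1)   # 0.3
#' round_half_up(99.85, 1)  # 99.9
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## canonical variant key string, unique per (chrom, pos, ref, alt)
vkey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## ordered factor index used to sort output tables by (chrom, pos)
order_calls <- function(df) {
  df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

## derive a reproducible substream seed from a master seed and stream indices.
## Streams are laid out on a fixed (platform, sample) grid so that adding a
## sample or platform never perturbs the draws of another stream.
substream_seed <- function(master, platform_index, sample_index = 0L) {
  master <- as.double(master) %% 1048573
  s <- (master * 1009 + as.double(platform_index) * 131071 +
        as.double(sample_index) * 524287) %% 2147483629
  as.integer(s) + 1L
}

## run expr with a local RNG state seeded at `seed`; restores caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
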