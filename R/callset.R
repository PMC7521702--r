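#' SNV call sets
#'
#' A `callset` holds the single-nucleotide substitution calls of one
#' sequencing method for one sample, with the genotype, total read depth (DP)
#' and per-allele read counts (AD) that the quality filters use. Calls are
#' identified across methods by (chrom, pos, ref, alt) only; the genotype is
#' deliberately not part of the identity, so that loci called by several
#' methods with discordant genotypes are treated as shared, not exclusive
#' (discordance is reported separately by [genotype_discordance()]).
#'
#' @param calls data frame with columns `chrom` (character), `pos` (1-based
#'   integer), `ref`, `alt` (single bases A/C/G/T, `ref != alt`), `genotype`
#'   (`"het"` or `"hom_alt"`), `depth`, `ref_reads`, `alt_reads` (integers;
#'   `NA` marks unknown — such calls still count for presence but can never
#'   pass quality filtering).
#' @param method method label (e.g. `"WGS"`).
#' @param sample sample identifier.
#' @param capture optional `region_set` of the method's captured regions.
#' @return An object of class `callset`.
#' @export
callset <- function(calls, method, sample, capture = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "genotype",
            "depth", "ref_reads", "alt_reads")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stopf("calls missing columns: %s",
                          paste(miss, collapse = ", "))
  calls <- as.data.frame(calls)[need]
  for (col in c("pos", "depth", "ref_reads", "alt_reads"))
    calls[[col]] <- as.integer(calls[[col]])
  bases <- c("A", "C", "G", "T")
  bad <- !(calls$ref %in% bases) | !(calls$alt %in% bases) |
    calls$ref == calls$alt
  if (any(bad)) stopf("call %d is not a single-nucleotide substitution (%s>%s)",
                      which(bad)[1], calls$ref[which(bad)[1]],
                      calls$alt[which(bad)[1]])
  if (!all(calls$genotype %in% c("het", "hom_alt")))
    stopf("genotype must be 'het' or 'hom_alt'")
  ok <- is.na(calls$depth) | calls$depth >= 0
  if (!all(ok)) stopf("negative depth in call %d", which(!ok)[1])
  ad_known <- !is.na(calls$ref_reads) & !is.na(calls$alt_reads) &
    !is.na(calls$depth)
  over <- ad_known & (calls$ref_reads + calls$alt_reads > calls$depth)
  if (any(over))
    stopf("call %d has ref_reads + alt_reads > depth", which(over)[1])
  key <- vkey(calls$chrom, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(key))
    stopf("duplicate call for %s", key[duplicated(key)][1])
  calls <- order_calls(calls)
  rownames(calls) <- NULL
  structure(list(method = method, sample = sample,
                 calls = calls, capture = capture),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("callset: method %s, sample %s, %d SNV call%s (%d het, %d hom_alt)\n",
              x$method, x$sample, nrow(x$calls),
              if (nrow(x$calls) == 1) "" else "s",
              sum(x$calls$genotype == "het"),
              sum(x$calls$genotype == "hom_alt")))
  invisible(x)
}

#' @export
length.callset <- function(x) nrow(x$calls)

call_keys <- function(cs) {
  vkey(cs$calls$chrom, cs$calls$pos, cs$calls$ref, cs$calls$alt)
}

#' Allele balance of variant calls
#'
#' The allele balance (AB) of a call is the minor-allele read count divided
#' by the total allele-supporting reads: `min(ref_reads, alt_reads) /
#' (ref_reads + alt_reads)`. It lies in `[0, 0.5]`; 0.5 is perfectly
#' balanced, 0 is a perfect homozygote. `NA` is returned when the allele
#' counts are unknown or sum to zero.
#'
#' @param x a `callset`, or a numeric vector of reference-allele read counts.
#' @param alt_reads numeric vector of alternate-allele read counts (only when
#'   `x` is numeric).
#' @return Numeric vector of allele balances in `[0, 0.5]` (with `NA`s).
#' @examples
#' allele_balance(60, 40)  # 0.4
#' allele_balance(0, 80)   # 0
#' @export
allele_balance <- function(x, alt_reads = NULL) {
  if (inherits(x, "callset")) {
    ref <- x$calls$ref_reads
    alt <- x$calls$alt_reads
  } else {
    ref <- x
    alt <- alt_reads
  }
  tot <- ref + alt
  ab <- pmin(ref, alt) / tot
  ab[!is.na(tot) & tot == 0] <- NA_real_
  ab
}

#' Restrict a callset to a region set
#'
#' Keeps only the calls whose position falls inside `r`. This is the
#' restriction applied before every between-method comparison, so that a
#' method is never penalised for regions it was not designed to sequence.
#'
#' @param cs a `callset`.
#' @param r a `region_set`.
#' @return A `callset` containing the retained calls.
#' @export
restrict_calls <- function(cs, r) {
  stopifnot(inherits(cs, "callset"), inherits(r, "region_set"))
  keep <- if (nrow(cs$calls)) {
    region_contains(r, cs$calls$chrom, cs$calls$pos)
  } else logical()
  cs$calls <- cs$calls[keep, , drop = FALSE]
  rownames(cs$calls) <- NULL
  cs
}
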