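#' Stratify calls by allele balance
#'
#' Heterozygous calls are binned on allele balance into five categories —
#' `[0, 0.1)`, `[0.1, 0.2)`, `[0.2, 0.3)`, `[0.3, 0.4)`, `[0.4, 0.5]` (the
#' last bin closed, since 0.5 is the maximum) — and homozygous-alternate
#' calls are split into AB = 0 (no minor-allele reads) versus AB > 0. For
#' each bin the fraction of calls (percent within genotype class) and the
#' quartiles of read depth are reported; rising depth across AB bins is the
#' signature that allele imbalance concentrates at low coverage.
#'
#' @param cs a `callset`, or a data frame of calls.
#' @return A data frame of class `ab_stratification`: `class`, `bin`, `n`,
#'   `percent`, `dp_q1`, `dp_median`, `dp_q3`. Calls with unknown AB or
#'   depth are excluded (and counted in the `n_excluded` attribute). An
#'   empty result is flagged with a warning.
#' @export
stratify_ab <- function(cs) {
  calls <- if (inherits(cs, "callset")) cs$calls else cs
  ab <- allele_balance(calls$ref_reads, calls$alt_reads)
  ok <- !is.na(ab) & !is.na(calls$depth)
  n_excluded <- sum(!ok)
  calls <- calls[ok, , drop = FALSE]
  ab <- ab[ok]
  het_edges <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  het_labels <- c("[0,0.1)", "[0.1,0.2)", "[0.2,0.3)", "[0.3,0.4)",
                  "[0.4,0.5]")
  rows <- list()
  qrow <- function(class, bin, sel) {
    d <- calls$depth[sel]
    q <- if (length(d)) stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(class = class, bin = bin, n = sum(sel), percent = NA_real_,
               dp_q1 = q[1], dp_median = q[2], dp_q3 = q[3],
               stringsAsFactors = FALSE)
  }
  het <- calls$genotype == "het"
  for (b in seq_along(het_labels)) {
    sel <- het & ab >= het_edges[b] &
      (if (b < length(het_labels)) ab < het_edges[b + 1]
       else ab <= het_edges[b + 1])
    rows[[length(rows) + 1L]] <- qrow("het", het_labels[b], sel)
  }
  hom <- calls$genotype == "hom_alt"
  rows[[length(rows) + 1L]] <- qrow("hom_alt", "AB=0", hom & ab == 0)
  rows[[length(rows) + 1L]] <- qrow("hom_alt", "AB>0", hom & ab > 0)
  out <- do.call(rbind, rows)
  for (cl in unique(out$class)) {
    tot <- sum(out$n[out$class == cl])
    out$percent[out$class == cl] <-
      if (tot > 0) 100 * out$n[out$class == cl] / tot else NA_real_
  }
  if (!nrow(calls)) warnf("no calls with known allele balance and depth")
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("ab_stratification", class(out))
  out
}

#' Trend test: read depth against allele balance in heterozygotes
#'
#' One-sided Spearman rank correlation testing for a positive association
#' between depth and allele balance among heterozygous calls: low-depth
#' sites are expected to show more allele imbalance, so depth should rise
#' with AB. Ties are handled with mid-ranks (the asymptotic test is used).
#'
#' @param cs a `callset` or data frame of calls; only heterozygous calls
#'   with known AB and depth are used.
#' @param alpha significance level (default 0.05).
#' @return A list with `statistic` (Spearman's rho), `p_value`, `n`,
#'   `significant` (p < alpha), and `direction` (`"increasing"` or
#'   `"decreasing"`).
#' @export
ab_dp_trend <- function(cs, alpha = 0.05) {
  calls <- if (inherits(cs, "callset")) cs$calls else cs
  ab <- allele_balance(calls$ref_reads, calls$alt_reads)
  sel <- calls$genotype == "het" & !is.na(ab) & !is.na(calls$depth)
  if (sum(sel) < 10)
    stopf("need at least 10 heterozygous calls with known AB and depth (have %d)",
          sum(sel))
  ct <- suppressWarnings(
    stats::cor.test(ab[sel], calls$depth[sel], method = "spearman",
                    alternative = "greater", exact = FALSE))
  rho <- unname(ct$estimate)
  list(statistic = rho, p_value = ct$p.value, n = sum(sel),
       significant = ct$p.value < alpha,
       direction = if (!is.na(rho) && rho < 0) "decreasing" else "increasing")
}

#' Fraction of homozygous calls with minor-allele reads
#'
#' Homozygous-alternate calls are expected to have allele balance 0; a
#' nonzero minor-allele read count reflects sequencing error, contamination
#' or mismapping, and its frequency grows with depth (more reads, more
#' chances of an erroneous one).
#'
#' @param cs a `callset` or data frame of calls.
#' @return Fraction (in `[0, 1]`) of homozygous-alternate calls with known
#'   allele counts that carry at least one minor-allele read; `NA` when
#'   there are none.
#' @export
hom_minor_fraction <- function(cs) {
  calls <- if (inherits(cs, "callset")) cs$calls else cs
  sel <- calls$genotype == "hom_alt" & !is.na(calls$ref_reads) &
    !is.na(calls$alt_reads)
  if (!any(sel)) return(NA_real_)
  minor <- pmin(calls$ref_reads[sel], calls$alt_reads[sel])
  mean(minor > 0)
}

#' Depth test for homozygous calls with minor-allele reads
#'
#' Among homozygous-alternate calls, tests whether the calls carrying at
#' least one minor-allele read have higher read depth than those without
#' (one-sided Mann–Whitney / Wilcoxon rank-sum test).
#'
#' @param cs a `callset` or data frame of calls; at least 10 homozygous
#'   calls with known allele counts and depth are required.
#' @param alpha significance level (default 0.05).
#' @return A list with `fraction_with_minor`, `n_with`, `n_without`,
#'   `statistic`, `p_value` and `significant`. When either group is empty
#'   the fraction is still reported and the test is skipped
#'   (`p_value = NA`) with a message.
#' @export
hom_minor_test <- function(cs, alpha = 0.05) {
  calls <- if (inherits(cs, "callset")) cs$calls else cs
  sel <- calls$genotype == "hom_alt" & !is.na(calls$ref_reads) &
    !is.na(calls$alt_reads) & !is.na(calls$depth)
  if (sum(sel) < 10)
    stopf("need at least 10 homozygous calls with known AD and depth (have %d)",
          sum(sel))
  minor <- pmin(calls$ref_reads[sel], calls$alt_reads[sel])
  depth <- calls$depth[sel]
  with_minor <- minor > 0
  frac <- mean(with_minor)
  if (!any(with_minor) || all(with_minor)) {
    message("one group is empty; depth test skipped")
    return(list(fraction_with_minor = frac, n_with = sum(with_minor),
                n_without = sum(!with_minor), statistic = NA_real_,
                p_value = NA_real_, significant = NA))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(depth[with_minor], depth[!with_minor],
                       alternative = "greater", exact = FALSE))
  list(fraction_with_minor = frac, n_with = sum(with_minor),
       n_without = sum(!with_minor), statistic = unname(wt$statistic),
       p_value = wt$p.value, significant = wt$p.value < alpha)
}
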