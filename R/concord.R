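#' Quality criteria for high-quality exclusive variants
#'
#' An exclusive (FE) variant is promoted to high-quality (HQFE) when its
#' read depth reaches the method's minimum (inclusive) and, for heterozygous
#' calls, its allele balance lies inside the window `[ab_low, ab_high]`
#' (inclusive at both ends). Homozygous-alternate calls are filtered on
#' depth alone: the allele-balance criterion is defined for balanced
#' heterozygotes only. Calls with unknown depth (or, for heterozygotes,
#' unknown allele counts) always fail.
#'
#' @param min_depth named numeric vector of per-method minimum depths.
#'   Defaults: 10x for the PCR-free whole-genome method, 40x for the two
#'   capture methods.
#' @param ab_low,ab_high allele-balance window for heterozygotes
#'   (defaults 0.2 and 0.5).
#' @return An object of class `quality_criteria`.
#' @export
quality_criteria <- function(min_depth = c(WGS = 10, WES = 40, HES = 40),
                             ab_low = 0.2, ab_high = 0.5) {
  if (!(ab_low >= 0 && ab_low < ab_high && ab_high <= 0.5))
    stopf("need 0 <= ab_low < ab_high <= 0.5")
  if (any(min_depth <= 0)) stopf("min_depth must be positive")
  structure(list(min_depth = min_depth, ab_low = ab_low, ab_high = ab_high),
            class = "quality_criteria")
}

criteria_depth <- function(criteria, method) {
  md <- criteria$min_depth
  if (!is.null(names(md)) && method %in% names(md)) return(md[[method]])
  if (length(md) == 1L) return(md[[1]])
  stopf("no min_depth entry for method '%s'", method)
}

#' Apply quality filtering to exclusive calls
#'
#' @param calls data frame of calls (as in a `callset`).
#' @param method method label, used to look up the depth cutoff.
#' @param criteria a [quality_criteria()] object.
#' @return Logical vector: does each call pass the HQFE criteria?
#' @examples
#' qc <- quality_criteria()
#' # het call, depth 12, AD (7,5): AB = 5/12 = 0.417, passes the WGS tier
#' hqfe_filter(data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G",
#'                        genotype = "het", depth = 12,
#'                        ref_reads = 7, alt_reads = 5), "WGS", qc)
#' @export
hqfe_filter <- function(calls, method, criteria = quality_criteria()) {
  if (inherits(calls, "callset")) {
    method <- calls$method
    calls <- calls$calls
  }
  if (!nrow(calls)) return(logical())
  md <- criteria_depth(criteria, method)
  ab <- allele_balance(calls$ref_reads, calls$alt_reads)
  depth_ok <- !is.na(calls$depth) & calls$depth >= md
  ab_ok <- calls$genotype != "het" |
    (!is.na(ab) & ab >= criteria$ab_low & ab <= criteria$ab_high)
  depth_ok & ab_ok
}

#' Pairwise comparison of two methods' call sets
#'
#' Restricts both call sets of one sample to a shared region and classifies
#' every variant key (chrom, pos, ref, alt) as shared (called by both) or
#' fully exclusive (FE — called by exactly one method; no quality filtering
#' is applied for a call to be FE). FE calls passing [quality_criteria()]
#' form the HQFE subsets.
#'
#' @param x,y `callset`s of the same sample from two methods.
#' @param region `region_set` restricting the comparison; default is the
#'   intersection of the two callsets' captures.
#' @param criteria a [quality_criteria()] object.
#' @return An object of class `pairwise_comparison`: method labels, the
#'   restriction region, the shared keys, and per-method data frames of FE
#'   calls with an `hqfe` flag, plus per-method tallies (`n_snv`, `n_fe`,
#'   `n_hqfe`).
#' @export
pairwise_compare <- function(x, y, region = NULL,
                             criteria = quality_criteria()) {
  stopifnot(inherits(x, "callset"), inherits(y, "callset"))
  if (!identical(x$sample, y$sample))
    stopf("callsets are from different samples ('%s' vs '%s')",
          x$sample, y$sample)
  if (is.null(region)) {
    if (is.null(x$capture) || is.null(y$capture))
      stopf("no region given and callsets carry no capture region")
    region <- region_intersect(x$capture, y$capture)
  }
  x <- restrict_calls(x, region)
  y <- restrict_calls(y, region)
  kx <- call_keys(x)
  ky <- call_keys(y)
  shared <- intersect(kx, ky)
  fe_x <- x$calls[!(kx %in% ky), , drop = FALSE]
  fe_y <- y$calls[!(ky %in% kx), , drop = FALSE]
  fe_x$hqfe <- hqfe_filter(fe_x, x$method, criteria)
  fe_y$hqfe <- hqfe_filter(fe_y, y$method, criteria)
  tallies <- data.frame(
    method = c(x$method, y$method),
    n_snv = c(nrow(x$calls), nrow(y$calls)),
    n_fe = c(nrow(fe_x), nrow(fe_y)),
    n_hqfe = c(sum(fe_x$hqfe), sum(fe_y$hqfe)),
    stringsAsFactors = FALSE)
  structure(list(method_x = x$method, method_y = y$method,
                 sample = x$sample, region = region, shared = shared,
                 fe_x = fe_x, fe_y = fe_y, tallies = tallies,
                 criteria = criteria),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("pairwise comparison %s vs %s (sample %s), %s shared bases\n",
              x$method_x, x$method_y, x$sample,
              format(total_bases(x$region), big.mark = ",")))
  cat(sprintf("  shared SNVs: %d\n", length(x$shared)))
  t <- x$tallies
  for (i in 1:2)
    cat(sprintf("  %s: %d SNVs, %d FE, %d HQFE\n",
                t$method[i], t$n_snv[i], t$n_fe[i], t$n_hqfe[i]))
  invisible(x)
}

#' Cohort-level pairwise comparison with per-sample medians
#'
#' Runs [pairwise_compare()] for every sample and summarizes the cohort the
#' way discordance tables are conventionally reported: the per-sample median
#' number of SNVs, FE and HQFE variants per method, with FE/HQFE expressed
#' as a percentage of the median SNV count (rounded half away from zero to
#' one decimal). The median of an even number of samples is the mean of the
#' two central order statistics.
#'
#' @param xs,ys lists of `callset`s (one per sample, same order) for the two
#'   methods.
#' @param region shared `region_set` for all samples.
#' @param criteria a [quality_criteria()] object.
#' @return A list of class `pairwise_cohort` with `comparisons` (per
#'   sample), `per_sample` (tall data frame of tallies) and `summary`
#'   (median table with percentage columns).
#' @export
pairwise_cohort <- function(xs, ys, region = NULL,
                            criteria = quality_criteria()) {
  stopifnot(length(xs) == length(ys), length(xs) >= 1)
  comps <- Map(function(x, y) pairwise_compare(x, y, region, criteria),
               xs, ys)
  per_sample <- do.call(rbind, lapply(comps, function(cp) {
    cbind(sample = cp$sample, cp$tallies)
  }))
  med <- function(v) stats::median(v)
  summary <- do.call(rbind, lapply(split(per_sample, per_sample$method),
    function(d) {
      snv <- med(d$n_snv)
      fe <- med(d$n_fe)
      hqfe <- med(d$n_hqfe)
      data.frame(method = d$method[1], median_snv = snv, median_fe = fe,
                 median_hqfe = hqfe,
                 fe_pct = exclusive_percent(fe, snv),
                 hqfe_pct = exclusive_percent(hqfe, snv),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  structure(list(comparisons = comps, per_sample = per_sample,
                 summary = summary),
            class = "pairwise_cohort")
}

#' @export
print.pairwise_cohort <- function(x, ...) {
  cat(sprintf("pairwise cohort comparison over %d samples\n",
              length(x$comparisons)))
  print(x$summary)
  invisible(x)
}

#' Exclusive-variant percentage of the SNV count
#'
#' The convention used in discordance tables: an FE (or HQFE) count as a
#' percentage of the SNV count, rounded half away from zero to one decimal.
#'
#' @param n_exclusive FE or HQFE count (typically a per-sample median).
#' @param n_snv SNV count (same unit).
#' @return Percentage, one decimal.
#' @examples
#' exclusive_percent(6, 402)   # 1.5
#' exclusive_percent(17, 636)  # 2.7
#' @export
exclusive_percent <- function(n_exclusive, n_snv) {
  if (n_snv == 0) return(NA_real_)
  round_half_up(100 * n_exclusive / n_snv, 1)
}

#' Detection sensitivity from confirmation counts
#'
#' The true positive rate of a method: confirmed variants divided by the
#' total of true positives (confirmed variants plus missed variants),
#' expressed as a percentage. Confirmed variants are those found by all
#' methods plus the method's exclusive variants confirmed by a third
#' method; missed variants (MVs) are the method's false negatives.
#'
#' @param confirmed_by_all variants detected by every method.
#' @param fe_confirmed the method's exclusive variants confirmed by a third
#'   method.
#' @param missed the method's missed variants.
#' @param digits decimals for rounding (half away from zero); `NULL` for
#'   the unrounded value.
#' @return Sensitivity in percent.
#' @examples
#' sensitivity(2252, 24, 2)  # 99.9
#' sensitivity(2252, 6, 20)  # 99.1
#' @export
sensitivity <- function(confirmed_by_all, fe_confirmed, missed, digits = 1) {
  tp <- confirmed_by_all + fe_confirmed
  denom <- tp + missed
  if (denom == 0) return(NA_real_)
  s <- 100 * tp / denom
  if (is.null(digits)) s else round_half_up(s, digits)
}

## classify the keys of three restricted callsets of one sample; returns the
## per-key presence pattern and per-method FE call frames with hqfe flags
threeway_classify <- function(cs_list, region, criteria) {
  cs_list <- lapply(cs_list, restrict_calls, r = region)
  keys <- lapply(cs_list, call_keys)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  present <- vapply(keys, function(k) all_keys %in% k,
                    logical(length(all_keys)))
  if (length(all_keys) == 1L) present <- matrix(present, nrow = 1)
  colnames(present) <- vapply(cs_list, function(c) c$method, character(1))
  list(callsets = cs_list, keys = keys, all_keys = all_keys,
       present = present)
}

#' Three-way confirmation, missed variants, and sensitivity
#'
#' The second stage of the comparison design: within the region sequenced by
#' all three methods, every variant key is classified by its presence
#' pattern. A key present in all three is confirmed by all methods. A key
#' present in exactly two is an exclusive (FE) variant of each of those two
#' (relative to the absent method) that is *confirmed* by the other — and is
#' simultaneously a missed variant (MV, a false negative) of the absent
#' method. A key private to one method is an unconfirmed FE variant.
#' Confirmation is presence-based: a genotype mismatch does not block it
#' (see [genotype_discordance()]).
#'
#' Per-method sensitivity is
#' `100 * (confirmed_by_all + fe_confirmed) / (confirmed_by_all +
#' fe_confirmed + missed)`.
#'
#' The HQFE tier repeats the bookkeeping counting only FE calls that pass
#' `criteria`; a missed variant is counted in the HQFE tier when the
#' corresponding call of at least one confirming method is HQFE.
#'
#' @param cs_list list of three `callset`s (one per method) of the same
#'   sample, or — for pooled cohort totals — a list of three lists of
#'   per-sample `callset`s aligned by sample.
#' @param region the triple-shared `region_set`; must be contained in every
#'   callset's capture (when captures are present).
#' @param criteria a [quality_criteria()] object.
#' @return An object of class `three_way_report`: `counts` (per-method data
#'   frame with `total_detected`, `confirmed_by_all`, `fe`, `fe_confirmed`,
#'   `fe_not_confirmed`, `missed`, `sensitivity_pct` for the FE tier and
#'   `hqfe*` columns for the HQFE tier), `per_sample` breakdown, and the FE
#'   call tables.
#' @export
three_way <- function(cs_list, region = NULL,
                      criteria = quality_criteria()) {
  single <- all(vapply(cs_list, inherits, logical(1), "callset"))
  groups <- if (single) lapply(cs_list, list) else cs_list
  stopifnot(length(groups) == 3)
  n_samples <- unique(vapply(groups, length, integer(1)))
  if (length(n_samples) != 1)
    stopf("the three methods have different numbers of samples")
  methods <- vapply(groups, function(g) g[[1]]$method, character(1))
  if (is.null(region)) {
    caps <- lapply(groups, function(g) g[[1]]$capture)
    if (any(vapply(caps, is.null, logical(1))))
      stopf("no region given and callsets carry no capture region")
    region <- region_intersect(region_intersect(caps[[1]], caps[[2]]),
                               caps[[3]], label = "triple")
  }
  for (g in groups) for (cs in g) {
    if (!is.null(cs$capture) &&
        total_bases(region_subtract(region, cs$capture)) > 0)
      stopf("region is not contained in the %s capture set", cs$method)
  }

  per_sample <- list()
  fe_tables <- list()
  for (s in seq_len(n_samples)) {
    trio <- lapply(groups, `[[`, s)
    samp <- unique(vapply(trio, function(c) c$sample, character(1)))
    if (length(samp) != 1)
      stopf("sample mismatch across methods: %s",
            paste(vapply(trio, function(c) c$sample, character(1)),
                  collapse = ", "))
    cl <- threeway_classify(trio, region, criteria)
    pres <- cl$present
    n_present <- rowSums(pres)
    ## hqfe status of each (key, method) call, NA when the method lacks it
    hq <- matrix(NA, nrow = length(cl$all_keys), ncol = 3,
                 dimnames = list(NULL, methods))
    for (m in 1:3) {
      cs <- cl$callsets[[m]]
      pass <- hqfe_filter(cs$calls, cs$method, criteria)
      hq[match(cl$keys[[m]], cl$all_keys), m] <- pass
    }
    rows <- lapply(1:3, function(m) {
      has <- pres[, m]
      others <- setdiff(1:3, m)
      conf_all <- has & n_present == 3
      fe <- has & n_present < 3
      fe_conf <- fe & n_present == 2
      missed <- !has & rowSums(pres[, others, drop = FALSE]) == 2
      hqfe <- fe & !is.na(hq[, m]) & hq[, m]
      hqfe_conf <- fe_conf & hqfe
      ## MV in the HQFE tier: confirmed by at least one HQFE call elsewhere
      other_hq <- hq[, others, drop = FALSE]
      other_hq[is.na(other_hq)] <- FALSE
      hqfe_missed <- missed & rowSums(other_hq) > 0
      data.frame(sample = samp, method = methods[m],
                 total_detected = sum(has),
                 confirmed_by_all = sum(conf_all),
                 fe = sum(fe), fe_confirmed = sum(fe_conf),
                 fe_not_confirmed = sum(fe & !fe_conf),
                 missed = sum(missed),
                 hqfe = sum(hqfe), hqfe_confirmed = sum(hqfe_conf),
                 hqfe_not_confirmed = sum(hqfe & !hqfe_conf),
                 hqfe_missed = sum(hqfe_missed),
                 stringsAsFactors = FALSE)
    })
    per_sample[[s]] <- do.call(rbind, rows)
    fe_tables[[s]] <- do.call(rbind, lapply(1:3, function(m) {
      cs <- cl$callsets[[m]]
      k <- cl$keys[[m]]
      idx <- match(k, cl$all_keys)
      fe_sel <- rowSums(pres)[idx] < 3
      if (!any(fe_sel)) return(NULL)
      df <- cs$calls[fe_sel, , drop = FALSE]
      df$method <- cs$method
      df$sample <- samp
      df$hqfe <- hq[idx[fe_sel], m]
      df$confirmed_by <- vapply(idx[fe_sel], function(i) {
        others <- setdiff(1:3, m)
        paste(methods[others][pres[i, others]], collapse = ",")
      }, character(1))
      df
    }))
  }
  per_sample <- do.call(rbind, per_sample)
  fe_calls <- do.call(rbind, fe_tables)

  counts <- do.call(rbind, lapply(methods, function(m) {
    d <- per_sample[per_sample$method == m, , drop = FALSE]
    tot <- colSums(d[, !(names(d) %in% c("sample", "method")), drop = FALSE])
    out <- as.data.frame(as.list(tot))
    out$method <- m
    out$sensitivity_pct <- sensitivity(out$confirmed_by_all,
                                       out$fe_confirmed, out$missed)
    out$hqfe_sensitivity_pct <- sensitivity(out$confirmed_by_all,
                                            out$hqfe_confirmed,
                                            out$hqfe_missed)
    out[, c("method", "total_detected", "confirmed_by_all", "fe",
            "fe_confirmed", "fe_not_confirmed", "missed", "sensitivity_pct",
            "hqfe", "hqfe_confirmed", "hqfe_not_confirmed", "hqfe_missed",
            "hqfe_sensitivity_pct")]
  }))
  rownames(counts) <- NULL
  structure(list(methods = methods, region = region, counts = counts,
                 per_sample = per_sample, fe_calls = fe_calls,
                 criteria = criteria, n_samples = n_samples),
            class = "three_way_report")
}

#' @export
print.three_way_report <- function(x, ...) {
  cat(sprintf(
    "three-way SNV detection report: %s; %d sample%s; %s shared bases\n",
    paste(x$methods, collapse = ", "), x$n_samples,
    if (x$n_samples == 1) "" else "s",
    format(total_bases(x$region), big.mark = ",")))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.three_way_report <- function(object, ...) object$counts

#' Genotype discordance across methods
#'
#' Finds variant keys called by at least two methods whose genotype labels
#' are not all equal among the methods that called them — the same locus
#' annotated heterozygous by one assay and homozygous by another, typically
#' a signature of allelic capture or amplification bias.
#'
#' @param cs_list list of `callset`s of the same sample (two or more
#'   methods), or a list of per-sample lists aligned by sample.
#' @param region optional `region_set` restriction.
#' @return Data frame with `sample`, `chrom`, `pos`, `ref`, `alt`, and one
#'   genotype column per method (`NA` when a method did not call the key).
#' @export
genotype_discordance <- function(cs_list, region = NULL) {
  single <- all(vapply(cs_list, inherits, logical(1), "callset"))
  groups <- if (single) lapply(cs_list, list) else cs_list
  methods <- vapply(groups, function(g) g[[1]]$method, character(1))
  n_samples <- length(groups[[1]])
  out <- list()
  for (s in seq_len(n_samples)) {
    trio <- lapply(groups, `[[`, s)
    if (!is.null(region)) trio <- lapply(trio, restrict_calls, r = region)
    keys <- lapply(trio, call_keys)
    all_keys <- unique(unlist(keys, use.names = FALSE))
    if (!length(all_keys)) next
    gt <- vapply(seq_along(trio), function(m) {
      g <- rep(NA_character_, length(all_keys))
      g[match(keys[[m]], all_keys)] <- trio[[m]]$calls$genotype
      g
    }, character(length(all_keys)))
    gt <- matrix(gt, ncol = length(trio),
                 dimnames = list(NULL, methods))
    n_called <- rowSums(!is.na(gt))
    n_distinct <- apply(gt, 1, function(r) length(unique(stats::na.omit(r))))
    disc <- n_called >= 2 & n_distinct > 1
    if (!any(disc)) next
    parts <- strsplit(all_keys[disc], ":", fixed = TRUE)
    df <- data.frame(sample = trio[[1]]$sample,
                     chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)),
                     ref = vapply(parts, `[`, "", 3),
                     alt = vapply(parts, `[`, "", 4),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(gt[disc, , drop = FALSE]))
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) {
    df <- data.frame(sample = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     stringsAsFactors = FALSE)
    for (m in methods) df[[m]] <- character()
    return(df)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate exclusive calls with repeat and GC-rich membership
#'
#' Tags each call with whether its position lies in a repetitive region and
#' whether it lies in GC-rich territory, and summarizes the tagged fractions
#' per method. Exclusive variants cluster in both kinds of region for
#' capture-based assays.
#'
#' @param fe_calls data frame of calls with `chrom`, `pos`, `method` columns
#'   (e.g. the `fe_calls` table of a [three_way()] report).
#' @param repeats `region_set` of repetitive regions (may be empty).
#' @param gc_rich `region_set` of GC-rich regions (e.g. from
#'   [gc_windows()]; may be empty).
#' @return A list with `calls` (the input plus logical `in_repeat`,
#'   `in_gc_rich`) and `summary` (per-method fractions).
#' @export
annotate_fe <- function(fe_calls, repeats = NULL, gc_rich = NULL) {
  df <- fe_calls
  tag <- function(rs) {
    if (is.null(rs) || !nrow(df)) return(rep(FALSE, nrow(df)))
    region_contains(rs, df$chrom, df$pos)
  }
  df$in_repeat <- tag(repeats)
  df$in_gc_rich <- tag(gc_rich)
  summ <- if (nrow(df)) {
    do.call(rbind, lapply(split(df, df$method), function(d) {
      data.frame(method = d$method[1], n = nrow(d),
                 frac_in_repeat = mean(d$in_repeat),
                 frac_in_gc_rich = mean(d$in_gc_rich),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(method = character(), n = integer(),
                    frac_in_repeat = numeric(), frac_in_gc_rich = numeric())
  rownames(summ) <- NULL
  list(calls = df, summary = summ)
}
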