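#' Run the full two-step comparison workflow
#'
#' Orchestrates the complete analysis from files on disk: reads the capture
#' designs and per-(method, sample) VCFs, runs the three pairwise
#' comparisons on pairwise-intersected captures (step 1), the three-way
#' confirmation/missed-variant report on the triple intersection (step 2),
#' coverage summaries and per-gene low-coverage reports, allele-balance /
#' read-depth stratification with trend tests, genotype discordance, and
#' repeat/GC annotation of exclusive variants. All tables are written as
#' deterministic, sorted TSVs together with a JSON run manifest and a
#' timestamped plain-text log.
#'
#' @param config a list (as returned by [write_cohort()]) with elements:
#'   `methods` (labels; three required), `samples`, `vcf` and `depth_tsv`
#'   (nested path lists `[[method]][[sample]]`; depth optional),
#'   `capture_bed` (per-method paths), `gene_bed`, optional `repeat_bed`
#'   and `reference_fasta`, `criteria` (a [quality_criteria()]),
#'   `low_cutoffs` (named per-method depth cutoffs), and `outdir`.
#' @param verbose log progress to the console as well as the log file.
#' @return An object of class `concordance_run`: all computed tables plus
#'   the output paths.
#' @export
run_full_analysis <- function(config, verbose = FALSE) {
  t0 <- Sys.time()
  outdir <- config$outdir %||% stopf("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  methods <- config$methods
  if (length(methods) != 3) stopf("three methods are required")
  samples <- config$samples
  if (!length(samples)) stopf("no samples configured")
  criteria <- config$criteria %||% quality_criteria(
    min_depth = stats::setNames(c(10, 40, 40), methods))
  cutoffs <- config$low_cutoffs %||%
    stats::setNames(c(10, 40, 40), methods)
  log("run started: methods %s, %d samples", paste(methods, collapse = "/"),
      length(samples))

  captures <- lapply(methods, function(m)
    read_bed(config$capture_bed[[m]], label = m))
  names(captures) <- methods
  for (m in methods)
    log("capture %s: %s bases", m,
        format(total_bases(captures[[m]]), big.mark = ","))

  ## ingest callsets; a sample missing any method's VCF is skipped
  callsets <- stats::setNames(vector("list", length(methods)), methods)
  kept <- character()
  for (s in samples) {
    ok <- all(vapply(methods, function(m)
      file.exists(config$vcf[[m]][[s]] %||% ""), logical(1)))
    if (!ok) {
      warnf("sample %s skipped: missing VCF", s)
      log("sample %s skipped (missing VCF)", s)
      next
    }
    for (m in methods)
      callsets[[m]][[s]] <- read_vcf(config$vcf[[m]][[s]], method = m,
                                     sample = s, capture = captures[[m]],
                                     verbose = FALSE)
    kept <- c(kept, s)
  }
  if (!length(kept)) stopf("no usable samples")
  log("%d of %d samples usable", length(kept), length(samples))

  ## step 1: pairwise comparisons on pairwise-intersected captures
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  pairwise <- list()
  table1 <- list()
  for (pr in pairs) {
    region <- region_intersect(captures[[pr[1]]], captures[[pr[2]]])
    pc <- pairwise_cohort(callsets[[pr[1]]], callsets[[pr[2]]],
                          region = region, criteria = criteria)
    key <- paste(pr, collapse = "_vs_")
    pairwise[[key]] <- pc
    s <- pc$summary
    s$comparison <- key
    s$region_bases <- total_bases(region)
    table1[[key]] <- s
    log("pairwise %s: %s shared bases", key,
        format(total_bases(region), big.mark = ","))
  }
  table1 <- do.call(rbind, table1)
  rownames(table1) <- NULL

  ## step 2: three-way report on the triple intersection
  triple <- Reduce(region_intersect, captures)
  triple$label <- "triple"
  log("triple-shared region: %s bases",
      format(total_bases(triple), big.mark = ","))
  report <- three_way(callsets, region = triple, criteria = criteria)

  ## coverage summaries and per-gene low-coverage reports
  genes <- if (!is.null(config$gene_bed)) read_gene_bed(config$gene_bed)
           else NULL
  coverage <- NULL
  per_gene <- NULL
  if (!is.null(config$depth_tsv)) {
    cov_rows <- list()
    gene_rows <- list()
    for (m in methods) {
      for (s in kept) {
        path <- config$depth_tsv[[m]][[s]] %||% ""
        if (!file.exists(path)) next
        tr <- read_depth_tsv(path, captures[[m]], method = m, sample = s)
        sm <- summarize_depth(tr, cutoff = cutoffs[[m]])
        cov_rows[[length(cov_rows) + 1L]] <- data.frame(
          method = m, sample = s, mean = sm$mean, median = sm$median,
          low_fraction = sm$low_fraction, cutoff = cutoffs[[m]],
          stringsAsFactors = FALSE)
        if (!is.null(genes)) {
          pg <- per_gene_low_fraction(tr, genes, cutoff = cutoffs[[m]])
          pg$method <- m
          pg$sample <- s
          gene_rows[[length(gene_rows) + 1L]] <- pg
        }
      }
    }
    coverage <- do.call(rbind, cov_rows)
    if (length(gene_rows)) {
      all_pg <- do.call(rbind, gene_rows)
      ## average per-gene fractions over samples, per method
      per_gene <- do.call(rbind, lapply(
        split(all_pg, list(all_pg$method, all_pg$gene), drop = TRUE),
        function(d) data.frame(method = d$method[1], gene = d$gene[1],
                               acmg_flag = d$acmg_flag[1],
                               low_fraction = mean(d$low_fraction),
                               mean_depth = mean(d$mean_depth),
                               stringsAsFactors = FALSE)))
      per_gene <- per_gene[order(per_gene$method, -per_gene$low_fraction,
                                 per_gene$gene), ]
      rownames(per_gene) <- NULL
    }
    log("coverage summarized for %d (method, sample) tracks",
        length(cov_rows))
  }

  ## allele balance / depth analyses on triple-region calls, pooled
  abdp <- list()
  for (m in methods) {
    pooled <- do.call(rbind, lapply(kept, function(s)
      restrict_calls(callsets[[m]][[s]], triple)$calls))
    strat <- tryCatch(stratify_ab(pooled), warning = function(w) NULL)
    trend <- tryCatch(ab_dp_trend(pooled), error = function(e) {
      log("ab_dp_trend (%s) skipped: %s", m, conditionMessage(e))
      NULL
    })
    hom <- tryCatch(hom_minor_test(pooled), error = function(e) {
      log("hom_minor_test (%s) skipped: %s", m, conditionMessage(e))
      NULL
    })
    abdp[[m]] <- list(stratification = strat, trend = trend,
                      hom_minor = hom)
  }

  ## genotype discordance across methods, within the triple region
  discordance <- genotype_discordance(callsets, region = triple)
  log("discordant-genotype loci: %d", nrow(discordance))

  ## FE annotation with repeats and GC-rich regions
  repeats <- if (!is.null(config$repeat_bed) &&
                 file.exists(config$repeat_bed))
    read_bed(config$repeat_bed, label = "repeats") else NULL
  gc_rich <- if (!is.null(config$reference_fasta) &&
                 file.exists(config$reference_fasta)) {
    reference <- Biostrings::readDNAStringSet(config$reference_fasta)
    names(reference) <- sub("\\s.*$", "", names(reference))
    gc_windows(reference)
  } else NULL
  fe_annot <- if (!is.null(report$fe_calls) && nrow(report$fe_calls))
    annotate_fe(report$fe_calls, repeats, gc_rich) else NULL

  ## write outputs (deterministically sorted)
  o <- function(...) file.path(outdir, ...)
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- list(
    table1 = wt(table1[order(table1$comparison, table1$method), ],
                o("pairwise_exclusive.tsv")),
    table2 = wt(report$counts, o("threeway_report.tsv")),
    per_sample = wt(report$per_sample, o("threeway_per_sample.tsv")),
    discordance = wt(discordance, o("discordant_genotypes.tsv")))
  if (!is.null(report$fe_calls) && nrow(report$fe_calls)) {
    fe_out <- if (!is.null(fe_annot)) fe_annot$calls else report$fe_calls
    fe_out <- fe_out[order(fe_out$method, fe_out$sample, fe_out$chrom,
                           fe_out$pos), ]
    paths$fe_calls <- wt(fe_out, o("fe_variants.tsv"))
  }
  if (!is.null(coverage)) paths$coverage <- wt(coverage, o("coverage.tsv"))
  if (!is.null(per_gene))
    paths$per_gene <- wt(per_gene, o("per_gene_low_coverage.tsv"))
  strat_rows <- do.call(rbind, lapply(methods, function(m) {
    st <- abdp[[m]]$stratification
    if (is.null(st)) return(NULL)
    cbind(method = m, as.data.frame(st))
  }))
  if (!is.null(strat_rows))
    paths$ab_strata <- wt(strat_rows, o("ab_dp_strata.tsv"))

  manifest <- list(
    package = "snvconcord",
    version = as.character(utils::packageVersion("snvconcord")),
    r_version = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    methods = methods, samples_used = kept,
    region_bases = list(
      pairwise = stats::setNames(
        lapply(pairs, function(pr) total_bases(
          region_intersect(captures[[pr[1]]], captures[[pr[2]]]))),
        vapply(pairs, paste, "", collapse = "_vs_")),
      triple = total_bases(triple)),
    criteria = list(min_depth = as.list(criteria$min_depth),
                    ab_low = criteria$ab_low, ab_high = criteria$ab_high),
    low_cutoffs = as.list(cutoffs),
    tests = lapply(abdp, function(a) list(
      trend_p = a$trend$p_value %||% NA,
      hom_minor_fraction = a$hom_minor$fraction_with_minor %||% NA,
      hom_minor_p = a$hom_minor$p_value %||% NA)),
    outputs = paths)
  jsonlite::write_json(manifest, o("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("run finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  writeLines(log_lines, o("run_log.txt"))

  structure(list(table1 = table1, report = report, pairwise = pairwise,
                 coverage = coverage, per_gene = per_gene, abdp = abdp,
                 discordance = discordance, fe_annotation = fe_annot,
                 triple_region = triple, captures = captures,
                 paths = paths, manifest = manifest, outdir = outdir),
            class = "concordance_run")
}

#' @export
print.concordance_run <- function(x, ...) {
  cat("concordance_run\n")
  cat(sprintf("  triple-shared region: %s bases\n",
              format(total_bases(x$triple_region), big.mark = ",")))
  print(x$report)
  cat(sprintf("  outputs in %s\n", x$outdir))
  invisible(x)
}
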