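#' Gene models as flat interval sets
#'
#' A gene model is a gene symbol plus the region set of its exons (with any
#' flanking bases the capture design adds) and a flag marking membership of
#' the ACMG SF v.2.0 secondary-findings list. Transcript structure is not
#' modelled; per-gene coverage reporting only needs the base set.
#'
#' @param symbol character vector of gene symbols (unique).
#' @param intervals a single `region_set`, or a list of `region_set`s, one
#'   per gene.
#' @param acmg_flag logical vector: is the gene on the ACMG SF v.2.0 list?
#'   Defaults to membership of [acmg_sf2_genes()].
#' @return An object of class `gene_models`: a list with elements `symbol`,
#'   `acmg_flag`, and `regions` (a named list of `region_set`s).
#' @export
gene_models <- function(symbol, intervals, acmg_flag = NULL) {
  if (inherits(intervals, "region_set")) intervals <- list(intervals)
  if (anyDuplicated(symbol))
    stopf("duplicated gene symbol: %s", symbol[duplicated(symbol)][1])
  if (length(symbol) != length(intervals))
    stopf("need one region_set per gene symbol")
  empty <- vapply(intervals, function(r) total_bases(r) == 0, logical(1))
  if (any(empty)) stopf("gene %s has an empty interval set", symbol[empty][1])
  if (is.null(acmg_flag)) acmg_flag <- symbol %in% acmg_sf2_genes()
  names(intervals) <- symbol
  structure(list(symbol = as.character(symbol),
                 acmg_flag = as.logical(acmg_flag),
                 regions = intervals),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d ACMG-flagged), %s bases total\n",
              length(x$symbol), sum(x$acmg_flag),
              format(sum(vapply(x$regions, total_bases, numeric(1))),
                     big.mark = ",")))
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$symbol)

#' The 20 ACMG SF v.2.0 genes among the studied cardiac panel
#'
#' Returns the bundled list of the cardiomyopathy/channelopathy panel genes
#' that appear on the ACMG SF v.2.0 secondary-findings list; per-gene
#' coverage reports flag these genes.
#'
#' @return Character vector of 20 gene symbols.
#' @export
acmg_sf2_genes <- function() {
  path <- system.file("extdata", "acmg_sf2_genes.txt",
                      package = "snvconcord", mustWork = TRUE)
  readLines(path)
}

#' Read gene models from an extended BED file
#'
#' Expects columns: chrom, start (0-based), end, gene symbol, and optionally
#' an ACMG flag (0/1). Rows sharing a symbol are merged into one gene model.
#' When the flag column is absent, flags default to membership of
#' [acmg_sf2_genes()].
#'
#' @param path path to the BED-like file (tab-separated, no header).
#' @return A `gene_models` object.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("gene BED needs >= 4 columns (4th = gene symbol)")
  syms <- unique(df[[4]])
  regions <- lapply(syms, function(s) {
    sub <- df[df[[4]] == s, , drop = FALSE]
    region_set(sub[[1]], sub[[2]], sub[[3]], label = s)
  })
  flags <- if (ncol(df) >= 5) {
    vapply(syms, function(s) any(df[df[[4]] == s, 5] != 0), logical(1))
  } else NULL
  gene_models(syms, regions, acmg_flag = flags)
}

#' Write gene models as an extended BED file
#'
#' @param x a `gene_models` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_bed <- function(x, path) {
  rows <- do.call(rbind, lapply(seq_along(x$symbol), function(i) {
    df <- as.data.frame(x$regions[[i]])
    df$name <- x$symbol[i]
    df$acmg <- as.integer(x$acmg_flag[i])
    df
  }))
  rows <- rows[order(rows$chrom, rows$start), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
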