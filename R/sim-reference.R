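#' Build a synthetic reference with genes, repeats, and capture designs
#'
#' Lays out `n_genes` genes on one synthetic chromosome, each with
#' `n_exons` exons separated by introns, genes separated by intergenic
#' spacers. The sequence is random at a background GC fraction, except that
#' a configurable number of genes get exons with elevated GC content
#' (achieved by exact per-exon G+C counts, so realized CDS GC matches the
#' target to within rounding) — these emulate the GC-rich genes that
#' capture-based assays cover poorly. Low-complexity repeat blocks (AT
#' tandem repeats) are planted downstream of the last exon of a subset of
#' genes, overlapping the captured flank.
#'
#' Three capture designs are derived:
#' \itemize{
#'   \item \strong{WGS}: the whole chromosome;
#'   \item \strong{HES}: every exon plus `flank` bases of adjacent intron;
#'   \item \strong{WES}: the HES design with a fraction `wes_omit_fraction`
#'     of exons omitted at random (exome kits target the most frequent
#'     transcripts, not every exon).
#' }
#' Gene models carry the exon-plus-flank intervals; a fraction of genes is
#' flagged as ACMG secondary-findings genes for per-gene reporting.
#'
#' @param n_genes number of genes (default 20).
#' @param n_exons exons per gene (default 5).
#' @param exon_size exon width in bases (default 150).
#' @param intron_size intron width (default 400).
#' @param intergenic intergenic spacer width (default 2000).
#' @param flank intronic bases captured on each side of an exon
#'   (default 25).
#' @param base_gc background GC fraction of the sequence (default 0.42).
#' @param gc_targets GC fractions for the high-GC genes (defaults 0.73,
#'   0.64, 0.69, 0.56; recycled/truncated to `n_gc_genes`).
#' @param n_gc_genes number of genes drawn with elevated GC (default 4).
#' @param wes_omit_fraction fraction of exons absent from the WES design
#'   (default 0.15).
#' @param repeat_every plant a repeat block after every `repeat_every`-th
#'   gene (default 4); the block covers the captured flank of the gene's
#'   last exon plus 100 bases of intron.
#' @param acmg_fraction fraction of genes flagged as ACMG-listed
#'   (default 0.2).
#' @param seed integer seed; output is deterministic given the seed.
#' @return An object of class `synthetic_reference`: list with `sequence`
#'   (named [Biostrings::DNAStringSet]), `genes` (`gene_models`, exon plus
#'   flank), `cds` (per-gene exon-only `region_set`s), `repeats`, `gc_rich`
#'   and `captures` (`region_set`s; `captures` is a named list WGS/WES/HES),
#'   plus `gc_gene_targets`.
#' @export
make_reference <- function(n_genes = 20, n_exons = 5, exon_size = 150,
                           intron_size = 400, intergenic = 2000,
                           flank = 25, base_gc = 0.42,
                           gc_targets = c(0.73, 0.64, 0.69, 0.56),
                           n_gc_genes = 4, wes_omit_fraction = 0.15,
                           repeat_every = 4, acmg_fraction = 0.2,
                           seed = 1) {
  if (n_genes < 1 || n_exons < 1 || exon_size < 1 || intron_size < flank)
    stopf("inconsistent sizes: need n_genes, n_exons, exon_size >= 1 and intron_size >= flank")
  if (n_gc_genes > n_genes) stopf("n_gc_genes exceeds n_genes")
  with_seed(seed, {
    gc_targets <- rep_len(gc_targets, max(n_gc_genes, 1))[seq_len(n_gc_genes)]
    gc_genes <- if (n_gc_genes) sort(sample.int(n_genes, n_gc_genes)) else
      integer()

    gene_span <- n_exons * exon_size + (n_exons - 1) * intron_size
    chrom_len <- n_genes * (intergenic + gene_span) + intergenic
    chrom <- "chr1"

    base_seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE,
                       prob = c((1 - base_gc) / 2, base_gc / 2, base_gc / 2,
                                (1 - base_gc) / 2))

    exon_rows <- list()
    repeat_rows <- list()
    for (g in seq_len(n_genes)) {
      gene_start <- (g - 1) * (intergenic + gene_span) + intergenic
      starts <- gene_start + (seq_len(n_exons) - 1) * (exon_size + intron_size)
      ends <- starts + exon_size
      exon_rows[[g]] <- data.frame(gene = g, exon = seq_len(n_exons),
                                   start = starts, end = ends)
      if (g %in% gc_genes) {
        target <- gc_targets[match(g, gc_genes)]
        for (e in seq_len(n_exons)) {
          n_gc <- round(target * exon_size)
          exon_bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
                          sample(c("A", "T"), exon_size - n_gc,
                                 replace = TRUE))
          base_seq[(starts[e] + 1):ends[e]] <- sample(exon_bases)
        }
      }
      if (repeat_every > 0 && g %% repeat_every == 0) {
        rep_start <- ends[n_exons]           # last exon end, 0-based
        rep_end <- min(rep_start + flank + 100, chrom_len)
        base_seq[(rep_start + 1):rep_end] <-
          rep_len(c("A", "T"), rep_end - rep_start)
        repeat_rows[[length(repeat_rows) + 1L]] <-
          data.frame(start = rep_start, end = rep_end)
      }
    }
    exons <- do.call(rbind, exon_rows)

    sequence <- Biostrings::DNAStringSet(paste(base_seq, collapse = ""))
    names(sequence) <- chrom

    cap_start <- pmax(exons$start - flank, 0)
    cap_end <- pmin(exons$end + flank, chrom_len)
    hes <- region_set(rep(chrom, nrow(exons)), cap_start, cap_end,
                      label = "HES")
    keep <- stats::runif(nrow(exons)) >= wes_omit_fraction
    if (!any(keep)) keep[1] <- TRUE
    wes <- region_set(rep(chrom, sum(keep)), cap_start[keep], cap_end[keep],
                      label = "WES")
    wgs <- region_set(chrom, 0, chrom_len, label = "WGS")

    symbols <- sprintf("GENE%03d", seq_len(n_genes))
    acmg <- rep(FALSE, n_genes)
    n_acmg <- round(acmg_fraction * n_genes)
    if (n_acmg) acmg[sample.int(n_genes, n_acmg)] <- TRUE
    gene_regions <- lapply(seq_len(n_genes), function(g) {
      e <- exons[exons$gene == g, ]
      region_set(rep(chrom, nrow(e)), pmax(e$start - flank, 0),
                 pmin(e$end + flank, chrom_len), label = symbols[g])
    })
    genes <- gene_models(symbols, gene_regions, acmg_flag = acmg)
    ## exon-only (CDS) intervals, without the captured flank
    cds <- lapply(seq_len(n_genes), function(g) {
      e <- exons[exons$gene == g, ]
      region_set(rep(chrom, nrow(e)), e$start, e$end, label = symbols[g])
    })
    names(cds) <- symbols

    repeats <- if (length(repeat_rows)) {
      rr <- do.call(rbind, repeat_rows)
      region_set(rep(chrom, nrow(rr)), rr$start, rr$end, label = "repeats")
    } else region_set(label = "repeats")

    gc_rich <- gc_windows(sequence, window = 100, threshold = 0.60)
    names(gc_targets) <- symbols[gc_genes]

    structure(list(sequence = sequence, genes = genes, cds = cds,
                   repeats = repeats, gc_rich = gc_rich,
                   captures = list(WGS = wgs, WES = wes, HES = hes),
                   gc_gene_targets = gc_targets, flank = flank,
                   chrom = chrom, chrom_len = chrom_len, seed = seed),
              class = "synthetic_reference")
  })
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat(sprintf(
    "synthetic_reference: %s bases on %s; %d genes (%d high-GC, %d ACMG); captures WGS/WES/HES = %s/%s/%s bases\n",
    format(x$chrom_len, big.mark = ","), x$chrom, length(x$genes$symbol),
    length(x$gc_gene_targets), sum(x$genes$acmg_flag),
    format(total_bases(x$captures$WGS), big.mark = ","),
    format(total_bases(x$captures$WES), big.mark = ","),
    format(total_bases(x$captures$HES), big.mark = ",")))
  invisible(x)
}
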