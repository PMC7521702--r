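#' Per-base depth tracks
#'
#' A `depth_track` stores the read depth of every base of a region set, in
#' region order (regions sorted by chromosome and start, bases left to
#' right). It is the unit on which coverage summaries, low-coverage
#' fractions and per-gene reports are computed.
#'
#' @param depths integer vector of per-base depths, one per covered base,
#'   length `total_bases(regions)`.
#' @param regions a `region_set`.
#' @param method method label.
#' @param sample sample id.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(depths, regions, method = "", sample = "") {
  stopifnot(inherits(regions, "region_set"))
  if (length(depths) != total_bases(regions))
    stopf("depth vector length (%d) != total bases of regions (%d)",
          length(depths), total_bases(regions))
  if (any(depths < 0, na.rm = TRUE)) stopf("negative depth")
  structure(list(method = method, sample = sample,
                 regions = regions, depths = as.numeric(depths)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: method %s, sample %s, %s bases, mean depth %.1f\n",
              x$method, x$sample,
              format(length(x$depths), big.mark = ","), mean(x$depths)))
  invisible(x)
}

## genomic (chrom, pos 1-based) -> index into the track's depth vector;
## NA for positions outside the track regions
track_index <- function(track, chrom, pos) {
  df <- as.data.frame(track$regions)
  width <- df$end - df$start
  offset <- cumsum(c(0, width[-length(width)]))
  idx <- rep(NA_real_, length(chrom))
  for (k in seq_len(nrow(df))) {
    hit <- chrom == df$chrom[k] & pos >= df$start[k] + 1 & pos <= df$end[k]
    idx[hit] <- offset[k] + (pos[hit] - df$start[k])
  }
  idx
}

## per-base depths over an arbitrary region set; bases outside the track
## count as uncovered (depth 0)
depths_at <- function(track, rs) {
  df <- as.data.frame(rs)
  unlist(lapply(seq_len(nrow(df)), function(k) {
    pos <- seq.int(df$start[k] + 1, df$end[k])
    idx <- track_index(track, rep(df$chrom[k], length(pos)), pos)
    d <- rep(0, length(pos))
    d[!is.na(idx)] <- track$depths[idx[!is.na(idx)]]
    d
  }), use.names = FALSE) %||% numeric()
}

#' Read a per-base depth table into a depth track
#'
#' Expects a 3-column TSV (chrom, 1-based position, depth) as produced by
#' standard depth utilities (e.g. `samtools depth`). Positions inside
#' `regions` that are absent from the file get depth 0; positions outside
#' `regions` are ignored.
#'
#' @param path path to the TSV (no header).
#' @param regions `region_set` defining the track territory.
#' @param method,sample labels.
#' @return A `depth_track`.
#' @export
read_depth_tsv <- function(path, regions, method = "", sample = "") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "depth"),
                          colClasses = c("character", "numeric", "numeric"))
  depths <- rep(0, total_bases(regions))
  tr <- structure(list(regions = regions), class = "depth_track")
  idx <- track_index(tr, df$chrom, df$pos)
  keep <- !is.na(idx)
  depths[idx[keep]] <- df$depth[keep]
  depth_track(depths, regions, method = method, sample = sample)
}

#' Write a depth track as a 3-column TSV
#'
#' @param track a `depth_track`.
#' @param path output path.
#' @param omit_zero drop zero-depth bases (they are implicit on re-reading).
#' @return Invisibly, `path`.
#' @export
write_depth_tsv <- function(track, path, omit_zero = TRUE) {
  df <- as.data.frame(track$regions)
  rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(k) {
    data.frame(chrom = df$chrom[k],
               pos = seq.int(df$start[k] + 1, df$end[k]),
               stringsAsFactors = FALSE)
  }))
  rows$depth <- track$depths
  if (omit_zero) rows <- rows[rows$depth > 0, , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize a depth track
#'
#' Computes the mean and median per-base depth, the low-coverage fraction
#' (bases with depth strictly below `cutoff` divided by all bases), and a
#' depth histogram binned at width 1. The strict inequality matches the
#' definition of a low-covered base (`< 10x` for PCR-free whole-genome,
#' `< 40x` for capture assays).
#'
#' @param track a `depth_track`.
#' @param cutoff low-coverage depth cutoff (default 10).
#' @return A list of class `depth_summary` with elements `mean`, `median`,
#'   `low_fraction`, `cutoff`, `n_bases`, and `histogram` (data frame with
#'   `depth`, `count`).
#' @export
summarize_depth <- function(track, cutoff = 10) {
  stopifnot(inherits(track, "depth_track"))
  if (!length(track$depths)) stopf("empty depth track")
  if (cutoff <= 0) stopf("cutoff must be positive")
  d <- track$depths
  tab <- table(d)
  structure(list(mean = mean(d), median = stats::median(d),
                 low_fraction = mean(d < cutoff), cutoff = cutoff,
                 n_bases = length(d),
                 histogram = data.frame(depth = as.numeric(names(tab)),
                                        count = as.integer(tab))),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat(sprintf(
    "depth summary over %s bases: mean %.1f, median %.1f, %.1f%% below %sx\n",
    format(x$n_bases, big.mark = ","), x$mean, x$median,
    100 * x$low_fraction, x$cutoff))
  invisible(x)
}

#' Per-gene low-coverage report
#'
#' For each gene model, computes the fraction of its bases with depth
#' strictly below `cutoff` and the mean depth, with the gene's ACMG
#' secondary-findings flag carried through. Gene bases outside the track's
#' regions count as uncovered (depth 0). Overlapping genes are reported
#' independently.
#'
#' @param track a `depth_track`.
#' @param genes a `gene_models` object.
#' @param cutoff low-coverage depth cutoff.
#' @return Data frame with columns `gene`, `acmg_flag`, `n_bases`,
#'   `low_fraction`, `mean_depth`, sorted by decreasing `low_fraction`.
#' @export
per_gene_low_fraction <- function(track, genes, cutoff = 10) {
  stopifnot(inherits(track, "depth_track"), inherits(genes, "gene_models"))
  rows <- lapply(seq_along(genes$symbol), function(i) {
    d <- depths_at(track, genes$regions[[i]])
    if (!length(d)) stopf("gene %s has zero bases", genes$symbol[i])
    data.frame(gene = genes$symbol[i], acmg_flag = genes$acmg_flag[i],
               n_bases = length(d), low_fraction = mean(d < cutoff),
               mean_depth = mean(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$low_fraction, out$gene), ]
}

#' GC content of a region set
#'
#' @param regions a `region_set`.
#' @param reference a named [Biostrings::DNAStringSet] (names = chromosome
#'   names) covering every region base.
#' @return Fraction (G+C)/(A+C+G+T) over the region bases; ambiguous bases
#'   are excluded from the denominator.
#' @export
gc_content <- function(regions, reference) {
  stopifnot(inherits(regions, "region_set"))
  df <- as.data.frame(regions)
  miss <- setdiff(unique(df$chrom), names(reference))
  if (length(miss)) stopf("chromosome %s not in reference", miss[1])
  over <- df$end > Biostrings::width(reference)[match(df$chrom,
                                                      names(reference))]
  if (any(over)) stopf("region %s:[%d,%d) extends beyond the reference",
                       df$chrom[over][1], df$start[over][1], df$end[over][1])
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(df)), function(k) {
    Biostrings::subseq(reference[[df$chrom[k]]],
                       start = df$start[k] + 1, end = df$end[k])
  }))
  counts <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  sum(counts[, c("C", "G")]) / tot
}

#' Identify GC-rich regions of a reference
#'
#' Tiles each reference sequence with non-overlapping windows, computes each
#' window's GC fraction, and returns the merged set of windows whose GC
#' fraction exceeds `threshold`. Capture-based assays lose coverage in such
#' regions, so this set is used both to annotate exclusive variants and to
#' drive the simulator's capture-dropout model.
#'
#' @param reference a named [Biostrings::DNAStringSet].
#' @param window window width in bases (default 100).
#' @param threshold GC fraction above which a window is GC-rich
#'   (default 0.60).
#' @return A `region_set` of GC-rich territory.
#' @export
gc_windows <- function(reference, window = 100, threshold = 0.60) {
  if (window < 1) stopf("window must be >= 1")
  out <- lapply(names(reference), function(chrom) {
    len <- Biostrings::width(reference)[match(chrom, names(reference))]
    starts <- seq.int(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    v <- Biostrings::Views(reference[[chrom]], start = starts + 1, end = ends)
    counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    tot <- rowSums(counts)
    gcf <- ifelse(tot > 0, rowSums(counts[, c("C", "G"), drop = FALSE]) / tot,
                  0)
    keep <- which(gcf > threshold)
    data.frame(chrom = rep(chrom, length(keep)), start = starts[keep],
               end = ends[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df) || !nrow(df)) return(region_set(label = "gc_rich"))
  region_set(df$chrom, df$start, df$end, label = "gc_rich")
}
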