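#' Genomic region sets
#'
#' A `region_set` is a normalized collection of genomic intervals: sorted by
#' (chromosome, start), with overlapping or abutting intervals merged, so that
#' the set of covered bases is represented uniquely and [total_bases()] is
#' well defined. Coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`. Interval arithmetic is delegated to
#' \pkg{GenomicRanges}/\pkg{IRanges}; the 1-based closed coordinates those
#' packages use internally are converted at the boundary.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start offsets.
#' @param end integer vector, exclusive end offsets; `start < end` required.
#' @param label free-text label carried through set operations (e.g. a
#'   sequencing method name).
#' @return An object of class `region_set`.
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(10, 15), c(20, 30))
#' total_bases(rs)  # 20: the two intervals merge into [10, 30)
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = "") {
  if (length(chrom) != length(start) || length(start) != length(end))
    stopf("chrom, start, end must have equal length")
  if (length(chrom)) {
    if (any(is.na(chrom) | !nzchar(chrom)))
      stopf("empty chromosome name in interval %d",
            which(is.na(chrom) | !nzchar(chrom))[1])
    bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
    if (length(bad))
      stopf("malformed interval %d: %s:[%s, %s) (need 0 <= start < end)",
            bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.numeric(start) + 1,
                              end = as.numeric(end)))
  new_region_set(GenomicRanges::reduce(GenomicRanges::sort(gr)), label)
}

new_region_set <- function(gr, label = "") {
  structure(list(gr = gr, label = label), class = "region_set")
}

#' Normalize a data frame of intervals into a region set
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param label label for the resulting set.
#' @return A `region_set` with overlapping/abutting intervals merged.
#' @export
normalize_regions <- function(intervals, label = "") {
  region_set(intervals$chrom, intervals$start, intervals$end, label = label)
}

#' @export
print.region_set <- function(x, ...) {
  n <- length(x$gr)
  cat(sprintf("region_set%s: %d interval%s on %d chromosome%s, %s bases\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              n, if (n == 1) "" else "s",
              length(GenomeInfoDb::seqlevelsInUse(x$gr)),
              if (length(GenomeInfoDb::seqlevelsInUse(x$gr)) == 1) "" else "s",
              format(total_bases(x), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.region_set <- function(x, ...) {
  gr <- x$gr
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @export
length.region_set <- function(x) length(x$gr)

#' Total number of bases covered by a region set
#'
#' @param x a `region_set`.
#' @return Integer count of distinct covered bases.
#' @export
total_bases <- function(x) {
  stopifnot(inherits(x, "region_set"))
  sum(as.numeric(GenomicRanges::width(x$gr)))
}

## put two GRanges on a common seqlevel universe so set operations compare
## them base-by-base; warn when the inputs share no chromosome names, which
## almost always indicates a naming mismatch (e.g. "chr1" vs "1")
harmonize <- function(a, b, warn_disjoint = TRUE) {
  la <- GenomeInfoDb::seqlevelsInUse(a)
  lb <- GenomeInfoDb::seqlevelsInUse(b)
  if (warn_disjoint && length(la) && length(lb) && !length(intersect(la, lb)))
    warnf("inputs share no chromosome names (e.g. '%s' vs '%s'); %s",
          la[1], lb[1], "chromosome matching is exact, no aliasing applied")
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Intersect two region sets
#'
#' Comparisons between sequencing methods are restricted to the regions
#' captured by both; this computes that restriction as the exact base-set
#' intersection.
#'
#' @param a,b `region_set` objects.
#' @param label label for the result (default combines the input labels).
#' @return A normalized `region_set` containing the bases present in both.
#' @export
region_intersect <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  h <- harmonize(a$gr, b$gr)
  res <- GenomicRanges::intersect(h$a, h$b, ignore.strand = TRUE)
  new_region_set(res, label %||% paste(a$label, b$label, sep = " & "))
}

#' Subtract one region set from another
#'
#' @param a,b `region_set` objects.
#' @param label label for the result.
#' @return A `region_set` of the bases in `a` and not in `b`.
#' @export
region_subtract <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  h <- harmonize(a$gr, b$gr, warn_disjoint = FALSE)
  res <- GenomicRanges::setdiff(h$a, h$b, ignore.strand = TRUE)
  new_region_set(res, label %||% paste(a$label, b$label, sep = " - "))
}

#' Union of two region sets
#'
#' @param a,b `region_set` objects.
#' @param label label for the result.
#' @return A `region_set` of the bases in either input.
#' @export
region_union <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  h <- harmonize(a$gr, b$gr, warn_disjoint = FALSE)
  res <- GenomicRanges::union(h$a, h$b, ignore.strand = TRUE)
  new_region_set(res, label %||% paste(a$label, b$label, sep = " | "))
}

#' Test whether 1-based positions fall inside a region set
#'
#' Variant positions come from VCF and are 1-based; the region set stores
#' 0-based half-open intervals, so position `p` is inside when offset `p - 1`
#' is covered.
#'
#' @param r a `region_set`.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (recycled against `chrom`).
#' @return Logical vector.
#' @export
region_contains <- function(r, chrom, pos) {
  stopifnot(inherits(r, "region_set"))
  if (any(pos < 1)) stopf("positions are 1-based; got %s", min(pos))
  if (!length(chrom)) return(logical())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  lev <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(r$gr))
  GenomeInfoDb::seqlevels(q) <- lev
  gr <- r$gr
  GenomeInfoDb::seqlevels(gr) <- lev
  IRanges::overlapsAny(q, gr, ignore.strand = TRUE)
}

#' Read a BED file into a region set
#'
#' Reads the first three columns (chrom, 0-based start, end) of a BED file;
#' additional columns are ignored. Intervals are normalized (sorted, merged).
#'
#' @param path path to a BED file (plain text, tab-separated, no header).
#' @param label label for the region set (default: file name).
#' @return A `region_set`.
#' @export
read_bed <- function(path, label = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         rep("NULL", 20))[seq_len(
                                           max(utils::count.fields(path, sep = "\t")))])
  region_set(df[[1]], df[[2]], df[[3]],
             label = label %||% basename(path))
}

#' Write a region set as BED
#'
#' @param x a `region_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
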