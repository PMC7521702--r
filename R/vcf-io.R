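#' Read SNV calls from a VCF file
#'
#' Ingests a VCF (v4.x) through \pkg{VariantAnnotation} and normalizes it to
#' the call representation used throughout the package:
#' \itemize{
#'   \item multi-allelic records are decomposed into biallelic records; a
#'     `1/2` genotype yields one `het` call per alternate allele;
#'   \item only single-nucleotide substitutions are retained — indels, MNVs
#'     and symbolic alleles are dropped and counted;
#'   \item genotypes are mapped to `het` (one alternate allele) or `hom_alt`
#'     (two); homozygous-reference and no-call genotypes are dropped;
#'   \item missing DP/AD leaves the call present (it still counts for
#'     exclusivity) with depth/allele counts marked unknown, which excludes
#'     it from quality filtering and allele-balance analyses.
#' }
#' No FILTER-column screening is applied by default: exclusivity is defined
#' on unfiltered calls. Set `pass_only = TRUE` to keep only PASS records.
#'
#' @param path path to a VCF file.
#' @param method method label to attach (default: file name without
#'   extension).
#' @param sample sample column to extract (default: the first sample in the
#'   file); also used as the sample id of the result.
#' @param capture optional `region_set`; when given, calls are restricted to
#'   it and it is attached as the callset's capture.
#' @param pass_only keep only records whose FILTER is PASS or missing.
#' @param verbose report dropped-record counts with `message()`.
#' @return A `callset`.
#' @export
read_vcf <- function(path, method = NULL, sample = NULL, capture = NULL,
                     pass_only = FALSE, verbose = TRUE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g))
    stopf("%s: no GT (genotype) FORMAT field; cannot ingest", path)
  samples <- colnames(g$GT)
  col <- if (is.null(sample)) 1L else match(sample, samples)
  if (is.na(col)) stopf("sample '%s' not present in %s", sample, path)
  sample_id <- sample %||% (if (length(samples)) samples[1] else "sample1")
  method <- method %||% sub("\\.vcf(\\.gz)?$", "", basename(path))

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alts <- if (is(alts, "List")) as.list(as(alts, "CharacterList")) else
    as.list(as.character(alts))
  filt <- VariantAnnotation::filt(vcf)
  gt <- g$GT[, col]
  dp <- if ("DP" %in% names(g)) g$DP[, col] else rep(NA_integer_, length(gt))
  ad <- if ("AD" %in% names(g)) g$AD else NULL
  # AD comes back as a matrix of integer vectors (Number=R) or a 3-d array
  ad_at <- function(i) {
    if (is.null(ad)) return(NULL)
    v <- if (is.list(ad)) ad[[i, col]] else if (length(dim(ad)) == 3)
      ad[i, col, ] else ad[i, col]
    suppressWarnings(as.integer(unlist(v, use.names = FALSE)))
  }

  bases <- c("A", "C", "G", "T")
  n_non_snv <- 0L
  n_nocall <- 0L
  n_filtered <- 0L
  n_missing_ad <- 0L
  out <- vector("list", length(gt))

  for (i in seq_along(gt)) {
    if (pass_only && !is.na(filt[i]) && !filt[i] %in% c("PASS", ".")) {
      n_filtered <- n_filtered + 1L
      next
    }
    gstr <- gt[i]
    if (is.na(gstr) || gstr %in% c(".", "./.", ".|.")) {
      n_nocall <- n_nocall + 1L
      next
    }
    alleles <- suppressWarnings(
      as.integer(strsplit(gstr, "[/|]")[[1]]))
    if (!length(alleles) || all(is.na(alleles)) ||
        all(alleles == 0, na.rm = TRUE)) {
      n_nocall <- n_nocall + 1L
      next
    }
    ref_i <- toupper(refs[i])
    alt_i <- toupper(unlist(alts[[i]], use.names = FALSE))
    ad_i <- ad_at(i)
    for (j in seq_along(alt_i)) {
      cnt <- sum(alleles == j, na.rm = TRUE)
      if (cnt == 0L) next
      a <- alt_i[j]
      if (nchar(ref_i) != 1L || nchar(a) != 1L ||
          !(ref_i %in% bases) || !(a %in% bases)) {
        n_non_snv <- n_non_snv + 1L
        next
      }
      depth <- if (is.na(dp[i])) NA_integer_ else as.integer(dp[i])
      rr_j <- NA_integer_
      ar_j <- NA_integer_
      if (!is.null(ad_i) && length(ad_i) >= j + 1L &&
          !is.na(ad_i[1]) && !is.na(ad_i[j + 1L])) {
        rr_j <- ad_i[1]
        ar_j <- ad_i[j + 1L]
        # some callers report DP < sum(AD) (uninformative reads excluded);
        # keep the invariant ref + alt <= depth by lifting depth
        if (!is.na(depth) && rr_j + ar_j > depth) depth <- rr_j + ar_j
        if (is.na(depth)) depth <- rr_j + ar_j
      } else if (!is.null(ad)) {
        n_missing_ad <- n_missing_ad + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref_i, alt = a,
        genotype = if (cnt == 2L) "hom_alt" else "het",
        depth = depth, ref_reads = rr_j, alt_reads = ar_j,
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(), depth = integer(),
               ref_reads = integer(), alt_reads = integer(),
               stringsAsFactors = FALSE)
  ## de-duplicate identical (chrom,pos,ref,alt) rows, keeping the first
  key <- vkey(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[!duplicated(key), , drop = FALSE]
  if (verbose && (n_non_snv || n_nocall || n_filtered || n_missing_ad))
    message(sprintf(
      "%s: dropped %d non-SNV allele(s), %d hom-ref/no-call record(s), %d filtered record(s); %d call(s) lack AD",
      basename(path), n_non_snv, n_nocall, n_filtered, n_missing_ad))
  cs <- callset(calls, method = method, sample = sample_id, capture = capture)
  if (!is.null(capture)) cs <- restrict_calls(cs, capture)
  cs
}

#' Write a callset as a VCF file
#'
#' Writes biallelic single-sample VCF v4.2 records with GT, DP and AD.
#' Unknown depth/allele counts are written as missing (`.`). An optional
#' per-call category (e.g. FE/HQFE) is carried in the INFO field as
#' `CAT=<value>`.
#'
#' @param cs a `callset`.
#' @param path output path.
#' @param category optional character vector (length 1 or `nrow(calls)`)
#'   written as `CAT=` INFO tags.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(cs, path, category = NULL) {
  stopifnot(inherits(cs, "callset"))
  calls <- cs$calls
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=snvconcord",
    "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Concordance category\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", cs$sample, sep = "\t"))
  if (nrow(calls)) {
    info <- if (is.null(category)) "." else paste0("CAT=", category)
    gtf <- ifelse(calls$genotype == "hom_alt", "1/1", "0/1")
    dpf <- ifelse(is.na(calls$depth), ".", as.character(calls$depth))
    adf <- ifelse(is.na(calls$ref_reads) | is.na(calls$alt_reads), ".",
                  paste(calls$ref_reads, calls$alt_reads, sep = ","))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "GT:DP:AD",
                  paste(gtf, dpf, adf, sep = ":"), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write calls as a TSV table
#'
#' @param calls a `callset` or a data frame of calls.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  df <- if (inherits(calls, "callset")) cbind(method = calls$method,
                                              sample = calls$sample,
                                              calls$calls) else calls
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
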