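# shared fixtures and independent brute-force oracles

# --- interval oracles: represent a region set as the explicit set of its
# covered bases ("chrom:offset" strings), and compute set algebra on that ---

base_set_df <- function(df) {
  if (!nrow(df)) return(character())
  unlist(lapply(seq_len(nrow(df)), function(i) {
    paste(df$chrom[i], seq.int(df$start[i], df$end[i] - 1), sep = ":")
  }), use.names = FALSE)
}

base_set <- function(rs) unique(base_set_df(as.data.frame(rs)))

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 60,
                             max_len = 10) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# --- call-set construction helpers ---

make_calls <- function(pos, genotype = "het", depth = 50L,
                       ref_reads = NULL, alt_reads = NULL,
                       chrom = "chr1", ref = "A", alt = "G") {
  n <- length(pos)
  genotype <- rep_len(genotype, n)
  depth <- rep_len(depth, n)
  if (is.null(alt_reads))
    alt_reads <- ifelse(genotype == "het", floor(depth / 2), depth)
  if (is.null(ref_reads)) ref_reads <- depth - alt_reads
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             genotype = genotype, depth = depth,
             ref_reads = rep_len(ref_reads, n),
             alt_reads = rep_len(alt_reads, n),
             stringsAsFactors = FALSE)
}

make_callset <- function(pos, method = "WGS", sample = "S01", ...) {
  callset(make_calls(pos, ...), method = method, sample = sample)
}

# write a small VCF from raw lines (header prepended)
write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                          sample = "s1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gt, dp = NULL, ad = NULL,
                    filter = "PASS") {
  fmt <- "GT"
  val <- gt
  if (!is.null(dp)) { fmt <- paste0(fmt, ":DP"); val <- paste0(val, ":", dp) }
  if (!is.null(ad)) { fmt <- paste0(fmt, ":AD"); val <- paste0(val, ":", ad) }
  paste(chrom, pos, ".", ref, alt, ".", filter, ".", fmt, val, sep = "\t")
}

# --- three-way truth-table oracle: classify every key directly from its
# presence pattern, independent of the package's bookkeeping ---

threeway_oracle <- function(present) {
  # present: logical matrix keys x 3 methods
  n_present <- rowSums(present)
  out <- lapply(1:3, function(m) {
    has <- present[, m]
    c(total_detected = sum(has),
      confirmed_by_all = sum(has & n_present == 3),
      fe = sum(has & n_present < 3),
      fe_confirmed = sum(has & n_present == 2),
      fe_not_confirmed = sum(has & n_present == 1),
      missed = sum(!has & n_present == 2))
  })
  do.call(rbind, out)
}

# build three callsets at distinct positions realizing a presence matrix
callsets_from_presence <- function(present, methods = c("WGS", "WES", "HES"),
                                   sample = "S01") {
  pos <- seq_len(nrow(present)) * 10L
  lapply(1:3, function(m) {
    make_callset(pos[present[, m]], method = methods[m], sample = sample,
                 depth = 100L)
  })
}
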