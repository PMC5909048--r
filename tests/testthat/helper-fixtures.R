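# Fixture builders and independent brute-force oracles used across tests.

# Write a small VCF from raw body lines (already tab-separated).
write_test_vcf <- function(body, samples = c("S1", "S2"),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

rec <- function(chrom, pos, format, ..., ref = "A", alt = "T") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", format, ...),
        collapse = "\t")
}

# Brute-force histogram of balances on (0,1] with half-open bins, written
# as plain loops, independent of the package's vectorized path.
oracle_bins <- function(values, bin_width) {
  nb <- as.integer(ceiling(1 / bin_width - 1e-9))
  counts <- integer(nb)
  for (x in values) {
    if (is.na(x)) next
    for (i in seq_len(nb)) {
      lo <- (i - 1) * bin_width
      hi <- i * bin_width
      if (x > lo + 1e-9 * bin_width && x <= hi + 1e-9 * bin_width) {
        counts[i] <- counts[i] + 1L
        break
      }
    }
  }
  counts
}

# Modal bin midpoint with the documented tie rule (nearest 0.5, then the
# lower bin), formulated via order() rather than the package's max scan.
oracle_peak <- function(counts, bin_width) {
  if (max(counts) == 0L) return(NA_real_)
  mid <- (seq_along(counts) - 0.5) * bin_width
  # distances rounded so that mathematically equidistant bins (e.g. 0.42
  # and 0.58) tie despite floating-point noise; then the lower bin wins
  o <- order(-counts, round(abs(mid - 0.5), 9), mid)
  mid[o[1L]]
}

# Textbook Nei Gst for equal-weight populations: unweighted mean Hs,
# pooled frequencies as the plain mean across populations.
oracle_nei_gst <- function(freq_list) {
  hs <- mean(vapply(freq_list, function(p) 1 - sum(p^2), numeric(1L)))
  pbar <- Reduce(`+`, freq_list) / length(freq_list)
  ht <- 1 - sum(pbar^2)
  list(Hs = hs, Ht = ht, Gst = (ht - hs) / ht)
}

# Allele frequencies of one population from a block of GT strings (loops).
oracle_pop_freq <- function(gts) {
  al <- character()
  for (g in gts) {
    a <- strsplit(g, "[/|]")[[1L]]
    al <- c(al, a[a != "." & nzchar(a)])
  }
  if (!length(al)) return(numeric())
  tab <- table(al)
  as.numeric(tab) / sum(tab)
}
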