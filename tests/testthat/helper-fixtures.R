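# In-code fixtures shared across test files.

extdata <- function(f) system.file("extdata", f, package = "mdaqc")

# ratio profile over an evenly spaced single- or multi-chromosome layout
make_profile <- function(values, chrom = "chr1", spacing = 1000L,
                         probe_length = 60L, smoothed = FALSE) {
  n <- length(values)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  probes <- data.frame(
    probe_id = sprintf("P%05d", seq_len(n)),
    chrom = chrom,
    start = (idx - 1L) * spacing,
    end = (idx - 1L) * spacing + probe_length,
    stringsAsFactors = FALSE)
  ratio_profile(probes, values, smoothed = smoothed)
}

# probe array with explicit intensities on the same layout
make_array <- function(test, reference, chrom = "chr1") {
  n <- length(test)
  probes <- data.frame(
    probe_id = sprintf("P%05d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 60L,
    stringsAsFactors = FALSE)
  probe_array(probes, test, reference)
}

# exhaustive O(n^2) arc-statistic oracle, independent of the C++ kernel
oracle_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- list(i = 0L, j = 0L, stat = -1)
  for (i in seq_len(n)) {
    if (i + min_width - 1L > n) next
    for (j in seq.int(i + min_width - 1L, n)) {
      k <- j - i + 1L
      if (k < min_width || n - k < min_width) next
      arc <- x[i:j]
      rest <- x[-(i:j)]
      st <- abs(mean(arc) - mean(rest)) / sqrt(1 / k + 1 / (n - k))
      if (st > best$stat) best <- list(i = i, j = j, stat = st)
    }
  }
  best
}
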