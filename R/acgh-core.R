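#' Probe-level two-channel array container
#'
#' Holds one hybridization: an ordered probe table plus positive test and
#' reference channel intensities, with the labels (sample, kit, replicate,
#' comparison tag) that downstream reports carry along.
#'
#' @param probes data.frame with columns probe_id, chrom, start, end and
#'   optionally gc (0-based half-open coordinates).
#' @param test,reference Positive intensity vectors, one value per probe.
#' @param sample,kit,replicate,comparison Labels.
#' @return A `probe_array` object, probes sorted by (chrom, start).
#' @export
probe_array <- function(probes, test, reference, sample = NA_character_,
                        kit = NA_character_, replicate = NA_integer_,
                        comparison = NA_character_) {
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(probes)))
    stop("probes needs columns: ", paste(need, collapse = ", "))
  n <- nrow(probes)
  if (length(test) != n || length(reference) != n)
    stop("intensity vectors must match the probe count")
  if (any(!is.finite(test)) || any(!is.finite(reference)) ||
      any(test <= 0) || any(reference <= 0))
    stop("intensities must be positive and finite")
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$start)
  structure(
    list(probes = probes[ord, , drop = FALSE],
         test = as.numeric(test)[ord],
         reference = as.numeric(reference)[ord],
         labels = list(sample = sample, kit = kit, replicate = replicate,
                       comparison = comparison)),
    class = "probe_array"
  )
}

#' @export
print.probe_array <- function(x, ...) {
  l <- x$labels
  cat("Probe array:", nrow(x$probes), "probes on",
      length(unique(x$probes$chrom)), "chromosome(s)\n")
  cat("  sample:", l$sample, " kit:", l$kit, " replicate:", l$replicate,
      " comparison:", l$comparison, "\n")
  invisible(x)
}

#' Read a probe intensity table
#'
#' Reads the package's TSV dialect: a header line with columns `probe_id`,
#' `chrom`, `start`, `end`, `test_intensity`, `ref_intensity` and optionally
#' `gc`.  Rows with non-positive or missing intensities are dropped with a
#' warning; rows are sorted by (chrom, start).
#'
#' @param path File path.
#' @param sample,kit,replicate,comparison Labels attached to the result.
#' @return A [probe_array()].
#' @export
read_probe_table <- function(path, sample = NA_character_,
                             kit = NA_character_, replicate = NA_integer_,
                             comparison = NA_character_) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "test_intensity", "ref_intensity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("probe table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (!"probe_id" %in% names(d))
    d$probe_id <- sprintf("P%06d", seq_len(nrow(d)))
  bad <- !is.finite(d$test_intensity) | !is.finite(d$ref_intensity) |
    d$test_intensity <= 0 | d$ref_intensity <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive intensity dropped")
    d <- d[!bad, , drop = FALSE]
  }
  cols <- intersect(c("probe_id", "chrom", "start", "end", "gc"), names(d))
  probe_array(d[, cols], d$test_intensity, d$ref_intensity,
              sample = sample, kit = kit, replicate = replicate,
              comparison = comparison)
}

#' Write a probe intensity table
#'
#' @param array A [probe_array()].
#' @param path Output path.
#' @export
write_probe_table <- function(array, path) {
  stopifnot(inherits(array, "probe_array"))
  d <- array$probes
  d$test_intensity <- array$test
  d$ref_intensity <- array$reference
  cols <- intersect(c("probe_id", "chrom", "start", "end",
                      "test_intensity", "ref_intensity", "gc"), names(d))
  write.table(d[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-probe log2 ratios of a hybridization
#'
#' Computes log2(test / reference) for every probe.  With `normalize = TRUE`
#' a single global scale factor is applied to the test channel (equivalently,
#' the median log2 ratio is subtracted), the linear dye-bias correction used
#' on two-channel arrays; no spatial or intensity-dependent correction is
#' attempted.
#'
#' @param array A [probe_array()].
#' @param normalize Median-center the log2 ratios?
#' @return A `ratio_profile`: list with the probe table, `log2_ratio`, the
#'   `smoothed` flag (FALSE here) and the source labels.
#' @export
compute_log2_ratios <- function(array, normalize = TRUE) {
  stopifnot(inherits(array, "probe_array"))
  r <- log2(array$test / array$reference)
  if (normalize) r <- r - median(r)
  ratio_profile(array$probes, r, smoothed = FALSE, labels = array$labels)
}

#' Ratio profile container
#'
#' @param probes Probe table (sorted by chrom, start).
#' @param log2_ratio Finite numeric vector, one value per probe.
#' @param smoothed Are the values segment means (TRUE) or raw (FALSE)?
#' @param labels Label list as in [probe_array()].
#' @return A `ratio_profile` object.
#' @export
ratio_profile <- function(probes, log2_ratio, smoothed = FALSE,
                          labels = list()) {
  if (nrow(probes) != length(log2_ratio))
    stop("log2_ratio must match the probe count")
  if (any(!is.finite(log2_ratio))) stop("log2 ratios must be finite")
  structure(list(probes = probes, log2_ratio = as.numeric(log2_ratio),
                 smoothed = isTRUE(smoothed), labels = labels),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat("Ratio profile:", nrow(x$probes), "probes,",
      if (x$smoothed) "segment-smoothed" else "raw", "\n")
  cat("  median", round(median(x$log2_ratio), 4),
      " IQR", round(IQR(x$log2_ratio), 4), "\n")
  invisible(x)
}

#' @export
summary.ratio_profile <- function(object, ...) {
  c(n_probes = nrow(object$probes),
    median = median(object$log2_ratio),
    iqr = IQR(object$log2_ratio),
    dlrs = if (object$smoothed) NA_real_ else dlrs(object))
}

#' Plot a ratio profile along the genome
#'
#' Simple per-chromosome scatter of log2 ratios against position, optionally
#' overlaying segment means.
#'
#' @param x A `ratio_profile`.
#' @param chrom Chromosome to plot (default: first).
#' @param segments Optional [cbs_segment()] result to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ratio_profile <- function(x, chrom = NULL, segments = NULL, ...) {
  chrom <- chrom %||% x$probes$chrom[1]
  idx <- x$probes$chrom == chrom
  pos <- (x$probes$start[idx] + x$probes$end[idx]) / 2
  graphics::plot(pos, x$log2_ratio[idx], pch = 16, cex = 0.4,
                 col = "grey40", xlab = paste(chrom, "position (bp)"),
                 ylab = "log2 ratio", ...)
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(segments)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    graphics::segments(s$start, s$mean, s$end, s$mean, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Direction-agnostic fold change
#'
#' `2^|r|` for a log2 ratio r: a 2-fold over- and a 2-fold under-amplification
#' both map to 2, matching how over- and under-amplified probes are counted
#' together in threshold tables.
#'
#' @param log2_ratio Numeric vector.
#' @return Fold changes (>= 1).
#' @export
fold_change <- function(log2_ratio) {
  if (any(!is.finite(log2_ratio))) stop("log2 ratios must be finite")
  2^abs(log2_ratio)
}

#' Derivative log-ratio spread (DLRS)
#'
#' Robust spread of consecutive-probe log2-ratio differences within
#' chromosomes, scaled to estimate the per-probe noise sd of the array:
#' IQR(differences) / (1.349 * sqrt(2)).  The 1.349 converts IQR to sd under
#' normality, and sqrt(2) accounts for differencing two independent probes.
#' The quantity is defined for raw profiles only; a smoothed profile is
#' rejected.
#'
#' @param profile A raw `ratio_profile` with at least 3 probes.
#' @return Non-negative noise-sd estimate.
#' @export
dlrs <- function(profile) {
  stopifnot(inherits(profile, "ratio_profile"))
  if (profile$smoothed) stop("DLRS is defined on raw (unsmoothed) profiles")
  if (nrow(profile$probes) < 3) stop("need at least 3 probes")
  d <- chromwise_diffs(profile)
  IQR(d) / (1.349 * sqrt(2))
}

# consecutive differences that never cross a chromosome boundary
chromwise_diffs <- function(profile) {
  unlist(lapply(split(profile$log2_ratio, profile$probes$chrom), diff),
         use.names = FALSE)
}

#' Fold-change threshold table
#'
#' For each cutoff, the percent of probes whose direction-agnostic fold
#' change exceeds it, averaged across the given replicate profiles.  By
#' convention the table is computed on raw (unsmoothed) per-probe ratios;
#' pass smoothed profiles to reproduce a segment-level variant.
#'
#' @param profiles A `ratio_profile` or list of them sharing one probe set.
#' @param cutoffs Ascending fold-change cutoffs.
#' @param one_sided Optional "gain" or "loss" to count one direction only.
#' @param group Label for the table.
#' @return A `threshold_table` data.frame with columns cutoff and percent.
#' @export
threshold_table <- function(profiles, cutoffs = c(1.5, 2, 2.5, 3, 4),
                            one_sided = NULL, group = NA_character_) {
  if (inherits(profiles, "ratio_profile")) profiles <- list(profiles)
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  for (p in profiles[-1]) stopifnot_same_probes(profiles[[1]]$probes, p$probes)
  pct <- sapply(profiles, function(p) {
    r <- p$log2_ratio
    if (!is.null(one_sided))
      r <- switch(one_sided, gain = pmax(r, 0), loss = pmin(r, 0),
                  stop("one_sided must be 'gain' or 'loss'"))
    sapply(cutoffs, function(k) 100 * mean(fold_change(r) > k))
  })
  out <- data.frame(cutoff = cutoffs,
                    percent = rowMeans(matrix(pct, nrow = length(cutoffs))))
  attr(out, "group") <- group
  attr(out, "n_profiles") <- length(profiles)
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("Threshold table", if (!is.na(attr(x, "group"))) paste0("[", attr(x, "group"), "]"),
      "- mean of", attr(x, "n_profiles"), "replicate profile(s)\n")
  print(data.frame(cutoff = x$cutoff, percent = round(x$percent, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Quality-weighted combination of replicate profiles
#'
#' Per-probe weighted mean across replicate profiles on a shared probe set.
#' The default weights are proportional to 1/DLRS^2 -- replicates with lower
#' noise count more -- normalized to sum to 1; if any replicate has DLRS of
#' zero (noiseless), equal weights are used.
#'
#' @param profiles List of raw `ratio_profile`s on one probe set.
#' @param weights Optional non-negative weights, one per profile.
#' @return A combined raw `ratio_profile`.
#' @export
combine_replicates <- function(profiles, weights = NULL) {
  if (inherits(profiles, "ratio_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile")
  for (p in profiles[-1]) stopifnot_same_probes(profiles[[1]]$probes, p$probes)
  if (is.null(weights)) {
    d <- vapply(profiles, dlrs, numeric(1))
    weights <- if (any(d == 0)) rep(1, length(profiles)) else 1 / d^2
  }
  if (length(weights) != length(profiles))
    stop("one weight per profile required")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  r <- Reduce(`+`, Map(function(p, wi) wi * p$log2_ratio, profiles, w))
  labels <- profiles[[1]]$labels
  labels$replicate <- NA_integer_
  labels$combined <- length(profiles)
  ratio_profile(profiles[[1]]$probes, r, smoothed = FALSE, labels = labels)
}

#' Export probe ratios as BED
#'
#' BED6-compatible track (0-based half-open) with the integer score column
#' carrying the log2 ratio multiplied by 1000.
#'
#' @param profile A `ratio_profile`.
#' @param path Output path.
#' @export
export_ratio_bed <- function(profile, path) {
  stopifnot(inherits(profile, "ratio_profile"))
  p <- profile$probes
  gr <- GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1L, end = p$end),
    name = p$probe_id, score = as.integer(round(1000 * profile$log2_ratio)),
    strand = "*")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
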