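#' Circular binary segmentation of a ratio profile
#'
#' Recursively partitions each chromosome's log2-ratio sequence into
#' constant-mean segments.  At each step the arc of probes maximizing the
#' standardized mean-difference statistic against its (circular) complement
#' is located; the split is kept when its permutation p-value falls below
#' `alpha`, and recursion continues inside the resulting pieces.  After
#' segmentation, adjacent segments whose means differ by less than
#' `undo_sd` times the profile's noise sd (MAD of consecutive differences /
#' sqrt(2)) are merged back ("undo" rule).  The arc search is exhaustive for
#' chromosomes up to `max_exact` probes and samples `n_sample_arcs` random
#' arcs above that; ties in the maximizing arc go to the leftmost, then
#' shortest arc so results are reproducible.
#'
#' @param profile A raw `ratio_profile`.
#' @param alpha Split significance level in (0, 1).
#' @param n_permutations Permutations per tested split (>= 100).
#' @param min_width Minimum probes per segment.
#' @param undo_sd Undo threshold in noise-sd units; 0 disables undoing.
#' @param max_exact Largest window searched exhaustively.
#' @param n_sample_arcs Arcs sampled per window above `max_exact`.
#' @param seed Optional integer seed (permutations and arc sampling).
#' @return A `segment_set` data.frame: chrom, first_probe, last_probe
#'   (1-based global probe indices, inclusive), start, end (bp, half-open),
#'   n_probes, mean.
#' @examples
#' probes <- data.frame(probe_id = sprintf("P%02d", 1:40), chrom = "chr1",
#'                      start = (0:39) * 1000L, end = (0:39) * 1000L + 60L)
#' prof <- ratio_profile(probes, rep(c(0, 1), each = 20))
#' cbs_segment(prof, n_permutations = 100, seed = 1)
#' @export
cbs_segment <- function(profile, alpha = 0.01, n_permutations = 1000,
                        min_width = 2, undo_sd = 1.0, max_exact = 2000,
                        n_sample_arcs = 20000, seed = NULL) {
  stopifnot(inherits(profile, "ratio_profile"))
  if (profile$smoothed) stop("segmentation expects a raw (unsmoothed) profile")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_permutations < 100) stop("need at least 100 permutations")
  if (!is.null(seed)) set.seed(seed)

  probes <- profile$probes
  out <- list()
  offset <- 0L
  for (chrom in unique(probes$chrom)) {
    idx <- which(probes$chrom == chrom)
    x <- profile$log2_ratio[idx]
    bounds <- segment_chromosome(x, alpha, n_permutations, min_width,
                                 max_exact, n_sample_arcs)
    if (undo_sd > 0 && nrow(bounds) > 1) {
      noise <- mad(diff(x)) / sqrt(2)
      bounds <- undo_segments(x, bounds, undo_sd * noise)
    }
    out[[chrom]] <- data.frame(
      chrom = chrom,
      first_probe = offset + bounds$lo,
      last_probe = offset + bounds$hi,
      start = probes$start[idx[bounds$lo]],
      end = probes$end[idx[bounds$hi]],
      n_probes = bounds$hi - bounds$lo + 1L,
      mean = bounds$mean,
      stringsAsFactors = FALSE
    )
    offset <- offset + length(idx)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("segment_set", "data.frame")
  out
}

# Recursive splitting of one chromosome; returns data.frame(lo, hi, mean)
# of probe index ranges (1-based, inclusive, local to the chromosome).
segment_chromosome <- function(x, alpha, n_perm, min_width, max_exact,
                               n_sample_arcs) {
  n <- length(x)
  cuts <- integer()  # positions k meaning a boundary between k and k+1
  stack <- list(c(1L, n))
  while (length(stack)) {
    w <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- w[1]; hi <- w[2]
    m <- hi - lo + 1L
    if (m < 2L * min_width) next
    xv <- x[lo:hi]
    if (diff(range(xv)) < 1e-12) next  # flat window: nothing to split
    exhaustive <- m <= max_exact
    hit <- .cbs_max_arc(xv, as.integer(min_width), exhaustive,
                        as.integer(n_sample_arcs))
    if (hit$i == 0L) next
    p <- .cbs_perm_pvalue(xv, hit$stat, as.integer(min_width),
                          as.integer(n_perm), alpha, exhaustive,
                          as.integer(n_sample_arcs))
    if (p >= alpha) next
    i <- hit$i; j <- hit$j
    new_cuts <- integer()
    if (i > 1L) new_cuts <- c(new_cuts, lo + i - 2L)   # boundary before arc
    if (j < m) new_cuts <- c(new_cuts, lo + j - 1L)    # boundary after arc
    cuts <- c(cuts, new_cuts)
    pieces <- sort(unique(c(lo - 1L, new_cuts, hi)))
    for (k in seq_len(length(pieces) - 1L))
      stack[[length(stack) + 1L]] <- c(pieces[k] + 1L, pieces[k + 1L])
  }
  cuts <- sort(unique(cuts))
  lo <- c(1L, cuts + 1L)
  hi <- c(cuts, n)
  data.frame(lo = lo, hi = hi,
             mean = vapply(seq_along(lo),
                           function(k) mean(x[lo[k]:hi[k]]), numeric(1)))
}

# Merge adjacent segments whose mean difference is below the undo threshold,
# smallest difference first, recomputing means after each merge.
undo_segments <- function(x, bounds, threshold) {
  repeat {
    if (nrow(bounds) < 2) break
    d <- abs(diff(bounds$mean))
    k <- which.min(d)
    if (d[k] >= threshold) break
    bounds$hi[k] <- bounds$hi[k + 1]
    bounds$mean[k] <- mean(x[bounds$lo[k]:bounds$hi[k]])
    bounds <- bounds[-(k + 1), , drop = FALSE]
  }
  rownames(bounds) <- NULL
  bounds
}

#' @export
print.segment_set <- function(x, ...) {
  cat("Segment set:", nrow(x), "segment(s) on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Replace probe values by their segment means
#'
#' @param profile The raw `ratio_profile` the segments were computed from.
#' @param segments A [cbs_segment()] result on the same probe set.
#' @return A `ratio_profile` with `smoothed = TRUE`.
#' @export
smooth_profile <- function(profile, segments) {
  stopifnot(inherits(profile, "ratio_profile"))
  n <- nrow(profile$probes)
  if (sum(segments$n_probes) != n || max(segments$last_probe) != n)
    stop("segments do not cover this profile's probe set")
  r <- numeric(n)
  for (k in seq_len(nrow(segments)))
    r[segments$first_probe[k]:segments$last_probe[k]] <- segments$mean[k]
  ratio_profile(profile$probes, r, smoothed = TRUE, labels = profile$labels)
}

#' Binary CNV calls from a smoothed profile
#'
#' A probe is called changed (1) when the direction-agnostic fold change of
#' its segment mean exceeds the cutoff; segments within the cutoff are
#' "unchanged" (no CNV).
#'
#' @param smoothed A segment-smoothed `ratio_profile`.
#' @param fold_cutoff Fold-change cutoff (> 1); default 2.
#' @return A `cnv_calls` object: 0/1 vector plus the cutoff and labels.
#' @export
call_cnv <- function(smoothed, fold_cutoff = 2.0) {
  stopifnot(inherits(smoothed, "ratio_profile"))
  if (!smoothed$smoothed) stop("CNV calling expects a smoothed profile")
  if (fold_cutoff <= 1) stop("fold_cutoff must be > 1")
  structure(
    list(calls = as.integer(fold_change(smoothed$log2_ratio) > fold_cutoff),
         fold_cutoff = fold_cutoff,
         probes = smoothed$probes,
         labels = smoothed$labels),
    class = "cnv_calls"
  )
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat("CNV calls:", sum(x$calls), "of", length(x$calls),
      "probes changed at fold cutoff", x$fold_cutoff, "\n")
  invisible(x)
}

#' Export a segment set as BED
#'
#' 0-based half-open intervals with the segment mean log2 ratio in the name
#' column and mean x 1000 as integer score.
#'
#' @param segments A `segment_set`.
#' @param path Output path.
#' @export
export_segments_bed <- function(segments, path) {
  gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1L, end = segments$end),
    name = sprintf("%.4f", segments$mean),
    score = as.integer(round(1000 * segments$mean)), strand = "*")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
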