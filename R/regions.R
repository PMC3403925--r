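#' Aberration report: runs of probes beyond a fold cutoff
#'
#' Scans a segment-smoothed profile for maximal runs of at least `min_probes`
#' consecutive probes (within a chromosome, same direction) whose
#' direction-agnostic fold change exceeds `fold_cutoff`, and reports one
#' region per run.  Replicates are normally combined with
#' [combine_replicates()] before segmentation and reporting.
#'
#' @param smoothed A segment-smoothed `ratio_profile`.
#' @param fold_cutoff Fold-change cutoff (> 1); default 3.
#' @param min_probes Minimum run length; default 3.
#' @param group Label recorded as the supporting group.
#' @return A `region_set` data.frame: chrom, start, end (bp, half-open),
#'   n_probes, direction ("gain"/"loss"), mean_fold, group.
#' @export
aberration_report <- function(smoothed, fold_cutoff = 3.0, min_probes = 3,
                              group = NA_character_) {
  stopifnot(inherits(smoothed, "ratio_profile"))
  if (!smoothed$smoothed) stop("aberration reporting expects a smoothed profile")
  if (fold_cutoff <= 1) stop("fold_cutoff must be > 1")
  if (min_probes < 1) stop("min_probes must be >= 1")
  probes <- smoothed$probes
  r <- smoothed$log2_ratio
  state <- ifelse(fold_change(r) > fold_cutoff, sign(r), 0)
  key <- paste(probes$chrom, state)
  runs <- rle(key)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  keep <- which(runs$lengths >= min_probes &
                  !endsWith(runs$values, " 0"))
  out <- data.frame(
    chrom = probes$chrom[starts[keep]],
    start = probes$start[starts[keep]],
    end = probes$end[stops[keep]],
    n_probes = runs$lengths[keep],
    direction = ifelse(endsWith(runs$values[keep], " 1"), "gain", "loss"),
    mean_fold = vapply(keep, function(k)
      mean(fold_change(r[starts[k]:stops[k]])), numeric(1)),
    group = rep(group, length(keep)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

# region_set / data.frame -> GRanges (0-based half-open in, 1-based in GRanges)
regions_to_granges <- function(regions) {
  if (is(regions, "GRanges")) return(regions)
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

granges_to_regions <- function(gr, group = NA_character_) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    group = rep(group, length(gr)),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Regions common to every group
#'
#' Base-pair intersection of the (merged) region sets of every group,
#' followed by merging of fragments separated by at most `gap_tolerance` bp.
#' Used to find loci consistently under-amplified across all samples and
#' both amplification methods.
#'
#' @param region_sets Named list (>= 2) of `region_set` data.frames or
#'   GRanges.
#' @param gap_tolerance Merge fragments separated by <= this many bp.
#' @param direction Optional "loss" or "gain": filter each set first.
#' @return A `region_set` with `group` listing the supporting groups.
#' @export
common_regions <- function(region_sets, gap_tolerance = 0, direction = NULL) {
  if (length(region_sets) < 2) stop("need at least 2 groups")
  grs <- lapply(region_sets, function(rs) {
    if (!is(rs, "GRanges") && !is.null(direction) && "direction" %in% names(rs))
      rs <- rs[rs$direction == direction, , drop = FALSE]
    GenomicRanges::reduce(regions_to_granges(rs))
  })
  common <- Reduce(GenomicRanges::intersect, grs)
  common <- GenomicRanges::reduce(common, min.gapwidth = gap_tolerance + 1L)
  groups <- paste(names(region_sets) %||% seq_along(region_sets),
                  collapse = ",")
  granges_to_regions(common, group = groups)
}

#' Fraction of the genome covered by regions
#'
#' Overlapping regions are merged before summing, so double-covered bases
#' count once.
#'
#' @param regions A `region_set`, data.frame, or GRanges.
#' @param chromosome_lengths Named vector of chromosome lengths (bp).
#' @return Percent of total genome length covered.
#' @export
genome_fraction <- function(regions, chromosome_lengths) {
  gr <- GenomicRanges::reduce(regions_to_granges(regions))
  if (length(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chrom %in% names(chromosome_lengths)))
      stop("region chromosome missing from chromosome_lengths")
    if (any(GenomicRanges::end(gr) > chromosome_lengths[chrom]))
      stop("region extends beyond its chromosome")
  }
  100 * sum(GenomicRanges::width(gr)) / sum(chromosome_lengths)
}

#' GC content of regions
#'
#' Per-region GC fraction, (G + C) / (A + C + G + T) with ambiguity codes
#' excluded from both counts, plus the length-weighted mean across regions
#' (weights = unambiguous base counts).
#'
#' @param regions A `region_set`, data.frame, or GRanges (0-based half-open).
#' @param genome A `genome_model`, [Biostrings::DNAStringSet], or FASTA path.
#' @return list with `regions` (the input plus a `gc` column) and `mean_gc`.
#' @export
region_gc <- function(regions, genome) {
  sequence <- if (inherits(genome, "genome_model")) genome$sequence
    else if (is(genome, "DNAStringSet")) genome
    else Biostrings::readDNAStringSet(genome)
  names(sequence) <- sub("\\s.*$", "", names(sequence))
  gr <- regions_to_granges(regions)
  gc <- numeric(length(gr))
  nbase <- numeric(length(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  for (ch in unique(chrom)) {
    if (!ch %in% names(sequence)) stop("no sequence for chromosome ", ch)
    idx <- which(chrom == ch)
    if (any(GenomicRanges::end(gr)[idx] > length(sequence[[ch]])))
      stop("region extends beyond the sequence of ", ch)
    v <- Biostrings::Views(sequence[[ch]], start = GenomicRanges::start(gr)[idx],
                           end = GenomicRanges::end(gr)[idx])
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    nbase[idx] <- rowSums(f)
    gc[idx] <- (f[, "C"] + f[, "G"]) / nbase[idx]
  }
  out <- as.data.frame(regions)
  out$gc <- gc
  list(regions = out, mean_gc = sum(gc * nbase) / sum(nbase))
}

#' Roll regions up to cytoband spans
#'
#' For presentation parity with cytoband-level region tables: each region is
#' reported with the range of cytobands it touches and the bp span of that
#' cytoband range.
#'
#' @param regions A `region_set` or data.frame.
#' @param cytobands data.frame or BED4 path: chrom, start, end, name
#'   (0-based half-open).
#' @return The regions with cytoband, band_start, band_end columns added.
#' @export
cytoband_rollup <- function(regions, cytobands) {
  if (is.character(cytobands)) {
    gr <- rtracklayer::import(cytobands)
    cytobands <- granges_to_regions(gr)
    cytobands$name <- gr$name
  }
  cb <- as.data.frame(cytobands)
  if (!"name" %in% names(cb)) stop("cytobands need a name column")
  out <- as.data.frame(regions)
  out$cytoband <- NA_character_
  out$band_start <- NA_integer_
  out$band_end <- NA_integer_
  for (k in seq_len(nrow(out))) {
    hit <- cb$chrom == out$chrom[k] & cb$start < out$end[k] &
      out$start[k] < cb$end
    if (!any(hit)) next
    bands <- cb[hit, , drop = FALSE]
    out$cytoband[k] <- if (nrow(bands) == 1) bands$name else
      paste(bands$name[1], bands$name[nrow(bands)], sep = " - ")
    out$band_start[k] <- min(bands$start)
    out$band_end[k] <- max(bands$end)
  }
  out
}

#' Read and write region BED files
#'
#' Regions travel as BED (0-based half-open); the `group` label goes to the
#' BED name column.
#'
#' @param regions A `region_set` or data.frame.
#' @param path File path.
#' @return `read_regions_bed` returns a `region_set`.
#' @export
write_regions_bed <- function(regions, path) {
  r <- as.data.frame(regions)
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(start = r$start + 1L,
                                                end = r$end))
  if ("group" %in% names(r)) gr$name <- as.character(r$group)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_regions(gr)
  if (!is.null(gr$name)) out$group <- gr$name
  out
}
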