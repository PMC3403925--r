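#' Simulate a genome with a probe layout
#'
#' Generates a small multi-chromosome genome whose base composition follows a
#' first-order Markov chain with a regionally varying GC target, so that
#' GC-rich blocks exist (the substrate of GC-dependent amplification bias),
#' and lays out probes at a configurable spacing along each chromosome, as on
#' a high-density CGH array (roughly one probe every 1--2 kb).
#'
#' Coordinates are 0-based, half-open throughout the package; they are
#' converted only at file-format boundaries (BED is native, the primer-table
#' convention is 1-based inclusive).
#'
#' @param chromosome_lengths Named integer vector of chromosome lengths in bp.
#' @param spacing Length-2 numeric vector: the probe start-to-start spacing is
#'   drawn uniformly from this range (bp).
#' @param probe_length Probe window length in bp.  The default (500) treats
#'   the probe plus its local context as the GC-measurement window, so that
#'   GC-dependent bias acts regionally rather than as per-probe jitter.
#' @param gc_mean Genome-wide GC target.
#' @param gc_block Mean length (bp) of a constant-GC-target block.
#' @param gc_high_prob Probability that a block is a high-GC block.
#' @param gc_high_mean GC target of high-GC blocks; the low-GC target is set
#'   so the genome-wide mean stays at `gc_mean`.
#' @param markov_rho Base-to-base class persistence of the Markov chain in
#'   (0, 1); higher values give longer homogeneous runs.
#' @param seed Optional integer seed; the result is deterministic per seed.
#' @return A `genome_model`: list with `chromosomes` (data.frame of name and
#'   length), `sequence` (a [Biostrings::DNAStringSet]), and `probes` (a
#'   data.frame with probe_id, chrom, start, end, gc), where `gc` is the GC
#'   fraction of the emitted sequence under each probe.
#' @examples
#' g <- simulate_genome(c(chr1 = 50000), seed = 1)
#' head(g$probes)
#' @export
simulate_genome <- function(chromosome_lengths = c(chr1 = 1e6, chr2 = 1e6),
                            spacing = c(1000, 2000),
                            probe_length = 500,
                            gc_mean = 0.41,
                            gc_block = 5e4,
                            gc_high_prob = 0.15,
                            gc_high_mean = 0.55,
                            markov_rho = 0.9,
                            seed = NULL) {
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (length(spacing) != 2L || any(spacing <= 0) || spacing[1] > spacing[2])
    stop("spacing must be an increasing positive range")
  if (any(spacing[1] >= chromosome_lengths))
    stop("probe spacing must be smaller than every chromosome")
  if (!is.null(seed)) set.seed(seed)

  gc_low_mean <- (gc_mean - gc_high_prob * gc_high_mean) / (1 - gc_high_prob)
  bases_weak <- c("A", "T")
  bases_strong <- c("G", "C")

  seqs <- character(length(chromosome_lengths))
  probe_rows <- vector("list", length(chromosome_lengths))
  for (ci in seq_along(chromosome_lengths)) {
    len <- as.integer(chromosome_lengths[ci])
    # block-wise GC targets
    n_blocks <- max(1L, ceiling(len / gc_block))
    high <- runif(n_blocks) < gc_high_prob
    target <- ifelse(high, rnorm(n_blocks, gc_high_mean, 0.02),
                     rnorm(n_blocks, gc_low_mean, 0.02))
    target <- pmin(pmax(target, 0.2), 0.8)
    p <- rep(target, each = gc_block, length.out = len)
    cls <- .markov_gc_classes(p, markov_rho)
    base <- character(len)
    base[cls == 1L] <- sample(bases_strong, sum(cls == 1L), replace = TRUE)
    base[cls == 0L] <- sample(bases_weak, sum(cls == 0L), replace = TRUE)
    seqs[ci] <- paste(base, collapse = "")

    # probe layout: cumulative uniform spacings, probes fully inside
    gaps <- runif(ceiling(len / spacing[1]) + 1L, spacing[1], spacing[2])
    starts <- floor(cumsum(gaps)) - as.integer(spacing[1])
    starts <- starts[starts >= 0 & starts + probe_length <= len]
    probe_rows[[ci]] <- data.frame(
      chrom = names(chromosome_lengths)[ci],
      start = as.integer(starts),
      end = as.integer(starts + probe_length),
      stringsAsFactors = FALSE
    )
  }
  sequence <- Biostrings::DNAStringSet(seqs)
  names(sequence) <- names(chromosome_lengths)

  probes <- do.call(rbind, probe_rows)
  probes <- probes[order(match(probes$chrom, names(chromosome_lengths)),
                         probes$start), , drop = FALSE]
  probes$probe_id <- sprintf("P%06d", seq_len(nrow(probes)))
  probes$gc <- probe_gc(sequence, probes)
  probes <- probes[, c("probe_id", "chrom", "start", "end", "gc")]
  rownames(probes) <- NULL

  structure(
    list(
      chromosomes = data.frame(name = names(chromosome_lengths),
                               length = as.integer(chromosome_lengths),
                               stringsAsFactors = FALSE),
      sequence = sequence,
      probes = probes
    ),
    class = "genome_model"
  )
}

#' GC fraction of probe windows
#'
#' @param sequence A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param probes data.frame with chrom, start, end (0-based half-open).
#' @return Numeric GC fraction per probe.
#' @export
probe_gc <- function(sequence, probes) {
  gc <- numeric(nrow(probes))
  for (chrom in unique(probes$chrom)) {
    idx <- which(probes$chrom == chrom)
    v <- Biostrings::Views(sequence[[chrom]], start = probes$start[idx] + 1L,
                           end = probes$end[idx])
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    gc[idx] <- (f[, "C"] + f[, "G"]) / rowSums(f)
  }
  gc
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic genome:", nrow(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes$length), "bp,", nrow(x$probes), "probes\n")
  cat("  mean probe GC:", round(mean(x$probes$gc), 3), "\n")
  invisible(x)
}

#' Amplification bias model
#'
#' Describes how a whole-genome-amplification kit distorts probe-level log2
#' ratios: a linear GC term (under-amplification of GC-rich DNA when
#' `gc_coefficient < 0`), an exponential depression toward chromosome ends
#' (`telomere_depression * exp(-d / telomere_decay)` at distance `d` from the
#' nearest end), injected copy-number segments, and per-probe Gaussian noise
#' on the log2 scale.  An all-zero model with `noise_sd` at the self-self
#' noise floor represents an unamplified (technical-replicate) hybridization.
#'
#' @param gc_coefficient Log2-ratio units per unit GC deviation from the
#'   genome-mean GC.
#' @param telomere_depression Maximum depression (log2 units, >= 0) at the
#'   chromosome end.
#' @param telomere_decay Decay length (bp, > 0) of the end depression.
#' @param cnv_segments Optional data.frame with columns chrom, start, end
#'   (0-based half-open) and shift (true log2 shift of probes inside).
#' @param noise_sd Per-probe Gaussian sd of the log2 ratio (>= 0).
#' @param kit Kit label carried into downstream reports.
#' @return A `bias_model` object.
#' @seealso [kit_preset()] for the built-in kit parameterizations.
#' @export
bias_model <- function(gc_coefficient = 0, telomere_depression = 0,
                       telomere_decay = 5e4, cnv_segments = NULL,
                       noise_sd = 0, kit = "none") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (telomere_decay <= 0) stop("telomere_decay must be > 0")
  if (!is.null(cnv_segments)) {
    need <- c("chrom", "start", "end", "shift")
    if (!all(need %in% names(cnv_segments)))
      stop("cnv_segments needs columns: ", paste(need, collapse = ", "))
  }
  structure(
    list(gc_coefficient = gc_coefficient,
         telomere_depression = telomere_depression,
         telomere_decay = telomere_decay,
         cnv_segments = cnv_segments,
         noise_sd = noise_sd,
         kit = kit),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat("Bias model [", x$kit, "]: gc coef ", x$gc_coefficient,
      ", telomere ", x$telomere_depression, " log2 (decay ", x$telomere_decay,
      " bp), noise sd ", x$noise_sd, ", ",
      if (is.null(x$cnv_segments)) 0 else nrow(x$cnv_segments),
      " CNV segment(s)\n", sep = "")
  invisible(x)
}

#' Built-in kit bias presets
#'
#' The two MDA kits are parameter presets of one bias model, not separate
#' code paths.  "genomiphi" carries a stronger GC penalty, deeper end
#' depression and more replicate noise than "repli-g", reflecting the
#' consistently larger fraction of fold-change outliers observed for that
#' chemistry; "unamplified" is bias-free with noise at the self-self
#' derivative-log-ratio-spread floor of 0.165.
#'
#' @param kit One of "unamplified", "repli-g", "genomiphi".
#' @param cnv_segments Optional shared CNV/under-amplified segments to inject.
#' @return A [bias_model()].
#' @export
kit_preset <- function(kit = c("unamplified", "repli-g", "genomiphi"),
                       cnv_segments = NULL) {
  kit <- match.arg(kit)
  switch(kit,
    "unamplified" = bias_model(noise_sd = 0.165, kit = "unamplified"),
    "repli-g" = bias_model(gc_coefficient = -3, telomere_depression = 1.5,
                           telomere_decay = 5e4, cnv_segments = cnv_segments,
                           noise_sd = 0.25, kit = "repli-g"),
    "genomiphi" = bias_model(gc_coefficient = -4, telomere_depression = 2,
                             telomere_decay = 5e4, cnv_segments = cnv_segments,
                             noise_sd = 0.33, kit = "genomiphi")
  )
}

# Closed-form expected log2 ratio of every probe under a bias model.
expected_log2_ratio <- function(genome, bias) {
  probes <- genome$probes
  r <- bias$gc_coefficient * (probes$gc - mean(probes$gc))
  chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  mid <- (probes$start + probes$end) / 2
  d <- pmin(mid, chrom_len[probes$chrom] - mid)
  r <- r - bias$telomere_depression * exp(-d / bias$telomere_decay)
  if (!is.null(bias$cnv_segments)) {
    for (k in seq_len(nrow(bias$cnv_segments))) {
      seg <- bias$cnv_segments[k, ]
      if (!seg$chrom %in% genome$chromosomes$name)
        stop("cnv segment on unknown chromosome: ", seg$chrom)
      hit <- probes$chrom == seg$chrom & mid >= seg$start & mid < seg$end
      r[hit] <- r[hit] + seg$shift
    }
  }
  unname(r)
}

#' Simulate one two-channel hybridization
#'
#' Produces probe-level test/reference intensities for one array.  The
#' expected log2 ratio at each probe is the closed-form bias sum (CNV shift +
#' GC term + chromosome-end term); Gaussian noise of sd `noise_sd` is added on
#' the log2 scale.  The reference channel is unbiased: per-probe brightness
#' variation is shared by both channels, so the log2 ratio of the emitted
#' intensities equals the biased ratio exactly when `noise_sd = 0`.
#'
#' @param genome A [simulate_genome()] result.
#' @param bias A [bias_model()].
#' @param seed Optional integer seed for this replicate.
#' @param base_intensity Median reference-channel intensity.
#' @param intensity_sd Sd (log2) of per-probe brightness shared by channels.
#' @param sample,replicate,comparison Labels carried into reports.
#' @return A [probe_array()].
#' @export
simulate_hybridization <- function(genome, bias, seed = NULL,
                                   base_intensity = 1000, intensity_sd = 0.2,
                                   sample = "S1", replicate = 1L,
                                   comparison = "Amp/UnAmp") {
  stopifnot(inherits(genome, "genome_model"), inherits(bias, "bias_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genome$probes)
  r <- expected_log2_ratio(genome, bias) + rnorm(n, 0, bias$noise_sd)
  bright <- base_intensity * 2^rnorm(n, 0, intensity_sd)
  probe_array(genome$probes, test = bright * 2^r, reference = bright,
              sample = sample, kit = bias$kit, replicate = replicate,
              comparison = comparison)
}

#' Simulate a qPCR cycle-threshold table
#'
#' Emulates TaqMan copy-number assays: under perfect doubling the target Ct of
#' a locus at copy number CN sits `log2(CN / 2)` cycles below the diploid
#' reference level, and the reference assay (e.g. RNase P) is flat across
#' samples.  Gaussian cycle noise is added to both channels.
#'
#' @param copy_numbers Named numeric vector: true copy number per locus
#'   (>= 0; 0 marks a homozygous deletion and is emitted at `max_cycles`).
#' @param sample Sample label.
#' @param reference_ct Reference-assay Ct level (cycles).
#' @param efficiency Amplification efficiency (2 = perfect doubling).
#' @param noise_sd Gaussian sd of Ct noise (cycles, >= 0).
#' @param replicates Number of replicate wells per locus.
#' @param max_cycles Cap for undetermined/zero-copy reactions.
#' @param seed Optional integer seed.
#' @return data.frame with columns sample, locus, replicate, ct_target,
#'   ct_reference.
#' @export
simulate_ct_table <- function(copy_numbers, sample = "S1", reference_ct = 25,
                              efficiency = 2, noise_sd = 0, replicates = 1L,
                              max_cycles = 45, seed = NULL) {
  if (any(copy_numbers < 0)) stop("copy numbers must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(copy_numbers)))
    names(copy_numbers) <- paste0("L", seq_along(copy_numbers))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(locus = names(copy_numbers),
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cn <- copy_numbers[grid$locus]
  ct_t <- reference_ct - log(cn / 2) / log(efficiency)
  ct_t <- pmin(ct_t, max_cycles)
  data.frame(sample = sample, locus = grid$locus, replicate = grid$replicate,
             ct_target = ct_t + rnorm(nrow(grid), 0, noise_sd),
             ct_reference = reference_ct + rnorm(nrow(grid), 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Simulate bidirectional Sanger base calls
#'
#' Builds a forward and a reverse base-call string over a reference with
#' injected events: true mutations (both strands agree on the same non-
#' reference base), no-calls ('N' on one strand, or both, chosen at random),
#' and strand-discordant positions (forward and reverse called differently).
#' Position sets must be disjoint; positions are 1-based within the string.
#'
#' @param reference Reference sequence (character string, A/C/G/T).
#' @param mutation_positions,nocall_positions,discordant_positions Disjoint
#'   integer vectors of 1-based positions.
#' @param seed Optional integer seed.
#' @return list(forward=, reverse=) of base-call strings.
#' @export
simulate_bidirectional_reads <- function(reference,
                                         mutation_positions = integer(),
                                         nocall_positions = integer(),
                                         discordant_positions = integer(),
                                         seed = NULL) {
  n <- nchar(reference)
  pos_all <- c(mutation_positions, nocall_positions, discordant_positions)
  if (anyDuplicated(pos_all)) stop("position sets must be disjoint")
  if (length(pos_all) && (min(pos_all) < 1 || max(pos_all) > n))
    stop("positions must lie within the reference")
  if (!is.null(seed)) set.seed(seed)
  ref <- strsplit(toupper(reference), "")[[1]]
  fwd <- ref
  rev <- ref
  other <- function(b) vapply(b, function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  if (length(mutation_positions)) {
    alt <- other(ref[mutation_positions])
    fwd[mutation_positions] <- alt
    rev[mutation_positions] <- alt
  }
  if (length(nocall_positions)) {
    which_strand <- sample(c("fwd", "rev", "both"), length(nocall_positions),
                           replace = TRUE)
    fwd[nocall_positions[which_strand != "rev"]] <- "N"
    rev[nocall_positions[which_strand != "fwd"]] <- "N"
  }
  if (length(discordant_positions)) {
    fwd[discordant_positions] <- other(ref[discordant_positions])
    # reverse keeps the reference base, so the strands disagree and both call
  }
  list(forward = paste(fwd, collapse = ""), reverse = paste(rev, collapse = ""))
}

#' Pick shared under-amplified loci from the GC landscape
#'
#' Selects the `n` highest-GC probe neighbourhoods (non-overlapping windows of
#' `span` bp) and returns them as CNV segments with a common negative log2
#' shift.  Injecting the same segments into every kit's bias model emulates
#' loci that are consistently under-amplified across samples and methods --
#' the GC-rich regions that resist strand displacement.
#'
#' @param genome A [simulate_genome()] result.
#' @param n Number of loci.
#' @param span Window length in bp.
#' @param shift Log2 shift (negative = under-amplified).  The default (-2.5,
#'   about 5.7-fold down) keeps the realized depression beyond a 3-fold
#'   reporting cutoff after median normalization re-centers the profile:
#'   the injected loci emulate regions that are *more* than 3-fold
#'   under-amplified, and the global median sits a few tenths of a log2 unit
#'   below zero under kit-scale GC and chromosome-end bias.
#' @param smooth_probes Probes in the running-mean GC smoother.
#' @return data.frame(chrom, start, end, shift) usable as `cnv_segments`.
#' @export
underamplified_loci <- function(genome, n = 6, span = 25000, shift = -2.5,
                                smooth_probes = 9) {
  probes <- genome$probes
  sm <- unlist(lapply(split(probes$gc, probes$chrom)[unique(probes$chrom)],
                      function(g) {
                        k <- min(smooth_probes, length(g))
                        stats::filter(g, rep(1 / k, k), sides = 2)
                      }), use.names = FALSE)
  ord <- order(sm, decreasing = TRUE, na.last = TRUE)
  picked <- list()
  for (i in ord) {
    if (length(picked) >= n) break
    mid <- (probes$start[i] + probes$end[i]) / 2
    cand <- data.frame(chrom = probes$chrom[i],
                       start = max(0, round(mid - span / 2)),
                       end = round(mid + span / 2), shift = shift,
                       stringsAsFactors = FALSE)
    clen <- genome$chromosomes$length[genome$chromosomes$name == cand$chrom]
    cand$end <- min(cand$end, clen)
    clash <- vapply(picked, function(p)
      p$chrom == cand$chrom && p$start < cand$end + span &&
        cand$start < p$end + span, logical(1))
    if (!any(clash)) picked[[length(picked) + 1L]] <- cand
  }
  out <- do.call(rbind, picked)
  out[order(match(out$chrom, genome$chromosomes$name), out$start), ,
      drop = FALSE]
}
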