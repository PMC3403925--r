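#' Study configuration
#'
#' Declarative description of a full uniformity/fidelity study: which samples
#' and kits, how many replicates, the synthetic genome, and every analysis
#' parameter.  The default is the scaled-down analogue of the canonical
#' design -- 3 samples x 2 kits x 4 replicates plus 4 self-self arrays (28
#' hybridizations) -- with kit bias presets, qPCR Ct noise, and per-kit
#' sequencing exclusion rates matching the magnitudes seen in practice.
#' `preset = "null"` zeroes every bias and noise source (a degenerate
#' control: all distances, threshold percentages and exclusion counts must
#' come out zero).
#'
#' @param samples Sample labels.
#' @param kits Kit names understood by [kit_preset()].
#' @param replicates Replicates per sample x kit cell (>= 2).
#' @param self_self_sample,self_self_replicates The self-self (technical
#'   noise floor) arm.
#' @param genome list(chromosome_lengths=, spacing=) for [simulate_genome()].
#' @param underamplified list(n=, span=, shift=) for [underamplified_loci()];
#'   `n = 0` disables injection.
#' @param analysis Analysis parameters; see Details in the source.
#' @param qpcr list(n_loci=, noise_sd=, replicates=, reference_ct=).
#' @param fidelity list(region_length=, replicates=, exclusion_rate= named
#'   per-kit per-base rate, discordant_share=).
#' @param preset "realistic" (default) or "null".
#' @return A `study_config` list.
#' @export
study_config <- function(samples = c("Normal", "CF1", "CF2"),
                         kits = c("repli-g", "genomiphi"),
                         replicates = 4,
                         self_self_sample = "Normal",
                         self_self_replicates = 4,
                         genome = list(
                           chromosome_lengths = c(chr1 = 4e5, chr2 = 4e5),
                           spacing = c(1000, 2000)),
                         underamplified = list(n = 4, span = 25000,
                                               shift = -2.5),
                         analysis = list(),
                         qpcr = list(),
                         fidelity = list(),
                         preset = c("realistic", "null")) {
  preset <- match.arg(preset)
  if (replicates < 2) stop("replicates must be >= 2 for within-group matrices")
  analysis_defaults <- list(
    normalize = TRUE, cbs_alpha = 0.01, cbs_permutations = 200,
    cbs_min_width = 2, cbs_undo_sd = 1, cnv_fold_cutoff = 2,
    aberration_fold_cutoff = 3, aberration_min_probes = 3,
    threshold_cutoffs = c(1.5, 2, 2.5, 3, 4), gap_tolerance = 0)
  qpcr_defaults <- list(n_loci = 10, noise_sd = 0.05, replicates = 4,
                        reference_ct = 25)
  fidelity_defaults <- list(
    region_length = 2000, replicates = 4,
    exclusion_rate = c("repli-g" = 11 / 23744, "genomiphi" = 53 / 23744),
    discordant_share = 0.5)
  analysis <- utils::modifyList(analysis_defaults, analysis)
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  fidelity <- utils::modifyList(fidelity_defaults, as.list(fidelity))
  if (is.unsorted(analysis$threshold_cutoffs))
    stop("threshold_cutoffs must be ascending")
  kit_params <- lapply(kits, function(k) {
    b <- kit_preset(k)
    b[c("gc_coefficient", "telomere_depression", "telomere_decay", "noise_sd")]
  })
  names(kit_params) <- kits
  self_noise <- 0.165
  if (preset == "null") {
    kit_params <- lapply(kit_params, function(p) {
      p$gc_coefficient <- 0; p$telomere_depression <- 0; p$noise_sd <- 0; p
    })
    self_noise <- 0
    underamplified$n <- 0
    qpcr$noise_sd <- 0
    fidelity$exclusion_rate[] <- 0
  }
  structure(
    list(samples = samples, kits = kits, kit_params = kit_params,
         replicates = replicates, self_self_sample = self_self_sample,
         self_self_replicates = self_self_replicates,
         self_self_noise_sd = self_noise,
         genome = genome, underamplified = underamplified,
         analysis = analysis, qpcr = qpcr, fidelity = fidelity,
         preset = preset),
    class = "study_config"
  )
}

#' Read a study configuration from a JSON file
#'
#' Fields present in the file override [study_config()] defaults; the file
#' is a single declarative document.
#'
#' @param path JSON file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading JSON configs requires the jsonlite package")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$genome$chromosome_lengths))
    raw$genome$chromosome_lengths <- unlist(raw$genome$chromosome_lengths)
  do.call(study_config, raw)
}

comparison_label <- function(kit) {
  switch(kit, "repli-g" = "Amp-R/UnAmp", "genomiphi" = "Amp-G/UnAmp",
         "unamplified" = "UnAmp/UnAmp", paste0("Amp[", kit, "]/UnAmp"))
}

#' Run a full uniformity/fidelity study
#'
#' Simulates the configured design end to end and computes the complete
#' report bundle: per-group fold-change threshold tables; within-group and
#' between-group Kolmogorov and Phi pairwise matrices with medians
#' (amplified-vs-self-self and kit-vs-kit); replicate-combined aberration
#' reports intersected into common under-amplified regions with genome
#' fraction and GC summary; qPCR relative copy numbers against the
#' unamplified calibrator; and a bidirectional-sequencing fidelity report.
#' Every random draw descends from `seed` through stable per-stage child
#' seeds, so a bundle is byte-reproducible from (config, seed).
#'
#' If `out_dir` is given, the bundle is written there as TSV/BED files plus
#' a `run_log.txt`; on any stage failure the partially written files are
#' removed and a stage-labelled error is raised.
#'
#' @param config A [study_config()].
#' @param seed Root integer seed.
#' @param out_dir Optional output directory.
#' @return The report bundle (a `study_bundle` list), invisibly when
#'   `out_dir` is given.
#' @export
run_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  log_lines <- character()
  warn_lines <- character()
  written <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        warn_lines <<- c(warn_lines, paste0("[", name, "] ",
                                            conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        if (length(written)) unlink(written)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
  }
  an <- config$analysis

  # --- genome -------------------------------------------------------------
  genome <- stage("genome", {
    g <- simulate_genome(
      chromosome_lengths = config$genome$chromosome_lengths,
      spacing = config$genome$spacing,
      seed = derive_seed(seed, "genome"))
    note("[genome] ", nrow(g$probes), " probes on ",
         nrow(g$chromosomes), " chromosome(s); seed ",
         derive_seed(seed, "genome"))
    g
  })
  loci <- stage("loci", {
    if (config$underamplified$n > 0) {
      l <- underamplified_loci(genome, n = config$underamplified$n,
                               span = config$underamplified$span,
                               shift = config$underamplified$shift)
      note("[loci] ", nrow(l), " shared under-amplified loci, shift ",
           config$underamplified$shift)
      l
    } else NULL
  })

  # --- hybridizations -----------------------------------------------------
  groups <- list()
  for (s in config$samples)
    for (k in config$kits)
      groups[[paste(s, comparison_label(k))]] <-
        list(sample = s, kit = k, comparison = comparison_label(k),
             n = config$replicates, amplified = TRUE)
  ss <- config$self_self_sample
  groups[[paste(ss, "UnAmp/UnAmp")]] <-
    list(sample = ss, kit = "unamplified", comparison = "UnAmp/UnAmp",
         n = config$self_self_replicates, amplified = FALSE)

  profiles <- stage("hybridization", {
    lapply(groups, function(grp) {
      if (grp$amplified) {
        p <- config$kit_params[[grp$kit]]
        bias <- bias_model(gc_coefficient = p$gc_coefficient,
                           telomere_depression = p$telomere_depression,
                           telomere_decay = p$telomere_decay,
                           cnv_segments = loci, noise_sd = p$noise_sd,
                           kit = grp$kit)
      } else {
        bias <- bias_model(noise_sd = config$self_self_noise_sd,
                           kit = "unamplified")
      }
      lapply(seq_len(grp$n), function(rep) {
        arr <- simulate_hybridization(
          genome, bias, seed = derive_seed(seed, grp$sample, grp$kit, rep),
          sample = grp$sample, replicate = rep, comparison = grp$comparison)
        compute_log2_ratios(arr, normalize = an$normalize)
      })
    })
  })
  note("[hybridization] ", sum(vapply(groups, `[[`, numeric(1), "n")),
       " arrays simulated; normalize=", an$normalize)

  # --- segmentation and CNV calls per replicate ---------------------------
  calls <- stage("segmentation", {
    out <- lapply(names(profiles), function(gname) {
      lapply(seq_along(profiles[[gname]]), function(rep) {
        prof <- profiles[[gname]][[rep]]
        seg <- cbs_segment(prof, alpha = an$cbs_alpha,
                           n_permutations = an$cbs_permutations,
                           min_width = an$cbs_min_width,
                           undo_sd = an$cbs_undo_sd,
                           seed = derive_seed(seed, "cbs", gname, rep))
        call_cnv(smooth_profile(prof, seg),
                 fold_cutoff = an$cnv_fold_cutoff)
      })
    })
    names(out) <- names(profiles)
    out
  })
  note("[segmentation] alpha=", an$cbs_alpha, " permutations=",
       an$cbs_permutations, " cnv fold cutoff=", an$cnv_fold_cutoff)

  # --- threshold tables ---------------------------------------------------
  thresholds <- stage("thresholds", {
    rows <- lapply(names(profiles), function(gname) {
      tt <- threshold_table(profiles[[gname]], cutoffs = an$threshold_cutoffs,
                            group = gname)
      stats::setNames(
        cbind(data.frame(sample = groups[[gname]]$sample,
                         comparison = groups[[gname]]$comparison,
                         stringsAsFactors = FALSE),
              as.data.frame(t(tt$percent))),
        c("sample", "comparison", paste0("pct_gt_", an$threshold_cutoffs)))
    })
    do.call(rbind, rows)
  })
  note("[thresholds] cutoffs=", paste(an$threshold_cutoffs, collapse = ","))

  # --- pairwise consistency matrices --------------------------------------
  matrices <- stage("uniformity", {
    m <- list(within_kolmogorov = list(), within_phi = list(),
              amp_vs_self_kolmogorov = list(),
              between_kits_kolmogorov = list(), between_kits_phi = list())
    for (gname in names(profiles)) {
      m$within_kolmogorov[[gname]] <-
        pairwise_matrix(profiles[[gname]], metric = "kolmogorov",
                        group_label = gname)
      m$within_phi[[gname]] <-
        pairwise_matrix(calls[[gname]], metric = "phi", group_label = gname)
    }
    self_name <- paste(ss, "UnAmp/UnAmp")
    for (k in config$kits) {
      amp_name <- paste(ss, comparison_label(k))
      m$amp_vs_self_kolmogorov[[amp_name]] <-
        pairwise_matrix(profiles[[amp_name]], profiles[[self_name]],
                        metric = "kolmogorov", group_label = amp_name,
                        group_label_b = self_name)
    }
    if (length(config$kits) >= 2) {
      k1 <- config$kits[1]; k2 <- config$kits[2]
      for (s in config$samples) {
        n1 <- paste(s, comparison_label(k1))
        n2 <- paste(s, comparison_label(k2))
        m$between_kits_kolmogorov[[s]] <-
          pairwise_matrix(profiles[[n1]], profiles[[n2]],
                          metric = "kolmogorov", group_label = n1,
                          group_label_b = n2)
        m$between_kits_phi[[s]] <-
          pairwise_matrix(calls[[n1]], calls[[n2]], metric = "phi",
                          group_label = n1, group_label_b = n2)
      }
    }
    m
  })
  medians <- stage("uniformity", {
    rows <- list()
    for (fam in names(matrices))
      for (gname in names(matrices[[fam]]))
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, group = gname,
          median = matrix_median(matrices[[fam]][[gname]]),
          stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
  note("[uniformity] ", nrow(medians), " matrix medians computed")

  # --- combined profiles, aberrations, common regions ---------------------
  regions <- stage("regions", {
    amp_names <- names(groups)[vapply(groups, `[[`, logical(1), "amplified")]
    per_group <- list()
    for (gname in amp_names) {
      comb <- combine_replicates(profiles[[gname]])
      seg <- cbs_segment(comb, alpha = an$cbs_alpha,
                         n_permutations = an$cbs_permutations,
                         min_width = an$cbs_min_width,
                         undo_sd = an$cbs_undo_sd,
                         seed = derive_seed(seed, "cbs-combined", gname))
      per_group[[gname]] <- aberration_report(
        smooth_profile(comb, seg), fold_cutoff = an$aberration_fold_cutoff,
        min_probes = an$aberration_min_probes, group = gname)
    }
    common <- common_regions(per_group, gap_tolerance = an$gap_tolerance,
                             direction = "loss")
    lens <- stats::setNames(genome$chromosomes$length,
                            genome$chromosomes$name)
    frac <- genome_fraction(common, lens)
    gc <- if (nrow(common)) region_gc(common, genome)
      else list(regions = common, mean_gc = NA_real_)
    list(per_group = per_group, common = gc$regions,
         genome_fraction = frac, mean_gc = gc$mean_gc,
         genome_mean_gc = mean(genome$probes$gc))
  })
  note("[regions] ", nrow(regions$common), " common under-amplified ",
       "region(s); genome fraction ", sprintf("%.3f", regions$genome_fraction),
       "%; mean GC ", sprintf("%.3f", regions$mean_gc))

  # --- qPCR ---------------------------------------------------------------
  qpcr <- stage("qpcr", {
    loci_names <- as.character(utils::as.roman(seq_len(config$qpcr$n_loci)))
    cn <- stats::setNames(rep(2, config$qpcr$n_loci), loci_names)
    res <- list()
    for (s in config$samples) {
      cal_label <- paste(s, "UnAmp")
      ct <- simulate_ct_table(cn, sample = cal_label,
                              reference_ct = config$qpcr$reference_ct,
                              noise_sd = config$qpcr$noise_sd,
                              replicates = config$qpcr$replicates,
                              seed = derive_seed(seed, "qpcr", s, "unamp"))
      for (k in config$kits)
        ct <- rbind(ct, simulate_ct_table(
          cn, sample = paste(s, comparison_label(k)),
          reference_ct = config$qpcr$reference_ct,
          noise_sd = config$qpcr$noise_sd,
          replicates = config$qpcr$replicates,
          seed = derive_seed(seed, "qpcr", s, k)))
      res[[s]] <- estimate_copy_number(ct, calibrator = cal_label)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    class(out) <- c("copy_number_result", "data.frame")
    out
  })
  note("[qpcr] ", config$qpcr$n_loci, " loci x ", config$qpcr$replicates,
       " replicates; Ct noise sd ", config$qpcr$noise_sd)

  # --- sequencing fidelity ------------------------------------------------
  fidelity <- stage("fidelity", {
    len <- config$fidelity$region_length
    chr1 <- as.character(genome$sequence[[1]])
    from <- max(1L, floor(nchar(chr1) / 2) - floor(len / 2))
    ref <- substr(chr1, from, from + len - 1L)
    comparisons <- list()
    for (s in config$samples)
      for (k in config$kits) {
        rate <- config$fidelity$exclusion_rate[[k]] %||% 0
        for (rep in seq_len(config$fidelity$replicates)) {
          set.seed(derive_seed(seed, "fidelity", s, k, rep))
          n_excl <- stats::rbinom(1, len, rate)
          pos <- sample.int(len, n_excl)
          n_disc <- round(n_excl * config$fidelity$discordant_share)
          reads <- simulate_bidirectional_reads(
            ref, nocall_positions = pos[seq_len(n_excl - n_disc)],
            discordant_positions = if (n_disc) pos[(n_excl - n_disc + 1):n_excl]
              else integer())
          comparisons[[length(comparisons) + 1L]] <-
            compare_bidirectional(reads$forward, reads$reverse, ref,
                                  sample = s, kit = k)
        }
      }
    list(comparisons = comparisons, report = fidelity_report(comparisons))
  })
  note("[fidelity] ", length(fidelity$comparisons), " read pairs over ",
       config$fidelity$region_length, " bp")

  bundle <- structure(
    list(config = config, seed = seed, genome = genome, loci = loci,
         profiles = profiles, calls = calls, thresholds = thresholds,
         matrices = matrices, medians = medians, regions = regions,
         qpcr = qpcr, fidelity = fidelity, log = log_lines,
         warnings = warn_lines),
    class = "study_bundle")

  if (!is.null(out_dir)) {
    stage("write", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      wt <- function(d, f) {
        p <- file.path(out_dir, f)
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
        written <<- c(written, p)
      }
      wt(bundle$thresholds, "threshold_tables.tsv")
      for (fam in names(bundle$matrices))
        for (gname in names(bundle$matrices[[fam]])) {
          f <- file.path(out_dir, paste0(
            fam, "_", gsub("[^A-Za-z0-9]+", "_", gname), ".tsv"))
          write_pairwise_matrix(bundle$matrices[[fam]][[gname]], f)
          written <<- c(written, f)
        }
      wt(bundle$medians, "matrix_medians.tsv")
      if (nrow(bundle$regions$common)) {
        p <- file.path(out_dir, "common_underamplified.bed")
        write_regions_bed(bundle$regions$common, p)
        written <<- c(written, p)
      }
      wt(data.frame(genome_fraction_pct = bundle$regions$genome_fraction,
                    region_mean_gc = bundle$regions$mean_gc,
                    genome_mean_gc = bundle$regions$genome_mean_gc),
         "region_summary.tsv")
      wt(bundle$regions$common, "common_underamplified.tsv")
      wt(bundle$qpcr, "qpcr_copy_number.tsv")
      wt(bundle$fidelity$report, "fidelity_report.tsv")
      log_all <- c(paste0("seed\t", seed),
                   paste0("preset\t", config$preset),
                   bundle$log,
                   if (length(bundle$warnings))
                     paste0("[warning] ", bundle$warnings))
      p <- file.path(out_dir, "run_log.txt")
      writeLines(log_all, p)
      written <<- c(written, p)
    })
    return(invisible(bundle))
  }
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Study bundle: ", length(x$profiles), " groups, seed ", x$seed,
      " (", x$config$preset, " preset)\n", sep = "")
  cat("  matrix medians:\n")
  print(within(x$medians, median <- round(median, 3)), row.names = FALSE)
  cat("  common under-amplified regions:", nrow(x$regions$common),
      sprintf("(%.2f%% of genome, mean GC %.3f vs genome %.3f)\n",
              x$regions$genome_fraction, x$regions$mean_gc,
              x$regions$genome_mean_gc))
  cat("  qPCR cells flagged:", sum(x$qpcr$flagged), "of", nrow(x$qpcr), "\n")
  cat("  fidelity: ", sum(x$fidelity$report$mutations), " mutation(s) in ",
      sum(x$fidelity$report$examined), " examined bases\n", sep = "")
  invisible(x)
}
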