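#' Read a qPCR cycle-threshold table
#'
#' TSV dialect: `sample locus replicate ct_target ct_reference`.  Ct values
#' must be positive and finite.
#'
#' @param path File path.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "locus", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(d$ct_target)) || any(!is.finite(d$ct_reference)) ||
      any(d$ct_target <= 0) || any(d$ct_reference <= 0))
    stop("Ct values must be positive and finite")
  d
}

#' Delta-Ct of one or more records
#'
#' Target-assay Ct minus reference-assay Ct (e.g. RNase P) within the same
#' well/sample.
#'
#' @param ct_target,ct_reference Ct values (cycles).
#' @return ct_target - ct_reference.
#' @export
delta_ct <- function(ct_target, ct_reference) ct_target - ct_reference

#' Relative copy number from delta-delta-Ct
#'
#' The comparative-Ct model with amplification efficiency E:
#' `CN = calibrator_cn * E^-(dct_sample - dct_calibrator)`.  With perfect
#' doubling (E = 2) and a diploid calibrator this is the familiar
#' `2 * 2^-ddCt`.
#'
#' @param dct_sample,dct_calibrator Delta-Ct of the sample and of the
#'   calibrator (the unamplified DNA the result is standardized to).
#' @param calibrator_cn Copy number of the calibrator (> 0); default 2.
#' @param efficiency Amplification efficiency; default 2 (perfect doubling).
#' @return Estimated copy number (>= 0).
#' @export
copy_number <- function(dct_sample, dct_calibrator, calibrator_cn = 2,
                        efficiency = 2) {
  if (calibrator_cn <= 0) stop("calibrator_cn must be > 0")
  calibrator_cn * efficiency^(-(dct_sample - dct_calibrator))
}

#' Summarize replicate copy-number estimates
#'
#' Mean, minimum and maximum across replicate measurements (the min/max bars
#' of a replicate plot), with a flag raised when any replicate deviates from
#' the calibrator by more than `flag_fold`-fold in either direction.
#'
#' @param cn Numeric vector of replicate copy-number estimates (>= 1 value).
#' @param calibrator_cn Calibrator copy number for flagging.
#' @param flag_fold Fold-deviation threshold; default 2.
#' @return One-row data.frame: mean_cn, min_cn, max_cn, n, flagged.
#' @export
summarize_cn <- function(cn, calibrator_cn = 2, flag_fold = 2) {
  if (!length(cn)) stop("need at least one replicate")
  data.frame(mean_cn = mean(cn), min_cn = min(cn), max_cn = max(cn),
             n = length(cn),
             flagged = max(cn) / calibrator_cn > flag_fold |
               calibrator_cn / min(cn) > flag_fold)
}

#' Estimate copy numbers for all samples and loci of a Ct table
#'
#' Computes per-well delta-Ct, references each sample/locus against the
#' calibrator sample's mean delta-Ct at the same locus (delta-delta-Ct),
#' converts to relative copy number, and summarizes replicates at the
#' copy-number scale.
#'
#' @param ct_table data.frame as returned by [read_ct_table()] or
#'   [simulate_ct_table()] (the calibrator sample's rows included).
#' @param calibrator Name of the calibrator sample present in the table.
#' @param calibrator_cn,efficiency,flag_fold See [copy_number()] and
#'   [summarize_cn()].
#' @return A `copy_number_result` data.frame: sample, locus, mean_cn,
#'   min_cn, max_cn, n, flagged.
#' @export
estimate_copy_number <- function(ct_table, calibrator, calibrator_cn = 2,
                                 efficiency = 2, flag_fold = 2) {
  if (!calibrator %in% ct_table$sample)
    stop("calibrator sample not present in the Ct table")
  ct_table$dct <- delta_ct(ct_table$ct_target, ct_table$ct_reference)
  cal <- ct_table[ct_table$sample == calibrator, ]
  cal_dct <- tapply(cal$dct, cal$locus, mean)
  rows <- list()
  for (s in unique(ct_table$sample)) {
    d <- ct_table[ct_table$sample == s, ]
    for (l in unique(d$locus)) {
      if (!l %in% names(cal_dct))
        stop("locus ", l, " missing from the calibrator sample")
      cn <- copy_number(d$dct[d$locus == l], cal_dct[[l]],
                        calibrator_cn, efficiency)
      row <- summarize_cn(cn, calibrator_cn, flag_fold)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample = s, locus = l, stringsAsFactors = FALSE), row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("copy_number_result", "data.frame")
  out
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat("Relative copy number (", nrow(x), " sample x locus cells, ",
      sum(x$flagged), " flagged)\n", sep = "")
  y <- x
  y$mean_cn <- round(y$mean_cn, 3)
  y$min_cn <- round(y$min_cn, 3)
  y$max_cn <- round(y$max_cn, 3)
  print.data.frame(y, ...)
  invisible(x)
}
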