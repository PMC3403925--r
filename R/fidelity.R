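#' Amplicon length from primer coordinates
#'
#' Primer tables use the 1-based inclusive convention, so an amplicon running
#' from the first base of the forward primer to the last base of the reverse
#' primer spans `rev_end - fwd_start + 1` bases.  (Everything else in the
#' package is 0-based half-open; the conversion happens here.)
#'
#' @param fwd_start 1-based start of the forward primer on the reference.
#' @param rev_end 1-based end of the reverse primer.
#' @return Amplicon length in bp.
#' @export
amplicon_length <- function(fwd_start, rev_end) {
  if (any(rev_end < fwd_start)) stop("inverted primer coordinates")
  rev_end - fwd_start + 1
}

#' Read a sequencing-primer table
#'
#' TSV dialect mirroring a published primer table: columns `primer_name`
#' (amplicon name suffixed `_F`/`_R`), `location` (`start-end`, 1-based
#' inclusive; reverse primers may list coordinates descending), `sequence`,
#' `tm`, and optionally `amplicon_size`.  Returns one row per amplicon with
#' the expected length computed from the outermost primer coordinates via
#' [amplicon_length()].
#'
#' @param path File path.
#' @return data.frame: amplicon, fwd_start, fwd_end, fwd_seq, rev_start,
#'   rev_end, rev_seq, length.
#' @export
read_primer_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("primer_name", "location", "sequence")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("primer table lacks column(s): ", paste(miss, collapse = ", "))
  loc <- strsplit(d$location, "-")
  d$loc_start <- vapply(loc, function(x) min(as.numeric(x)), numeric(1))
  d$loc_end <- vapply(loc, function(x) max(as.numeric(x)), numeric(1))
  d$amplicon <- sub("_[FR]$", "", d$primer_name)
  d$dir <- sub("^.*_", "", d$primer_name)
  rows <- lapply(unique(d$amplicon), function(a) {
    f <- d[d$amplicon == a & d$dir == "F", ]
    r <- d[d$amplicon == a & d$dir == "R", ]
    if (nrow(f) != 1 || nrow(r) != 1)
      stop("amplicon ", a, " needs exactly one _F and one _R primer")
    data.frame(amplicon = a,
               fwd_start = f$loc_start, fwd_end = f$loc_end,
               fwd_seq = f$sequence,
               rev_start = r$loc_start, rev_end = r$loc_end,
               rev_seq = r$sequence,
               length = amplicon_length(f$loc_start, r$loc_end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bidirectional-read concordance against a reference
#'
#' Classifies every aligned position of a forward/reverse base-call pair
#' against the (unamplified) reference, applying the exclusion rules of
#' bidirectional Sanger confirmation: a position where either strand (or the
#' reference) has no call ('N') is excluded as a no-call; a position where
#' both strands are called but disagree is excluded as discordant (no-call
#' takes precedence); a position where both strands agree on a base that
#' differs from the reference is a mutation; everything else is a concordant
#' match.  The three inputs must be pre-aligned, gap-free, equal-length
#' strings in the same orientation (see [align_to_reference()]).
#'
#' @param forward,reverse,reference Base-call strings (A/C/G/T/N).
#' @param sample,kit Labels carried into reports.
#' @return A `sequence_comparison`: counts (aligned, examined,
#'   excluded_nocall, excluded_discordant) and a `mutations` data.frame
#'   (position, reference, call).
#' @export
compare_bidirectional <- function(forward, reverse, reference,
                                  sample = NA_character_,
                                  kit = NA_character_) {
  if (nchar(forward) != nchar(reverse) || nchar(forward) != nchar(reference))
    stop("forward, reverse and reference must have equal length")
  f <- strsplit(toupper(forward), "")[[1]]
  r <- strsplit(toupper(reverse), "")[[1]]
  ref <- strsplit(toupper(reference), "")[[1]]
  ok <- c("A", "C", "G", "T", "N")
  if (!all(c(f, r, ref) %in% ok)) stop("alphabet must be A/C/G/T/N")
  nocall <- f == "N" | r == "N" | ref == "N"
  discord <- !nocall & f != r
  mut <- !nocall & !discord & f != ref
  mutations <- data.frame(position = which(mut), reference = ref[mut],
                          call = f[mut], stringsAsFactors = FALSE)
  structure(
    list(sample = sample, kit = kit,
         aligned = length(f),
         examined = length(f) - sum(nocall) - sum(discord),
         excluded_nocall = sum(nocall),
         excluded_discordant = sum(discord),
         mutations = mutations),
    class = "sequence_comparison"
  )
}

#' @export
print.sequence_comparison <- function(x, ...) {
  cat("Sequence comparison [sample:", x$sample, " kit:", x$kit, "]\n")
  cat("  aligned:", x$aligned, " examined:", x$examined,
      " excluded: ", x$excluded_nocall, "no-call +",
      x$excluded_discordant, "discordant\n")
  cat("  mutations:", nrow(x$mutations), "\n")
  invisible(x)
}

#' Percent of aligned bases excluded
#'
#' @param excluded Number of excluded bases.
#' @param aligned Number of aligned bases (> 0).
#' @param digits Optional decimals to round the report to.
#' @return Percent excluded.
#' @examples
#' exclusion_rate(53, 23744, digits = 1)   # 0.2
#' exclusion_rate(11, 23744, digits = 2)   # 0.05
#' @export
exclusion_rate <- function(excluded, aligned, digits = NULL) {
  if (any(aligned <= 0)) stop("aligned must be > 0")
  pct <- 100 * excluded / aligned
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Mutation rate with an upper bound for zero counts
#'
#' Point rate `mutations / examined`.  When no mutations are seen, the
#' detection limit is reported in the "fewer than one per N" convention as
#' `1 / examined`, together with the one-sided 95% rule-of-three bound
#' `3 / examined`.
#'
#' @param mutations Mutation count.
#' @param examined Number of examined (non-excluded) bases (> 0).
#' @return list(point=, bound=, rule_of_three=); the latter two are NA when
#'   mutations > 0.
#' @export
mutation_rate_bound <- function(mutations, examined) {
  if (examined <= 0) stop("examined must be > 0")
  list(point = mutations / examined,
       bound = if (mutations == 0) 1 / examined else NA_real_,
       rule_of_three = if (mutations == 0) 3 / examined else NA_real_)
}

#' Fidelity report across sample/kit groups
#'
#' Aggregates `sequence_comparison` objects by (sample, kit): nucleotides
#' examined, mutation counts, and the mutation percentage -- printed as the
#' explicit detection bound "<x" when the count is zero.
#'
#' @param comparisons List of [compare_bidirectional()] results.
#' @return data.frame: sample, kit, examined, mutations, percentage (number),
#'   percentage_label (text with "<" bound for zero counts).
#' @export
fidelity_report <- function(comparisons) {
  key <- vapply(comparisons, function(x) paste(x$sample, x$kit, sep = "\r"),
                character(1))
  rows <- lapply(unique(key), function(k) {
    grp <- comparisons[key == k]
    examined <- sum(vapply(grp, `[[`, numeric(1), "examined"))
    muts <- sum(vapply(grp, function(x) nrow(x$mutations), numeric(1)))
    rate <- mutation_rate_bound(muts, examined)
    pct <- 100 * if (muts == 0) rate$bound else rate$point
    data.frame(sample = grp[[1]]$sample, kit = grp[[1]]$kit,
               examined = examined, mutations = muts,
               percentage = pct,
               percentage_label = if (muts == 0)
                 sprintf("<%.3g", pct) else sprintf("%.3g", pct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-register a read with its reference by global alignment
#'
#' Convenience wrapper around a Needleman-Wunsch global alignment (match 1,
#' mismatch -1, gap -2) for call strings that differ from the reference by
#' offsets.  Columns containing an indel in either sequence are dropped, so
#' the returned pair is gap-free, equal-length, and directly usable by
#' [compare_bidirectional()]; the per-position rules never see indel columns.
#'
#' @param read,reference Nucleotide strings.
#' @return list(read=, reference=) of gap-free aligned strings.
#' @export
align_to_reference <- function(read, reference) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(reference),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- p != "-" & s != "-"
  list(read = paste(p[keep], collapse = ""),
       reference = paste(s[keep], collapse = ""))
}
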