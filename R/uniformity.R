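#' Kolmogorov distance between two samples
#'
#' The supremum of the absolute difference between the two empirical
#' distribution functions (the two-sample Kolmogorov-Smirnov statistic, with
#' no p-value attached): a value in \[0, 1\], 0 for identical samples, 1 for
#' disjoint supports.  ECDFs are right-continuous and the supremum is
#' attained at pooled sample points.
#'
#' @param a,b Non-empty numeric vectors, or raw `ratio_profile`s (their
#'   log2 ratios are compared).
#' @return The distance in \[0, 1\].
#' @examples
#' kolmogorov_distance(c(0, 1, 2, 3), c(0, 1, 2, 100))  # 0.25
#' @export
kolmogorov_distance <- function(a, b) {
  if (inherits(a, "ratio_profile")) a <- a$log2_ratio
  if (inherits(b, "ratio_profile")) b <- b$log2_ratio
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  va <- sort(a)
  vb <- sort(b)
  pool <- sort(unique(c(va, vb)))
  fa <- findInterval(pool, va) / length(va)
  fb <- findInterval(pool, vb) / length(vb)
  max(abs(fa - fb))
}

#' Phi correlation of two binary CNV-location vectors
#'
#' Association of two 0/1 vectors through their 2x2 agreement table:
#' `(n11 n00 - n10 n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00))`,
#' identical to the Pearson correlation of the two vectors.  Degenerate
#' cases: identical vectors (including all-zero, the self-self case with no
#' CNVs anywhere) give 1; differing vectors with a degenerate marginal give
#' 0 with a warning.
#'
#' @param a,b Equal-length 0/1 vectors or `cnv_calls` on one probe set.
#' @return Value in \[-1, 1\].
#' @export
phi_correlation <- function(a, b) {
  if (inherits(a, "cnv_calls") && inherits(b, "cnv_calls"))
    stopifnot_same_probes(a$probes, b$probes)
  if (inherits(a, "cnv_calls")) a <- a$calls
  if (inherits(b, "cnv_calls")) b <- b$calls
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (!all(a %in% 0:1) || !all(b %in% 0:1)) stop("vectors must be binary 0/1")
  if (all(a == b)) return(1.0)
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  n00 <- sum(a == 0 & b == 0)
  den <- sqrt(n11 + n10) * sqrt(n01 + n00) * sqrt(n11 + n01) * sqrt(n10 + n00)
  if (den == 0) {
    warning("degenerate marginal in Phi correlation; returning 0")
    return(0.0)
  }
  (n11 * n00 - n10 * n01) / den
}

#' Pairwise metric matrix for replicate groups
#'
#' Evaluates a consistency metric on every pair of replicates.  In
#' within-group mode (one group) the matrix is square and symmetric with the
#' metric's self-value on the diagonal (0 for Kolmogorov, 1 for Phi); the
#' group median is taken over the unique unordered pairs (6 pairs for 4
#' replicates).  In between-group mode (two groups) every ordered cell is
#' filled (16 cells for 4 x 4) and the median runs over all cells.
#'
#' @param group_a List of raw `ratio_profile`s (Kolmogorov) or `cnv_calls`
#'   (Phi); at least 2 members within-group.
#' @param group_b Optional second group for between-group mode.
#' @param metric "kolmogorov" or "phi".
#' @param group_label,group_label_b Labels for reports.
#' @return A `pairwise_matrix` object.
#' @export
pairwise_matrix <- function(group_a, group_b = NULL,
                            metric = c("kolmogorov", "phi"),
                            group_label = "group A",
                            group_label_b = "group B") {
  metric <- match.arg(metric)
  fun <- switch(metric, kolmogorov = kolmogorov_distance, phi = phi_correlation)
  within <- is.null(group_b)
  if (within && length(group_a) < 2)
    stop("within-group mode needs at least 2 replicates")
  if (!within && (!length(group_a) || !length(group_b)))
    stop("between-group mode needs at least 1 replicate per group")
  b <- if (within) group_a else group_b
  values <- matrix(NA_real_, length(group_a), length(b),
                   dimnames = list(paste("Replicate", seq_along(group_a)),
                                   paste("Replicate", seq_along(b))))
  for (i in seq_along(group_a))
    for (j in seq_along(b)) {
      if (within && j > i) next
      values[i, j] <- fun(group_a[[i]], b[[j]])
    }
  if (within) values[upper.tri(values)] <- t(values)[upper.tri(values)]
  structure(
    list(values = values,
         mode = if (within) "within" else "between",
         metric = metric,
         group_a = group_label,
         group_b = if (within) group_label else group_label_b),
    class = "pairwise_matrix"
  )
}

#' Construct a pairwise matrix from given values
#'
#' Wraps an already-computed grid of metric values (for example the cells of
#' a published pairwise table) so that [matrix_median()] and the exporters
#' apply to it.
#'
#' @param values Numeric matrix.
#' @param mode "within" or "between".
#' @param metric Metric name.
#' @param group_a,group_b Labels.
#' @return A `pairwise_matrix`.
#' @export
as_pairwise_matrix <- function(values, mode = c("within", "between"),
                               metric = "kolmogorov", group_a = "group A",
                               group_b = group_a) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (mode == "within" && nrow(values) != ncol(values))
    stop("within-group matrices must be square")
  structure(list(values = values, mode = mode, metric = metric,
                 group_a = group_a, group_b = group_b),
            class = "pairwise_matrix")
}

#' Median of a pairwise matrix
#'
#' Within-group: the median of the unique off-diagonal unordered pairs (the
#' lower triangle).  Between-group: the median of all cells.  Even counts
#' take the midpoint of the two central order statistics.
#'
#' @param m A `pairwise_matrix`.
#' @return The median value.
#' @export
matrix_median <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"))
  v <- if (m$mode == "within") m$values[lower.tri(m$values)] else as.vector(m$values)
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty matrix")
  median(v)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("Pairwise", x$metric, "matrix (", x$mode, "-group )\n", sep = "")
  if (x$mode == "within") cat("  group:", x$group_a, "\n")
  else cat("  rows:", x$group_a, " columns:", x$group_b, "\n")
  print(round(x$values, 3))
  cat("  median:", round(matrix_median(x), 3), "\n")
  invisible(x)
}

#' Write a pairwise matrix as TSV
#'
#' Mirrors the published table layout: commented header lines carrying the
#' metric, mode and group labels, the labelled value grid, and the group
#' median appended as a final comment line.  [read_pairwise_matrix()] inverts
#' the format.
#'
#' @param m A `pairwise_matrix`.
#' @param path Output path.
#' @export
write_pairwise_matrix <- function(m, path) {
  stopifnot(inherits(m, "pairwise_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#metric\t", m$metric),
               paste0("#mode\t", m$mode),
               paste0("#group_a\t", m$group_a),
               paste0("#group_b\t", m$group_b)), con)
  writeLines(paste(c("", colnames(m$values)), collapse = "\t"), con)
  for (i in seq_len(nrow(m$values)))
    writeLines(paste(c(rownames(m$values)[i],
                       sprintf("%.6g", m$values[i, ])), collapse = "\t"), con)
  writeLines(paste0("#median\t", sprintf("%.6g", matrix_median(m))), con)
  invisible(path)
}

#' Read a pairwise matrix written by [write_pairwise_matrix()]
#'
#' @param path File path.
#' @return A `pairwise_matrix`.
#' @export
read_pairwise_matrix <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (!length(hit)) return(NA_character_)
    sub(paste0("^#", key, "\t"), "", hit[1])
  }
  header <- strsplit(body[1], "\t")[[1]][-1]
  rows <- strsplit(body[-1], "\t")
  values <- t(vapply(rows, function(r) as.numeric(r[-1]),
                     numeric(length(header))))
  dimnames(values) <- list(vapply(rows, `[`, character(1), 1), header)
  as_pairwise_matrix(values, mode = get("mode"), metric = get("metric"),
                     group_a = get("group_a"), group_b = get("group_b"))
}
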