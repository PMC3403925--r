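test_that("amplicon lengths use the 1-based inclusive convention", {
  expect_equal(amplicon_length(5, 5), 1)
  expect_equal(amplicon_length(1, 10), 10)
  expect_error(amplicon_length(100, 50), "inverted")
})

test_that("primer tables pair forward/reverse rows into amplicons", {
  tab <- read_primer_table(extdata("cftr_sequencing_primers.tsv"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$amplicon, c("Seq1", "Seq2", "Seq3"))
  # reverse primers listed with descending coordinates still parse
  expect_true(all(tab$rev_end > tab$rev_start))
  expect_equal(tab$length,
               amplicon_length(tab$fwd_start, tab$rev_end))
})

test_that("per-position classification is exhaustive and exclusive", {
  ref <- "ACGTACGTAC"
  same <- compare_bidirectional(ref, ref, ref)
  expect_equal(same$excluded_nocall, 0)
  expect_equal(same$excluded_discordant, 0)
  expect_equal(nrow(same$mutations), 0)
  expect_equal(same$examined, 10)

  # one no-call on the forward strand
  nc <- compare_bidirectional("ACGTNCGTAC", ref, ref)
  expect_equal(nc$excluded_nocall, 1)
  expect_equal(nc$examined, 9)

  # no-call takes precedence over discordance
  prec <- compare_bidirectional("ACGTNCGTAC", "ACGTTCGTAC", ref)
  expect_equal(prec$excluded_nocall, 1)
  expect_equal(prec$excluded_discordant, 0)

  # concordant non-reference call is a mutation
  mut <- compare_bidirectional("ATGTACGTAC", "ATGTACGTAC", ref)
  expect_equal(nrow(mut$mutations), 1)
  expect_equal(mut$mutations$position, 2)
  expect_equal(mut$mutations$reference, "C")
  expect_equal(mut$mutations$call, "T")

  # discordant positions are excluded, not mutations
  dis <- compare_bidirectional("ATGTACGTAC", ref, ref)
  expect_equal(dis$excluded_discordant, 1)
  expect_equal(nrow(dis$mutations), 0)

  expect_error(compare_bidirectional("ACG", "AC", "ACG"), "equal length")
  expect_error(compare_bidirectional("AXG", "ACG", "ACG"), "alphabet")
})

test_that("injected events are recovered exactly (round trip)", {
  set.seed(61)
  for (case in 1:20) {
    n <- sample(200:2000, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    pos <- sample.int(n, sample(0:12, 1))
    n_mut <- sample(0:min(4, length(pos)), 1)
    n_nc <- sample(0:(length(pos) - n_mut), 1)
    muts <- pos[seq_len(n_mut)]
    ncs <- pos[n_mut + seq_len(n_nc)]
    dis <- setdiff(pos, c(muts, ncs))
    reads <- simulate_bidirectional_reads(ref, muts, ncs, dis,
                                          seed = 600 + case)
    cmp <- compare_bidirectional(reads$forward, reads$reverse, ref)
    expect_equal(cmp$excluded_nocall, length(ncs))
    expect_equal(cmp$excluded_discordant, length(dis))
    expect_equal(sort(cmp$mutations$position), sort(muts))
    expect_equal(cmp$examined + cmp$excluded_nocall +
                   cmp$excluded_discordant, n)
  }
})

test_that("the documented exclusion example yields 5 excluded bases", {
  set.seed(62)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  reads <- simulate_bidirectional_reads(
    ref, nocall_positions = c(15, 700, 1999),
    discordant_positions = c(100, 1500), seed = 63)
  cmp <- compare_bidirectional(reads$forward, reads$reverse, ref)
  expect_equal(cmp$excluded_nocall + cmp$excluded_discordant, 5)
  expect_equal(cmp$examined, 1995)
})

test_that("exclusion rates and mutation bounds report as documented", {
  expect_equal(exclusion_rate(0, 1000), 0)
  expect_equal(exclusion_rate(5, 200), 2.5)
  expect_error(exclusion_rate(1, 0), "> 0")

  b0 <- mutation_rate_bound(0, 23744)
  expect_equal(b0$point, 0)
  expect_equal(b0$bound, 1 / 23744)
  expect_equal(mutation_rate_bound(0, 1000)$rule_of_three, 0.003)
  b1 <- mutation_rate_bound(1, 100)
  expect_equal(b1$point, 0.01)
  expect_true(is.na(b1$bound))
  expect_error(mutation_rate_bound(0, 0), "> 0")
})

test_that("fidelity reports aggregate by sample and kit", {
  ref <- strrep("ACGT", 500)
  mk <- function(s, k, muts = integer()) {
    reads <- simulate_bidirectional_reads(ref, mutation_positions = muts,
                                          seed = 64)
    compare_bidirectional(reads$forward, reads$reverse, ref,
                          sample = s, kit = k)
  }
  reps <- list(mk("N", "kitA"), mk("N", "kitA"), mk("N", "kitB", muts = 7))
  rep_tab <- fidelity_report(reps)
  expect_equal(nrow(rep_tab), 2)
  a <- rep_tab[rep_tab$kit == "kitA", ]
  expect_equal(a$examined, 4000)
  expect_equal(a$mutations, 0)
  expect_equal(a$percentage, 100 / 4000)
  expect_match(a$percentage_label, "^<")
  b <- rep_tab[rep_tab$kit == "kitB", ]
  expect_equal(b$mutations, 1)
  expect_false(startsWith(b$percentage_label, "<"))
})

test_that("offset reads co-register by global alignment", {
  ref <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  read <- substr(ref, 21, 280)                     # read missing both ends
  al <- align_to_reference(read, ref)
  expect_equal(nchar(al$read), nchar(al$reference))
  expect_identical(al$read, al$reference)

  # a substitution survives alignment; indel columns are dropped
  sub <- read
  substr(sub, 50, 50) <- if (substr(sub, 50, 50) == "A") "C" else "A"
  al2 <- align_to_reference(sub, ref)
  cmp <- compare_bidirectional(al2$read, al2$read, al2$reference)
  expect_equal(nrow(cmp$mutations), 1)
})
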