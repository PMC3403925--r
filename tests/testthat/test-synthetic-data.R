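test_that("simulate_genome is seed-deterministic and validates input", {
  g1 <- simulate_genome(c(chr1 = 5e4, chr2 = 5e4), seed = 1)
  g2 <- simulate_genome(c(chr1 = 5e4, chr2 = 5e4), seed = 1)
  # byte-identical sequence and probe layout (XStringSet compared as text:
  # identical() on external-pointer-backed objects is not informative)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_identical(g1$probes, g2$probes)
  expect_identical(g1$chromosomes, g2$chromosomes)
  g3 <- simulate_genome(c(chr1 = 5e4, chr2 = 5e4), seed = 2)
  expect_false(identical(as.character(g1$sequence),
                         as.character(g3$sequence)))

  expect_error(simulate_genome(c(chr1 = -1), seed = 1), "positive")
  expect_error(simulate_genome(c(chr1 = 800), spacing = c(1000, 2000),
                               seed = 1), "spacing")
})

test_that("probe GC is computed from the emitted sequence", {
  g <- simulate_genome(c(chr1 = 5e4), seed = 3)
  # recompute one probe's GC by brute-force string counting
  p <- g$probes[7, ]
  win <- substr(as.character(g$sequence[[p$chrom]]), p$start + 1, p$end)
  counts <- table(strsplit(win, "")[[1]])
  gc_oracle <- sum(counts[c("G", "C")], na.rm = TRUE) / nchar(win)
  expect_equal(p$gc, unname(gc_oracle))

  # an all-strong-base sequence gives GC 1.0 at every probe
  allgc <- Biostrings::DNAStringSet(c(chr1 = strrep("GC", 5000)))
  probes <- data.frame(chrom = "chr1", start = c(0L, 2000L, 7000L),
                       end = c(500L, 2500L, 7500L))
  expect_equal(probe_gc(allgc, probes), c(1, 1, 1))
})

test_that("probe counts follow the spacing arithmetic", {
  g <- simulate_genome(c(chr1 = 1e6), spacing = c(1000, 2000), seed = 4)
  n <- nrow(g$probes)
  expect_gte(n, 500)
  expect_lte(n, 1000)
  expect_true(all(diff(g$probes$start) >= 1000 - 1))
  expect_true(all(g$probes$end <= 1e6))
})

test_that("hybridization bias is the exact closed-form sum at zero noise", {
  g <- simulate_genome(c(chr1 = 1e5, chr2 = 1e5), seed = 5)
  # all-zero bias, zero noise: self-self limit, ratios exactly 0
  arr0 <- simulate_hybridization(g, bias_model(), seed = 6)
  expect_equal(log2(arr0$test / arr0$reference), rep(0, nrow(g$probes)))

  # single CNV segment at shift -1.585 ~ one third of the reference
  seg <- data.frame(chrom = "chr1", start = 20000, end = 50000,
                    shift = -1.585)
  arr1 <- simulate_hybridization(
    g, bias_model(cnv_segments = seg), seed = 6)
  mid <- (g$probes$start + g$probes$end) / 2
  inside <- g$probes$chrom == "chr1" & mid >= 20000 & mid < 50000
  expect_true(any(inside))
  ratio <- arr1$test / arr1$reference
  expect_equal(ratio[inside], rep(2^-1.585, sum(inside)), tolerance = 1e-12)
  expect_equal(ratio[!inside], rep(1, sum(!inside)), tolerance = 1e-12)

  # full bias sum (GC + telomere + CNV) reproduced independently
  bias <- bias_model(gc_coefficient = -2, telomere_depression = 1.2,
                     telomere_decay = 3e4, cnv_segments = seg)
  arr2 <- simulate_hybridization(g, bias, seed = 6)
  d <- pmin(mid, rep(1e5, length(mid)) - mid)
  expected <- -2 * (g$probes$gc - mean(g$probes$gc)) -
    1.2 * exp(-d / 3e4) + ifelse(inside, -1.585, 0)
  expect_equal(log2(arr2$test / arr2$reference), unname(expected),
               tolerance = 1e-12)

  expect_error(simulate_hybridization(
    g, bias_model(cnv_segments = data.frame(chrom = "chr9", start = 0,
                                            end = 10, shift = 1)),
    seed = 1), "chromosome")
})

test_that("ratio noise has the configured spread", {
  g <- simulate_genome(c(chr1 = 7.5e6), spacing = c(500, 1000), seed = 8)
  expect_gte(nrow(g$probes), 10000)
  arr <- simulate_hybridization(g, bias_model(noise_sd = 0.12), seed = 9)
  r <- log2(arr$test / arr$reference)
  expect_equal(sd(r), 0.12, tolerance = 0.005 / 0.12)
})

test_that("GC-dependent bias is monotone in the expected direction", {
  g <- simulate_genome(c(chr1 = 3e5), seed = 10)
  arr <- simulate_hybridization(g, bias_model(gc_coefficient = -3), seed = 11)
  r <- log2(arr$test / arr$reference)
  dec <- cut(g$probes$gc, quantile(g$probes$gc, c(0, 0.1, 0.9, 1)),
             include.lowest = TRUE, labels = c("low", "mid", "high"))
  expect_lt(mean(r[dec == "high"]), mean(r[dec == "low"]))
})

test_that("Ct tables follow the doubling model and recover copy number", {
  ct2 <- simulate_ct_table(c(A = 2), reference_ct = 25)
  expect_equal(ct2$ct_target, 25)           # CN 2 sits at the reference level
  ct4 <- simulate_ct_table(c(A = 4), reference_ct = 25)
  expect_equal(ct2$ct_target - ct4$ct_target, 1)  # one cycle per doubling

  expect_error(simulate_ct_table(c(A = -1)), ">= 0")
  expect_error(simulate_ct_table(c(A = 2), noise_sd = -1), ">= 0")
  expect_identical(simulate_ct_table(c(A = 2, B = 1), noise_sd = 0.1,
                                     replicates = 3, seed = 2),
                   simulate_ct_table(c(A = 2, B = 1), noise_sd = 0.1,
                                     replicates = 3, seed = 2))

  # noisy recovery: CN 2 against a noiseless calibrator
  noisy <- simulate_ct_table(c(A = 2), sample = "amp", noise_sd = 0.05,
                             replicates = 4, seed = 3)
  cal <- simulate_ct_table(c(A = 2), sample = "cal")
  est <- estimate_copy_number(rbind(noisy, cal), calibrator = "cal")
  got <- est$mean_cn[est$sample == "amp"]
  expect_gte(got, 1.9)
  expect_lte(got, 2.1)
})

test_that("bidirectional reads carry the injected events", {
  ref <- strrep("ACGT", 25)
  r0 <- simulate_bidirectional_reads(ref, seed = 1)
  expect_identical(r0$forward, ref)
  expect_identical(r0$reverse, ref)

  r1 <- simulate_bidirectional_reads(ref, mutation_positions = 10, seed = 1)
  f <- substr(r1$forward, 10, 10)
  expect_identical(f, substr(r1$reverse, 10, 10))
  expect_false(f == substr(ref, 10, 10))

  expect_error(simulate_bidirectional_reads(ref, mutation_positions = 5,
                                            nocall_positions = 5),
               "disjoint")
  expect_error(simulate_bidirectional_reads(ref, mutation_positions = 999),
               "within")
})
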