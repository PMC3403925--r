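test_that("aberration reports respect run length and direction", {
  quiet <- make_profile(rep(0.2, 50), smoothed = TRUE)
  expect_equal(nrow(aberration_report(quiet)), 0)

  # run of exactly 2 qualifying probes is below the minimum
  two <- make_profile(c(rep(0, 10), rep(-1.7, 2), rep(0, 10)),
                      smoothed = TRUE)
  expect_equal(nrow(aberration_report(two)), 0)

  # 5-probe loss at shift -1.7 (fold 3.25) is one region
  five <- make_profile(c(rep(0, 10), rep(-1.7, 5), rep(0, 10)),
                       smoothed = TRUE)
  rep5 <- aberration_report(five)
  expect_equal(nrow(rep5), 1)
  expect_equal(rep5$n_probes, 5)
  expect_equal(rep5$direction, "loss")
  expect_equal(rep5$mean_fold, 2^1.7)
  expect_equal(rep5$start, 10000)     # bp span of the run, half-open
  expect_equal(rep5$end, 14060)

  # min_probes boundary: a 3-run qualifies, and gains are reported too
  three <- make_profile(c(rep(1.7, 3), rep(0, 10), rep(-1.7, 4)),
                        smoothed = TRUE)
  rep3 <- aberration_report(three)
  expect_equal(rep3$direction, c("gain", "loss"))
  expect_equal(rep3$n_probes, c(3, 4))
  # regions never overlap
  expect_true(all(rep3$end[-nrow(rep3)] <= rep3$start[-1]))

  expect_error(aberration_report(five, fold_cutoff = 1), "> 1")
  expect_error(aberration_report(make_profile(rep(0, 10))), "smoothed")
})

test_that("common regions are the base-pair intersection across groups", {
  ra <- data.frame(chrom = "chr1", start = 100, end = 200)
  rb <- data.frame(chrom = "chr1", start = 150, end = 300)
  got <- common_regions(list(A = ra, B = rb))
  expect_equal(got$start, 150)
  expect_equal(got$end, 200)
  expect_equal(got$group, "A,B")

  same <- common_regions(list(A = ra, B = ra))
  expect_equal(same$start, 100)
  expect_equal(same$end, 200)

  disjoint <- common_regions(list(A = ra, B = data.frame(
    chrom = "chr1", start = 500, end = 600)))
  expect_equal(nrow(disjoint), 0)

  expect_error(common_regions(list(A = ra)), "2 groups")

  # order-independence / associativity across groups
  set.seed(41)
  mk <- function() {
    s <- sort(sample.int(5000, 6)) * 10
    data.frame(chrom = "chr1", start = s[c(1, 3, 5)], end = s[c(2, 4, 6)])
  }
  gs <- list(A = mk(), B = mk(), C = mk())
  perm <- common_regions(gs[c(3, 1, 2)])
  orig <- common_regions(gs)
  expect_equal(orig[, c("chrom", "start", "end")],
               perm[, c("chrom", "start", "end")])

  # gap tolerance merges nearby fragments
  frag <- list(A = data.frame(chrom = "chr1", start = c(0, 120),
                              end = c(100, 200)),
               B = data.frame(chrom = "chr1", start = 0, end = 200))
  expect_equal(nrow(common_regions(frag, gap_tolerance = 0)), 2)
  merged <- common_regions(frag, gap_tolerance = 20)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end - merged$start, 200)
})

test_that("genome fraction merges overlaps before summing", {
  lens <- c(chr1 = 1e6, chr2 = 9e6)
  expect_equal(genome_fraction(data.frame(chrom = character(),
                                          start = numeric(),
                                          end = numeric()), lens), 0)
  expect_equal(genome_fraction(data.frame(chrom = "chr1", start = 0,
                                          end = 1e6), lens), 10)
  over <- data.frame(chrom = "chr1", start = c(0, 400), end = c(600, 1000))
  expect_equal(genome_fraction(over, c(chr1 = 1e4)), 10.0)
  expect_error(genome_fraction(data.frame(chrom = "chr1", start = 0,
                                          end = 2e6), lens), "beyond")
})

test_that("region GC counts unambiguous bases only", {
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("G", 50), strrep("AT", 50), strrep("ACGT", 25))))
  allgc <- data.frame(chrom = "chr1", start = 0, end = 50)
  expect_equal(region_gc(allgc, seqs)$mean_gc, 1.0)
  atat <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_equal(region_gc(atat, seqs)$mean_gc, 0.0)
  acgt <- data.frame(chrom = "chr1", start = 150, end = 250)
  expect_equal(region_gc(acgt, seqs)$mean_gc, 0.5)

  both <- region_gc(rbind(allgc, atat), seqs)
  expect_equal(both$regions$gc, c(1, 0))
  expect_equal(both$mean_gc, 50 / 150)   # length-weighted mean

  # ambiguity codes drop out of numerator and denominator
  amb <- Biostrings::DNAStringSet(c(chr1 = "GGNNAA"))
  expect_equal(region_gc(data.frame(chrom = "chr1", start = 0, end = 6),
                         amb)$mean_gc, 0.5)

  expect_error(region_gc(data.frame(chrom = "chr1", start = 0, end = 999),
                         amb), "beyond")
})

test_that("regions round-trip through BED and cytoband rollup annotates", {
  r <- data.frame(chrom = c("chr1", "chr2"), start = c(100, 0),
                  end = c(300, 50), group = c("g1", "g2"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(r, path)
  back <- read_regions_bed(path)
  expect_equal(back$chrom, r$chrom)
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)

  bands <- data.frame(chrom = "chr1", start = c(0, 200, 400),
                      end = c(200, 400, 600),
                      name = c("p1.1", "p1.2", "q1.1"))
  rolled <- cytoband_rollup(data.frame(chrom = "chr1", start = 150,
                                       end = 450), bands)
  expect_equal(rolled$cytoband, "p1.1 - q1.1")
  expect_equal(rolled$band_start, 0)
  expect_equal(rolled$band_end, 600)
})

test_that("the full design recovers shared under-amplified loci with high GC", {
  b <- study_bundle_cached()
  loci <- b$loci
  common <- b$regions$common
  expect_gte(nrow(loci), 2)

  hit <- vapply(seq_len(nrow(loci)), function(k) {
    any(common$chrom == loci$chrom[k] &
          common$start < loci$end[k] & loci$start[k] < common$end)
  }, logical(1))
  expect_gte(mean(hit), 0.9)

  # recovered regions are GC-rich relative to the genome
  expect_gt(b$regions$mean_gc, b$regions$genome_mean_gc)
  expect_gt(b$regions$genome_fraction, 0)
})
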