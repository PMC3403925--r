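test_that("Kolmogorov distance matches the ECDF definition", {
  expect_equal(kolmogorov_distance(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(kolmogorov_distance(rep(0, 5), rep(1, 7)), 1)
  expect_equal(kolmogorov_distance(c(0, 1, 2, 3), c(0, 1, 2, 100)), 0.25)
  expect_error(kolmogorov_distance(numeric(), 1), "non-empty")

  # brute-force ECDF sweep and the standard two-sample statistic agree
  for (s in 1:10) {
    set.seed(s)
    a <- rnorm(40 + s)
    b <- rnorm(55, mean = s / 10)
    got <- kolmogorov_distance(a, b)
    pool <- c(a, b)
    sweep <- max(vapply(pool, function(t)
      abs(mean(a <= t) - mean(b <= t)), numeric(1)))
    expect_equal(got, sweep, tolerance = 1e-12)
    ks <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(got, unname(ks$statistic), tolerance = 1e-12)
  }
})

test_that("Kolmogorov distance is a bounded metric, monotone-invariant", {
  set.seed(31)
  for (rep in 1:5) {
    a <- rnorm(30); b <- rnorm(25, 1); c <- rexp(20)
    dab <- kolmogorov_distance(a, b)
    expect_equal(dab, kolmogorov_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_lte(dab,
               kolmogorov_distance(a, c) + kolmogorov_distance(c, b) + 1e-12)
    # identical monotone transform of both samples leaves the distance alone
    expect_equal(dab, kolmogorov_distance(exp(a), exp(b)), tolerance = 1e-12)
  }
})

test_that("Phi correlation equals Pearson on 0/1 vectors", {
  expect_equal(phi_correlation(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1)
  expect_equal(phi_correlation(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_equal(phi_correlation(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(phi_correlation(c(1, 0), c(1, 0, 1)), "length")
  expect_error(phi_correlation(c(1, 2), c(1, 0)), "binary")

  set.seed(32)
  for (rep in 1:10) {
    a <- rbinom(60, 1, 0.3)
    b <- ifelse(runif(60) < 0.7, a, rbinom(60, 1, 0.3))
    if (length(unique(a)) < 2 || length(unique(b)) < 2 || all(a == b)) next
    expect_equal(phi_correlation(a, b), cor(a, b), tolerance = 1e-12)
    expect_equal(phi_correlation(a, b), phi_correlation(b, a))
  }

  # degenerate self-self case: identical all-zero vectors correlate perfectly
  expect_equal(phi_correlation(rep(0, 10), rep(0, 10)), 1)
  expect_warning(v <- phi_correlation(rep(0, 10), c(rep(0, 9), 1)),
                 "degenerate")
  expect_equal(v, 0)
})

test_that("pairwise matrices have the documented shape and medians", {
  prof <- make_profile(c(0.2, -0.1, 0.4, 0))
  m <- pairwise_matrix(list(prof, prof, prof, prof), metric = "kolmogorov")
  expect_equal(dim(m$values), c(4, 4))
  expect_equal(m$values[lower.tri(m$values)], rep(0, 6))
  expect_equal(diag(m$values), rep(0, 4), ignore_attr = TRUE)
  expect_equal(m$values, t(m$values))
  expect_equal(matrix_median(m), 0)

  set.seed(33)
  ga <- lapply(1:4, function(i) make_profile(rnorm(50)))
  gb <- lapply(1:4, function(i) make_profile(rnorm(50, 1)))
  bt <- pairwise_matrix(ga, gb, metric = "kolmogorov")
  expect_equal(bt$mode, "between")
  expect_equal(sum(!is.na(bt$values)), 16)

  calls <- lapply(1:4, function(i) {
    sm <- make_profile(rep(c(0, -1.5), each = 25), smoothed = TRUE)
    call_cnv(sm)
  })
  ph <- pairwise_matrix(calls, metric = "phi")
  expect_equal(unname(ph$values[lower.tri(ph$values)]), rep(1, 6))
  expect_equal(matrix_median(ph), 1)

  expect_error(pairwise_matrix(list(prof), metric = "kolmogorov"),
               "at least 2")
})

test_that("matrix medians match a brute-force sort oracle", {
  m_const <- as_pairwise_matrix(matrix(0.3, 4, 4), mode = "between")
  expect_equal(matrix_median(m_const), 0.3)

  set.seed(34)
  for (n in 2:4) {
    v <- matrix(runif(n * n), n, n)
    v <- (v + t(v)) / 2; diag(v) <- 0
    mw <- as_pairwise_matrix(v, mode = "within")
    cells <- sort(v[lower.tri(v)])
    k <- length(cells)
    oracle <- if (k %% 2) cells[(k + 1) / 2] else
      (cells[k / 2] + cells[k / 2 + 1]) / 2
    expect_equal(matrix_median(mw), oracle)

    vb <- matrix(runif(n * 4), n, 4)
    mb <- as_pairwise_matrix(vb, mode = "between")
    cb <- sort(as.vector(vb))
    kb <- length(cb)
    oracle_b <- if (kb %% 2) cb[(kb + 1) / 2] else
      (cb[kb / 2] + cb[kb / 2 + 1]) / 2
    expect_equal(matrix_median(mb), oracle_b)
  }
})

test_that("pairwise matrices round-trip through the TSV dialect", {
  set.seed(35)
  ga <- lapply(1:3, function(i) make_profile(rnorm(40)))
  m <- pairwise_matrix(ga, metric = "kolmogorov", group_label = "demo group")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_pairwise_matrix(m, p1)
  m2 <- read_pairwise_matrix(p1)
  write_pairwise_matrix(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  expect_equal(matrix_median(m2), matrix_median(m), tolerance = 1e-6)
})

test_that("replicate noise separates from amplification bias", {
  g <- simulate_genome(c(chr1 = 2e5), seed = 36)
  bias <- kit_preset("repli-g")
  none <- bias_model(noise_sd = 0.165)
  amp1 <- compute_log2_ratios(simulate_hybridization(g, bias, seed = 37))
  amp2 <- compute_log2_ratios(simulate_hybridization(g, bias, seed = 38))
  self1 <- compute_log2_ratios(simulate_hybridization(g, none, seed = 39))
  within <- kolmogorov_distance(amp1, amp2)
  between <- kolmogorov_distance(amp1, self1)
  expect_lt(within, between)
})
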