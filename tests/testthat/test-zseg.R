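test_that("Z-curve increments follow the three disparity axes and skip N", {
  z <- compute_zcurve("AAAA")
  expect_equal(z$x, 1:4)
  expect_equal(z$y, 1:4)
  expect_equal(z$z, 1:4)

  z <- compute_zcurve("ACGT")
  expect_equal(z$x, c(1, 0, 1, 0))
  expect_equal(z$y, c(1, 2, 1, 0))
  expect_equal(z$z, c(1, 0, -1, 0))

  z <- compute_zcurve("ANA")
  expect_equal(z$x, c(1, 1, 2))
  expect_error(compute_zcurve(""), "empty")
})

test_that("quadratic divergence is zero iff compositions match, and symmetric", {
  u <- rep(0.25, 4)
  expect_equal(quadratic_divergence(u, u, 1000, 3000), 0)
  expect_equal(quadratic_divergence(c(1, 0, 0, 0), c(0, 1, 0, 0), 2000, 2000),
               2000)
  p <- c(0.4, 0.2, 0.1, 0.3); q <- c(0.1, 0.3, 0.35, 0.25)
  expect_equal(quadratic_divergence(p, q, 120, 480),
               quadratic_divergence(q, p, 480, 120))
  expect_gt(quadratic_divergence(p, q, 120, 480), 0)
  expect_error(quadratic_divergence(p, q, 0, 10), "zero-length")
})

test_that("homogeneous sequences are never split", {
  seg <- segment_sequence(strrep("A", 5000), t0 = 100, min_len = 1000)
  expect_length(seg$breakpoints, 0)
  expect_equal(nrow(seg$segments), 1)
})

test_that("a sharp two-block composition change is found near the junction", {
  g <- sim_genome_with_islands(
    4000, c(0.45, 0.05, 0.05, 0.45),
    list(list(start = 2000, end = 4000, freqs = c(0.05, 0.45, 0.45, 0.05))),
    seed = 11)
  seg <- segment_sequence(g$genome[[1]], t0 = 100, min_len = 1000)
  expect_length(seg$breakpoints, 1)
  expect_lt(abs(seg$breakpoints - 2000), 100)
})

test_that("a three-block sequence yields two breakpoints near the junctions", {
  g <- sim_genome_with_islands(
    9000, c(0.7, 0.1, 0.1, 0.1),
    list(list(start = 3000, end = 6000, freqs = c(0.1, 0.7, 0.1, 0.1))),
    seed = 12)
  seg <- segment_sequence(g$genome[[1]], t0 = 100, min_len = 1000)
  expect_length(seg$breakpoints, 2)
  expect_lt(abs(seg$breakpoints[1] - 3000), 150)
  expect_lt(abs(seg$breakpoints[2] - 6000), 150)
})

test_that("recursive segmentation equals the substring-rescan oracle", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(400:1500, 1)
    # blocky sequence so some replicates really do split
    g <- sim_genome_with_islands(
      n, c(0.4, 0.1, 0.2, 0.3),
      islands = if (rep %% 2 == 0) {
        list(list(start = floor(n / 3), end = floor(2 * n / 3),
                  freqs = c(0.05, 0.45, 0.45, 0.05)))
      } else list(),
      seed = 100 + rep)
    seg <- segment_sequence(g$genome[[1]], t0 = 30, min_len = 100)
    expect_identical(seg$breakpoints,
                     as.integer(sort(oracle_segmentation(g$genome[[1]], 30, 100))))
  }
})

test_that("raising t0 can only remove breakpoints (halting monotonicity)", {
  set.seed(31)
  for (rep in 1:5) {
    g <- sim_genome_with_islands(
      6000, c(0.4, 0.1, 0.2, 0.3),
      list(list(start = 2000, end = 4000, freqs = c(0.1, 0.4, 0.4, 0.1))),
      seed = 200 + rep)
    b_lo <- segment_sequence(g$genome[[1]], t0 = 50, min_len = 500)$breakpoints
    b_hi <- segment_sequence(g$genome[[1]], t0 = 200, min_len = 500)$breakpoints
    expect_true(all(b_hi %in% b_lo))
  }
})

test_that("strong-contrast islands are recovered at both boundaries", {
  # contrast well above the detectability floor of the halting statistic
  hits <- 0
  n_rep <- 20
  for (rep in seq_len(n_rep)) {
    start <- 20000
    g <- sim_genome_with_islands(
      50000, c(0.3, 0.2, 0.2, 0.3),
      list(list(start = start, end = start + 10000,
                freqs = c(0.05, 0.45, 0.45, 0.05))),
      seed = 300 + rep)
    bp <- segment_sequence(g$genome[[1]], t0 = 100, min_len = 1000)$breakpoints
    tol <- 0.05 * 10000
    ok <- any(abs(bp - start) <= tol) && any(abs(bp - (start + 10000)) <= tol)
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("locus scanning reports breakpoint distances and window flags", {
  seg0 <- segment_sequence(strrep("A", 12000), t0 = 100, min_len = 1000)
  sc <- scan_locus(seg0, list(start = 100, end = 400), window_bp = 5000)
  expect_false(sc$within_window)
  expect_identical(sc$distance, Inf)

  seg <- seg0
  seg$breakpoints <- c(5000L)
  sc <- scan_locus(seg, list(start = 4900, end = 5100), window_bp = 100)
  expect_equal(sc$distance, 0)
  expect_true(sc$within_window)

  seg$breakpoints <- c(10000L)
  sc <- scan_locus(seg, list(start = 0, end = 1000), window_bp = 5000)
  expect_equal(sc$distance, 9000)
  expect_false(sc$within_window)

  expect_error(scan_locus(seg, list(start = -5, end = 100)), "bounds")
})

test_that("segmentation results tidy into tiling segments", {
  g <- sim_genome_with_islands(
    4000, c(0.45, 0.05, 0.05, 0.45),
    list(list(start = 2000, end = 4000, freqs = c(0.05, 0.45, 0.45, 0.05))),
    seed = 41)
  seg <- segment_sequence(g$genome[[1]], t0 = 100, min_len = 1000)
  td <- tidy(seg)
  expect_equal(td$start[1], 0)
  expect_equal(td$end[nrow(td)], 4000)
  expect_equal(td$start[-1], td$end[-nrow(td)])
  expect_equal(rowSums(td[, c("freq_A", "freq_C", "freq_G", "freq_T")]),
               rep(1, nrow(td)))
  expect_equal(glance(seg)$n_breakpoints, length(seg$breakpoints))
})
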