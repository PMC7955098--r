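test_that("poisson upper tail matches direct series summation", {
  expect_equal(poisson_upper_tail(0, 1), 1.0)
  # 1 - e^-1 (1 + 1 + 1/2 + 1/6)
  expect_equal(poisson_upper_tail(4, 1), 1 - exp(-1) * (1 + 1 + 1/2 + 1/6),
               tolerance = 1e-12)
  series <- 1 - sum(exp(-5) * 5^(0:4) / factorial(0:4))
  expect_equal(poisson_upper_tail(5, 5), series, tolerance = 1e-12)
  # decreasing in k
  expect_true(all(diff(poisson_upper_tail(0:20, 3)) < 0))
  expect_error(poisson_upper_tail(2, 0), "positive")
})

test_that("window counts tile the genome and conserve reads", {
  g <- c(chr1 = 1000)
  tr <- point_track(c(10, 15, 250))
  wc <- window_counts(tr, 200, g, shift = 0)
  expect_equal(wc$count[wc$window == 0], 2)
  expect_equal(wc$count[wc$window == 1], 1)
  expect_equal(nrow(wc), 5)

  empty <- point_track(numeric())
  expect_true(all(window_counts(empty, 200, g)$count == 0))

  withr::with_seed(1, {
    tr2 <- point_track(floor(runif(1000, 0, 1e5)))
    expect_equal(sum(window_counts(tr2, 100, c(chr1 = 1e5), shift = 0)$count),
                 1000)
  })
})

test_that("window eligibility follows the Poisson tail threshold", {
  wc <- tibble::tibble(chrom = "chr1", window = 0:4, count = c(0, 0, 4, 2, 6))
  el <- eligible_windows(wc, lam_background = 1, eligibility_p = 0.05)
  expect_equal(el$eligible, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  # raising the threshold never removes eligible windows
  el2 <- eligible_windows(wc, 1, 0.2)
  expect_true(all(el2$eligible[el$eligible]))
  expect_error(eligible_windows(wc, 0), "positive")
})

test_that("island stitching allows internal gaps up to g bp", {
  mk <- function(which_eligible, n = 6) {
    tibble::tibble(chrom = "chr1", window = 0:(n - 1),
                   eligible = 0:(n - 1) %in% which_eligible)
  }
  one <- form_islands(mk(c(0, 2)), w = 200, g = 200)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 600))

  two <- form_islands(mk(c(0, 3)), w = 200, g = 200)
  expect_equal(nrow(two), 2)

  none <- form_islands(mk(integer(0)), w = 200, g = 200)
  expect_equal(nrow(none), 0)
  expect_error(form_islands(mk(0), w = 200, g = 150), "multiple")
})

test_that("Benjamini-Hochberg rejects a prefix of sorted p-values", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.5), alpha = 0.05)
  expect_equal(bh$reject, c(TRUE, TRUE, FALSE))
  expect_equal(benjamini_hochberg(rep(1, 5), 0.05)$reject, rep(FALSE, 5))
  expect_equal(benjamini_hochberg(runif(5), 1)$reject, rep(TRUE, 5))
  expect_length(benjamini_hochberg(numeric(0))$reject, 0)
  # prefix property: sorted by p, rejections form a prefix
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(50)^2
      bh <- benjamini_hochberg(p, 0.1)
      rej_sorted <- bh$reject[order(p)]
      if (any(rej_sorted)) {
        expect_true(all(rej_sorted[seq_len(max(which(rej_sorted)))]))
      }
      expect_true(all(diff(bh$q_values[order(p)]) >= -1e-12))
    }
  })
})

test_that("island scoring is invariant to library-size ratio and read order", {
  g <- c(chr1 = 10000)
  params <- island_params("histone")
  isl <- rg("chr1", 1000, 2000)
  chip <- point_track(c(seq(1100, 1900, by = 20), seq(0, 9999, by = 250)))
  ctrl <- point_track(seq(0, 9999, by = 100))
  s1 <- score_islands(isl, chip, ctrl, params, g, shift = 0)
  # doubling both libraries leaves lambda and p unchanged
  chip2 <- point_track(rep(chip$pos5, 2))
  ctrl2 <- point_track(rep(ctrl$pos5, 2))
  s2 <- score_islands(isl, chip2, ctrl2, params, g, shift = 0)
  expect_equal(s2$control_lambda, 2 * s1$control_lambda) # reads doubled,
  expect_equal(s2$p_value < s1$p_value, TRUE)            # ratio unchanged
  ratio1 <- s1$control_lambda / s1$chip_reads
  ratio2 <- s2$control_lambda / s2$chip_reads
  expect_equal(ratio1, ratio2)
  # read order within the track does not matter
  perm <- withr::with_seed(1, sample.int(length(chip$pos5)))
  chip_perm <- point_track(chip$pos5[perm])
  expect_equal(score_islands(isl, chip_perm, ctrl, params, g, shift = 0)$p_value,
               s1$p_value)
})

test_that("a strong island passes the factor-regime FDR", {
  g <- c(chr1 = 100000)
  isl <- rg("chr1", 1000, 2000)
  chip <- point_track(c(round(seq(1000, 1999, length.out = 50)),
                        round(seq(0, 99999, length.out = 450))))
  ctrl <- point_track(round(seq(0, 99999, length.out = 500)))
  s <- score_islands(isl, chip, ctrl, island_params("factor"), g, shift = 0)
  expect_equal(nrow(s), 1)
  expect_lt(s$p_value, 1e-10)
})

test_that("chip equal in law to control yields no islands at FDR 1e-3", {
  g <- c(chr1 = 2e6)
  n_called <- withr::with_seed(99, {
    vapply(1:3, function(i) {
      chip <- point_track(floor(runif(4e4, 0, g)))
      ctrl <- point_track(floor(runif(4e4, 0, g)))
      nrow(call_islands(chip, ctrl, genome = g, mode = "histone"))
    }, numeric(1))
  })
  expect_lte(mean(n_called), 0.5)
})

test_that("zero-read chip warns and returns nothing", {
  expect_warning(
    out <- call_islands(point_track(numeric()), genome = c(chr1 = 1e4)),
    "zero-read"
  )
  expect_equal(nrow(out), 0)
})

test_that("top_n_by_significance ranks by q, then score, then coordinate", {
  calls <- tibble::tibble(
    chrom = c("chr2", "chr1", "chr1", "chr1"),
    start = c(10, 500, 20, 40), end = c(60, 560, 80, 90),
    score = c(5, 9, 5, 2), q_value = c(0.01, 0.01, 0.01, 0.2)
  )
  top <- top_n_by_significance(calls, n = 3)
  expect_equal(top$start, c(500, 20, 10))
  expect_equal(nrow(top_n_by_significance(calls, n = 10)), 4)
})
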