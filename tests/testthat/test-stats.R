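test_that("Yates-corrected chi-square matches known values and properties", {
  expect_equal(chi2_yates(328, 705, 927, 2855)$statistic, 21.7,
               tolerance = 0.005)
  expect_equal(chi2_yates(303, 936, 34, 453)$statistic, 66.8,
               tolerance = 0.005)
  # balanced table: correction clamps the statistic at zero
  expect_equal(chi2_yates(10, 10, 10, 10)$statistic, 0)
  # symmetry under row and column swaps
  s <- chi2_yates(12, 30, 7, 55)$statistic
  expect_equal(chi2_yates(7, 55, 12, 30)$statistic, s)
  expect_equal(chi2_yates(30, 12, 55, 7)$statistic, s)
  # degree-1 homogeneity in the total count (asymptotic: the n/2
  # correction term is lower order, so check on a large table)
  expect_equal(chi2_yates(2400, 6000, 1400, 11000)$statistic,
               2 * chi2_yates(1200, 3000, 700, 5500)$statistic,
               tolerance = 0.01)
  # fractional (1/k-weighted) counts are legal input
  expect_silent(chi2_yates(3168.2, 17189.1, 180.5, 1702.4))
  expect_error(chi2_yates(5, 0, 7, 0), "margin")
  expect_error(chi2_yates(-1, 2, 3, 4), "non-negative")
  # matrix input equivalent to cellwise input
  expect_equal(chi2_yates(matrix(c(12, 7, 30, 55), 2))$statistic, s)
})

test_that("Mann-Whitney p-values: exact small-sample, approximate large", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  # most extreme of choose(6,3) = 20 layouts, doubled: 2/20
  expect_equal(r$p_value, 0.1)
  # identical samples are fully tied: approximation path, p = 1
  same <- mann_whitney_u(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(same$method, "normal_approx")
  expect_equal(same$p_value, 1)
  set.seed(83)
  big <- mann_whitney_u(rnorm(100), rnorm(100) + 10)
  expect_equal(big$method, "normal_approx")
  expect_lt(big$p_value, 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni correction multiplies and caps", {
  p <- stats::pchisq(10.7, 1, lower.tail = FALSE)
  expect_equal(bonferroni(p, 3), 3.3e-3, tolerance = 0.05)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
})

test_that("resampling test is seeded, calibrated at the null, and bounds extremes", {
  cfg <- resample_config(n_iter = 4000L, seed = 17L)
  x <- rep(c(1, 2, 3, 4, 5), 8)
  r1 <- resample_mean_diff(x, x, cfg)
  r2 <- resample_mean_diff(x, x, cfg)
  expect_identical(r1, r2)           # bit-for-bit under a fixed seed
  expect_gt(r1$p_value, 0.8)         # identical multisets: p near 1
  # a huge shift is reported as a bound, not a zero
  set.seed(19)
  y <- rnorm(200); z <- rnorm(200) + 100
  rb <- resample_mean_diff(y, z, resample_config(n_iter = 4000L, seed = 17L))
  expect_true(rb$p_is_bound)
  expect_equal(rb$p_value, 2 / 4000)
  expect_gt(abs(rb$z_score), 10)
  # geometric mean path demands positive values
  expect_error(resample_mean_diff(c(-1, 2), c(3, 4),
                                  resample_config(stat = "geometric",
                                                  n_iter = 1000L)),
               "positive")
  # geometric and arithmetic observed statistics order the same monotone data
  a <- c(1, 2, 4, 8); b <- c(16, 32, 64, 128)
  ra <- resample_mean_diff(a, b, resample_config(n_iter = 1000L, seed = 3L))
  rg <- resample_mean_diff(a, b, resample_config(n_iter = 1000L, seed = 3L,
                                                 stat = "geometric"))
  expect_lt(ra$z_score, 0)
  expect_lt(rg$z_score, 0)
})

test_that("length-matched nulls track the real set's length profile", {
  set.seed(23)
  pool <- data.frame(gene_id = sprintf("v%03d", 1:300),
                     degree = rpois(300, 5),
                     protein_length = round(rlnorm(300, log(400), 0.4)))
  x <- pool[sample(300, 40), ]
  cfg <- resample_config(n_iter = 1000L, seed = 29L)
  # matching-quality: mean length of matched draws stays within 2% of x's
  cand <- lapply(x$protein_length, function(L)
    which(abs(pool$protein_length - L) <= 0.10 * L))
  set.seed(29)
  draw_means <- vapply(1:50, function(d) {
    used <- logical(300); picked <- integer(0)
    for (k in order(lengths(cand))) {
      avail <- setdiff(cand[[k]], which(used))
      pick <- if (length(avail) == 1) avail else sample(avail, 1)
      used[pick] <- TRUE; picked <- c(picked, pick)
    }
    mean(pool$protein_length[picked])
  }, 0)
  # each matched draw stays inside the matching tolerance; the average
  # draw tracks the real set's mean length within 2%
  expect_true(all(abs(draw_means - mean(x$protein_length)) /
                    mean(x$protein_length) < 0.10))
  expect_lt(abs(mean(draw_means) - mean(x$protein_length)) /
              mean(x$protein_length), 0.02)
  r <- length_matched_resample(x, pool, cfg)
  expect_true(is.finite(r$z_score))
  # degenerate matching: pool = x with near-zero tolerance, p must be 1
  xu <- x[!duplicated(x$protein_length), ]
  deg <- length_matched_resample(
    xu, xu, resample_config(n_iter = 1000L, seed = 31L,
                            length_tolerance = 1e-9))
  expect_equal(deg$p_value, 1)
  expect_equal(deg$statistic, mean(xu$degree))
  # a vertex with no compatible candidate is a named error
  lonely <- data.frame(gene_id = "big", degree = 1, protein_length = 1e6)
  expect_error(length_matched_resample(lonely, pool,
                                       resample_config(n_iter = 1000L)),
               "big")
})
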