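test_that("time binning yields the stated bin counts and means", {
  times <- seq(0, 1198, by = 2)
  x <- rep(3.5, length(times))
  b15 <- bin_timecourse(x, times, window = c(100, 400), width = 20)
  expect_length(b15, 15)
  expect_true(all(b15 == 3.5))
  b50 <- bin_timecourse(x, times, window = c(0, 1000), width = 20)
  expect_length(b50, 50)
  expect_error(bin_timecourse(x, times, window = c(0, 130), width = 20),
               "multiple")
  ## half-open bins: the sample at 120 ms belongs to the second bin
  y <- as.numeric(times >= 120)
  b <- bin_timecourse(y, times, window = c(100, 140), width = 20)
  expect_equal(as.vector(b), c(0, 1), ignore_attr = TRUE)
  ## matrix input bins row-wise
  m <- rbind(x, 2 * x)
  bm <- bin_timecourse(m, times, window = c(100, 400), width = 20)
  expect_equal(dim(bm), c(2, 15))
  expect_true(all(bm[2, ] == 7))
})

test_that("signed-rank z and r reproduce the published statistic convention", {
  ## printed (W, n) pairs and their z / p / r values
  w119 <- wsr_from_w(119, 15)
  expect_equal(round(w119$z, 2), 3.35)
  expect_equal(round(w119$r, 2), 0.61)
  expect_equal(round(w119$p, 4), 8e-04)
  w60 <- wsr_from_w(60, 15)
  expect_equal(w60$z, 0)
  expect_equal(w60$p, 1)
  expect_equal(w60$r, 0)
  w102 <- wsr_from_w(102, 15)
  expect_equal(round(w102$z, 1), 2.4)
  expect_equal(round(w102$r, 2), 0.44)
  w11 <- wsr_from_w(11, 15)
  expect_equal(round(w11$z, 1), -2.8)
  expect_equal(round(w11$r, 2), 0.51)
})

test_that("the test statistic matches data-level computation with ties and zeros", {
  ## zero differences are dropped, tied magnitudes get average ranks
  x <- c(5, 3, 3, 2, 8, 4, 4, 4)
  y <- c(4, 3, 1, 4, 2, 1, 1, 7)
  t1 <- wilcoxon_signed_rank(x, y)
  expect_equal(t1$n, 7)                      # one zero difference dropped
  d <- (x - y)[x != y]
  rk <- rank(abs(d))
  expect_equal(t1$W, sum(rk[d > 0]))
  ## degenerate case
  t0 <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(t0$degenerate)
  ## antisymmetry
  t2 <- wilcoxon_signed_rank(y, x)
  expect_equal(t2$z, -t1$z)
})

test_that("W agrees exactly with the reference implementation for n <= 10", {
  ## worst-case gap between the normal approximation and the exact signrank
  ## distribution, enumerated over every attainable W at sample size n
  exact_p <- function(W, n) min(1, 2 * min(psignrank(W, n),
                                           1 - psignrank(W - 1, n)))
  norm_p <- function(W, n) {
    z <- (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
    min(1, 2 * pnorm(-abs(z)))
  }
  max_bias <- vapply(5:10, function(n) {
    max(vapply(0:(n * (n + 1) / 2), function(W) abs(norm_p(W, n) - exact_p(W, n)),
               numeric(1)))
  }, numeric(1))
  names(max_bias) <- 5:10

  set.seed(41)
  for (i in 1:60) {
    n <- sample(5:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    expect_equal(ours$W, unname(ref$statistic))
    ## without ties the approximation must stay inside its enumerated bias
    if (length(unique(rank(abs(x - y)))) == n) {
      expect_lte(abs(ours$p - exact_p(ours$W, n)), max_bias[[as.character(n)]])
    }
  }
})

test_that("step-up FDR reproduces the worked threshold example", {
  f <- fdr_correct(c(0.001, 0.02, 0.03, 0.04, 0.2), alpha = 0.05)
  expect_equal(f$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sort(f$fdr_alpha), c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_true(all(fdr_correct(rep(0.001, 15))$significant))
  expect_false(any(fdr_correct(rep(0.9, 15))$significant))
  expect_length(fdr_correct(numeric(0))$significant, 0)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR acceptance sets match the textbook BH procedure", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(3:60, 1)
    p <- switch(sample(3, 1), runif(k), rbeta(k, 0.3, 4), rep(runif(1), k))
    ours <- fdr_correct(p, alpha = 0.05)$significant
    bh <- p.adjust(p, method = "BH") <= 0.05
    expect_identical(ours, unname(bh))
  }
})

test_that("binned contrasts localize an injected offset and count bins", {
  set.seed(43)
  n_sub <- 15; k <- 15
  b <- matrix(rnorm(n_sub * k), n_sub)
  a <- b
  a[, 1:5] <- a[, 1:5] + 50                  # offset >> noise in bins 1-5
  res <- binned_contrast(a, b, bin_start = seq(100, 380, 20),
                         bin_end = seq(120, 400, 20))
  expect_s3_class(res, "binned_stat")
  expect_equal(attr(res, "k"), 15)
  expect_equal(which(res$significant), 1:5)
  w <- attr(res, "windows")
  expect_equal(c(w$start, w$end), c(100, 200))
  ## identical conditions: nothing significant
  res0 <- binned_contrast(b, b + 0 * b, bin_start = seq(100, 380, 20),
                          bin_end = seq(120, 400, 20))
  expect_false(any(res0$significant))
  expect_error(binned_contrast(a[1:4, ], b[1:4, ]), "fewer than 5")
})

test_that("scalp z-maps are zero under equality, antisymmetric, and localized", {
  set.seed(44)
  labels <- acticap_montage(32)$label
  b <- matrix(rnorm(15 * 32), 15, dimnames = list(NULL, labels))
  z0 <- scalp_zmap(b, b)
  expect_true(all(z0 == 0))
  a <- b
  roi <- c("P2", "P4", "PO4")
  a[, roi] <- a[, roi] + 5
  z <- scalp_zmap(a, b)
  expect_true(all(abs(z[roi]) >= max(abs(z[setdiff(labels, roi)]))))
  expect_equal(scalp_zmap(b, a), -z)
})
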