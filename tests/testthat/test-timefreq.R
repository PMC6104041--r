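test_that("the wavelet family follows the linear cycle schedule", {
  fam <- wavelet_family()
  expect_equal(length(fam$freqs), 100)
  expect_equal(fam$cycles[fam$freqs == 1], 3)
  expect_equal(fam$cycles[fam$freqs == 50], 7.9)
  expect_equal(fam$cycles[fam$freqs == 100], 12.9)
  ## unit energy
  for (k in c(1, 40, 100)) {
    expect_equal(sum(Mod(fam$kernels[[k]])^2), 1, tolerance = 1e-12)
  }
})

test_that("kernel spectral peaks sit within 0.5 Hz of the nominal frequency", {
  fam <- wavelet_family()
  for (k in c(2, 10, 40, 80)) {
    w <- fam$kernels[[k]]
    nfft <- 2^15
    spec <- Mod(fft(c(w, rep(0, nfft - length(w)))))^2
    fgrid <- (seq_len(nfft) - 1) * fam$rate / nfft
    half <- fgrid <= fam$rate / 2
    expect_lt(abs(fgrid[half][which.max(spec[half])] - fam$freqs[k]), 0.5)
  }
})

test_that("power of a pure tone is stationary, zero for silence, quadratic in amplitude", {
  fam <- wavelet_family()
  times <- seq(-2500, 2498, by = 2)
  tone <- sin(2 * pi * 10 * times / 1000)
  d <- array(0, c(3, 1, length(times)))
  d[1, 1, ] <- tone
  d[3, 1, ] <- 2 * tone
  ep <- make_epochs(d, times, labels = "P2")
  pw <- wavelet_power(ep, fam, freqs = 10, channels = "P2", times = c(-1000, 1000))
  p1 <- pw$power[1, 1, 1, ]
  expect_lt(sd(p1) / mean(p1), 0.05)         # stationary mid-epoch
  expect_equal(max(pw$power[2, 1, 1, ]), 0)  # silence
  expect_equal(pw$power[3, 1, 1, ], 4 * p1, tolerance = 1e-8)
})

test_that("spectral convolution matches direct convolution", {
  fam <- wavelet_family()
  set.seed(31)
  times <- seq(-2500, 2498, by = 2)
  x <- rnorm(length(times))
  ep <- make_epochs(array(x, c(1, 1, length(times))), times, labels = "Cz")
  pw <- wavelet_power(ep, fam, freqs = 6, channels = "Cz", times = c(-200, 200))
  k <- fam$kernels[[6]]
  h <- fam$half_support[6]
  direct <- vapply(which(times >= -200 & times <= 200), function(i) {
    Mod(sum(x[(i - h):(i + h)] * rev(k)))^2
  }, numeric(1))
  ## wavelet kernels are conjugate-symmetric in magnitude; compare power
  expect_equal(pw$power[1, 1, 1, ], direct, tolerance = 1e-8)
})

test_that("samples nearer the epoch edge than the wavelet support are invalid", {
  fam <- wavelet_family()
  times <- seq(-2500, 2498, by = 2)
  ep <- make_epochs(array(1, c(1, 1, length(times))), times, labels = "Cz")
  pw <- wavelet_power(ep, fam, freqs = 1, channels = "Cz")
  h <- fam$half_support[1]
  expect_true(all(is.na(pw$power[1, 1, 1, seq_len(h)])))
  expect_false(anyNA(pw$power[1, 1, 1, (h + 1):(length(times) - h)]))
  expect_error(wavelet_power(make_epochs(array(1, c(1, 1, 100)),
                                         seq(0, 198, 2), labels = "Cz"),
                             fam, freqs = 1, channels = "Cz"),
               "too short")
})

test_that("median aggregation resists outlier trials", {
  fam <- wavelet_family()
  times <- seq(-2500, 2498, by = 2)
  set.seed(32)
  n_tr <- 11
  d <- array(rnorm(n_tr * length(times)), c(n_tr, 1, length(times)))
  d[1:5, 1, ] <- d[1:5, 1, ] * 100          # < 50% huge-power outliers
  ep <- make_epochs(d, times, labels = "Cz")
  pw <- wavelet_power(ep, fam, freqs = 10, channels = "Cz", times = c(-500, 500))
  med_all <- median_ersp(pw)
  clean <- median_ersp(pw, trials = 6:11)
  rng <- range(apply(pw$power[6:11, 1, 1, , drop = FALSE], 4, range))
  expect_true(all(med_all$raw >= rng[1] & med_all$raw <= rng[2]))
  ## and the dB identity holds elementwise
  expect_equal(med_all$db,
               10 * log10(med_all$raw / array(med_all$baseline_mean,
                                              dim(med_all$raw))),
               tolerance = 1e-12)
  expect_equal(dim(clean$raw), dim(med_all$raw))
})

test_that("decibel conversion has its closed-form anchor points", {
  ## RP = BP -> 0 dB; RP = 10 BP -> 10 dB
  times <- seq(-600, 600, by = 2)
  pwr <- array(1, c(4, 1, 1, length(times)))
  pwr[, 1, 1, times > 0] <- 10
  obj <- structure(list(power = pwr, freqs = 5, times = times, channels = "Cz",
                        condition = rep("A", 4), unit = "uV^2"),
                   class = "trial_power")
  er <- median_ersp(obj, baseline = c(-500, 0))
  expect_equal(unname(er$db[1, 1, times == -250]), 0)
  expect_equal(unname(er$db[1, 1, times == 250]), 10)
  ## non-positive baseline power is an explicit failure
  obj$power[] <- 0
  expect_error(median_ersp(obj), "baseline power")
})

test_that("stationary-noise trials give dB fluctuating around zero post-onset", {
  fam <- wavelet_family()
  times <- seq(-2500, 2498, by = 2)
  set.seed(33)
  d <- array(rnorm(30 * length(times)), c(30, 1, length(times)))
  ep <- make_epochs(d, times, labels = "Cz")
  pw <- wavelet_power(ep, fam, freqs = 8, channels = "Cz", times = c(-500, 1000))
  er <- median_ersp(pw)
  post <- er$times > 0
  expect_lt(abs(mean(er$db[1, 1, post])), 1)
})
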