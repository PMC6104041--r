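test_that("band-pass keeps 30 Hz, kills 60 Hz and removes DC", {
  t <- seq(0, 40, by = 1 / 500)
  eeg <- make_eeg(rbind(sin(2 * pi * 30 * t), sin(2 * pi * 60 * t), 1))
  f <- filter_continuous(eeg)
  mid <- 4000:16000
  expect_gt(sd(f$signal[1, mid]) / sd(sin(2 * pi * 30 * t)[mid]), 0.95)
  expect_lt(sd(f$signal[1, mid]) / sd(sin(2 * pi * 30 * t)[mid]), 1.05)
  expect_lt(sd(f$signal[2, mid]) / sd(sin(2 * pi * 60 * t)[mid]), 0.1)
  expect_lt(max(abs(f$signal[3, mid])), 1e-6)
  expect_error(filter_continuous(eeg, band = c(0, 300)), "band edges")
})

test_that("spectral zero-phase filtering matches forward-backward filtfilt", {
  set.seed(11)
  x <- rnorm(6000)
  eeg <- make_eeg(rbind(x))
  f <- filter_continuous(eeg, notch = NULL)
  bp <- signal::butter(4, c(1, 100) / 250, type = "pass")
  ref <- signal::filtfilt(bp, x)
  mid <- 1500:4500
  expect_equal(f$signal[1, mid], ref[mid], tolerance = 1e-4)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(12)
  eeg <- make_eeg(matrix(rnorm(5 * 400), 5))
  r1 <- rereference_average(eeg)
  expect_lt(max(abs(colMeans(r1$signal))), 1e-12)
  r2 <- rereference_average(r1)
  expect_equal(r1$signal, r2$signal)
  ## identical signal on all channels vanishes
  same <- make_eeg(matrix(rep(sin(1:300 / 10), each = 4), 4, byrow = FALSE))
  expect_lt(max(abs(rereference_average(same)$signal)), 1e-12)
  expect_error(rereference_average(make_eeg(matrix(1, 1, 10))), "2 channels")
})

test_that("epoching aligns onsets, baselines exactly, and drops edge events", {
  n <- 6000
  ramp <- seq_len(n)                      # linear ramp channel
  const <- rep(7, n)
  eeg <- make_eeg(rbind(const, ramp),
                  events = data.frame(sample = c(3000, 100), trial = 1:2,
                                      code = c("STR", "STR")))
  ep <- epoch_and_baseline(eeg, window = c(-2500, 2500), baseline = c(-500, 0))
  ## the event at sample 100 lacks pre-onset context
  expect_equal(nrow(ep$dropped), 1)
  expect_equal(ep$dropped$reason, "NO_CONTEXT")
  expect_equal(dim(ep$data), c(1, 2, 2500))
  ## constant channel becomes all zeros
  expect_lt(max(abs(ep$data[1, 1, ])), 1e-12)
  ## ramp: baseline-window mean is exactly zero; slope is preserved
  bl <- ep$times >= -500 & ep$times < 0
  expect_equal(mean(ep$data[1, 2, bl]), 0, tolerance = 1e-10)
  expect_equal(diff(ep$data[1, 2, c(1, 2500)]), 2499, tolerance = 1e-9)
  ## ramp value at onset equals onset sample minus baseline mean (closed form)
  expect_equal(ep$data[1, 2, ep$times == 0], 3000 - mean(ramp[2750:2999]))
})

test_that("epoching commutes with channel permutation", {
  set.seed(13)
  sig <- matrix(rnorm(4 * 4000), 4)
  ev <- data.frame(sample = 2000, trial = 1, code = "X")
  ep1 <- epoch_and_baseline(make_eeg(sig, events = ev),
                            window = c(-1000, 1000), baseline = c(-500, 0))
  perm <- c(3, 1, 4, 2)
  ep2 <- epoch_and_baseline(make_eeg(sig[perm, ], events = ev),
                            window = c(-1000, 1000), baseline = c(-500, 0))
  expect_equal(ep1$data[, perm, ], ep2$data[, , ])
})

test_that("amplitude screening uses a strict 150 uV boundary", {
  d <- array(0, c(3, 2, 100))
  d[2, 1, 50] <- 151
  d[3, 2, 10] <- 150
  ep <- make_epochs(d, times = seq(-100, 98, by = 2))
  keep <- reject_amplitude(ep, 150)
  expect_equal(as.vector(keep), c(TRUE, FALSE, TRUE))
  ep$unit <- "csd"
  expect_error(reject_amplitude(ep), "potential")
})

test_that("component scoring flags artifacts on two of three criteria", {
  mon <- acticap_montage(64)
  set.seed(14)
  n <- 4000
  pink <- as.numeric(reachpe:::pink_noise(n))
  ## EMG-like component: spectral power rising with frequency
  white <- diff(rnorm(n + 1))
  bursty <- rnorm(n) * rbinom(n, 1, 0.01) * 20 + rnorm(n, 0, 0.1)
  central <- gaussian_topo <- exp(-0.5 * (mon$theta / 30)^2)      # vertex-peaked
  rim <- as.numeric(mon$theta > 65)
  sc <- score_components(rbind(pink, white, bursty),
                         rbind(central, rim, central), mon)
  ## pink-noise, centro-parietal component: a prototypical brain source
  expect_false(sc$artifact[1])
  expect_false(sc$spectral_slope_flag[1])
  ## flat-spectrum, rim-concentrated component: two flags -> artifact
  expect_true(sc$spectral_slope_flag[2])
  expect_true(sc$edge_topography_flag[2])
  expect_true(sc$artifact[2])
  ## bursty but central and 1/f-free: kurtosis + slope depends; one flag alone
  ## must not condemn a component
  one_flag <- sc$spectral_slope_flag[3] + sc$edge_topography_flag[3] +
    sc$burst_flag[3]
  expect_equal(sc$artifact[3], one_flag >= 2)
  expect_true(sc$burst_flag[3])
  expect_error(score_components(rbind(rep(1, 100)), rbind(central), mon),
               "zero variance")
})
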