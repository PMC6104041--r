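test_that("spline matrices are symmetric with positive diagonals", {
  mon <- acticap_montage(64)
  gm <- build_spline_matrices(mon)
  expect_equal(gm$G, t(gm$G))
  expect_equal(gm$H, t(gm$H))
  expect_true(all(diag(gm$G) > 0))
  expect_true(all(diag(gm$H) > 0))
})

test_that("G and H entries match a direct Legendre partial-sum oracle", {
  mon <- acticap_montage(32)
  cfg <- csd_config(legendre_terms = 100, smoothing_lambda = 0)
  gm <- build_spline_matrices(mon, cfg)
  xyz <- as.matrix(mon[, c("x", "y", "z")])
  pairs <- rbind(c(1, 2), c(5, 20), c(3, 30), c(10, 10))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    x <- max(-1, min(1, sum(xyz[i, ] * xyz[j, ])))
    g <- h <- 0
    for (n in 1:100) {
      Pn <- laplace_pn(n, x)
      g <- g + (2 * n + 1) / (n * (n + 1))^4 * Pn
      h <- h + (2 * n + 1) / (n * (n + 1))^3 * Pn
    }
    expect_equal(gm$G[i, j], g / (4 * pi), tolerance = 1e-9)
    expect_equal(gm$H[i, j], h / (4 * pi * 100), tolerance = 1e-9)
  }
})

test_that("H scales with the inverse square of the head radius", {
  mon <- acticap_montage(32)
  h1 <- build_spline_matrices(mon, csd_config(head_radius = 10))$H
  h2 <- build_spline_matrices(mon, csd_config(head_radius = 20))$H
  expect_equal(h1 / 4, h2)
})

test_that("coincident electrodes are rejected", {
  mon <- make_montage(c("a", "b", "c", "d", "e", "f", "g", "h", "i"),
                      theta = c(10, 10, 30, 40, 50, 60, 70, 80, 90),
                      phi = c(0, 0, 40, 60, 80, 100, 120, 140, 160))
  expect_error(build_spline_matrices(mon), "coincident")
})

test_that("a spatially uniform potential has zero CSD at every channel", {
  mon <- acticap_montage(64)
  d <- array(rep(3.7, 2 * 64 * 50), c(2, 64, 50))
  ep <- make_epochs(d, times = seq(0, 98, 2), labels = mon$label)
  csd <- apply_laplacian(ep, mon)
  expect_lt(max(abs(csd$data)), 1e-10)
  expect_equal(csd$unit, "csd")
})

test_that("the transform is linear and reference-free", {
  mon <- acticap_montage(32)
  Tm <- csd_transform_matrix(mon)
  set.seed(21)
  x <- rnorm(32); y <- rnorm(32)
  expect_equal(Tm %*% (2 * x + 3 * y), 2 * (Tm %*% x) + 3 * (Tm %*% y))
  ## adding a constant across channels changes nothing
  expect_equal(Tm %*% (x + 42), Tm %*% x, tolerance = 1e-9)
})

test_that("permuting channels permutes the CSD identically", {
  mon <- acticap_montage(32)
  set.seed(22)
  d <- array(rnorm(3 * 32 * 20), c(3, 32, 20))
  ep <- make_epochs(d, seq(0, 38, 2), labels = mon$label)
  csd1 <- apply_laplacian(ep, mon)
  perm <- sample(32)
  ep2 <- make_epochs(d[, perm, , drop = FALSE], seq(0, 38, 2),
                     labels = mon$label[perm])
  mon2 <- mon[perm, ]
  csd2 <- apply_laplacian(ep2, mon2)
  expect_equal(csd1$data[, perm, ], csd2$data[, , ], tolerance = 1e-8)
})

test_that("a smooth bump over PO4 yields a center-surround CSD pattern", {
  mon <- acticap_montage(64)
  ctr <- unlist(mon[mon$label == "PO4", c("x", "y", "z")])
  ang <- acos(pmin(1, as.matrix(mon[, c("x", "y", "z")]) %*% ctr)) * 180 / pi
  bump <- 10 * exp(-0.5 * (ang / 25)^2)
  d <- array(rep(bump, each = 1), c(1, 64, 1))
  ep <- make_epochs(d, times = 0, labels = mon$label)
  csd <- apply_laplacian(ep, mon)
  v <- csd$data[1, , 1]
  ## positive source under the bump center
  expect_gt(v[mon$label == "PO4"], 0)
  ## sign inversion in the surround (30-60 deg away)
  ring <- ang > 30 & ang < 60
  expect_lt(mean(v[ring]), 0)
  expect_equal(which.max(v), which(mon$label == "PO4"))
})
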