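# Spherical-spline surface Laplacian (current source density transform).

#' CSD spline configuration
#'
#' Parameters of the spherical-spline surface Laplacian: spline flexibility
#' order (m-constant) 4, smoothing (ridge) constant 1e-5 added to the
#' diagonal of the G matrix, head radius 10 cm, and the truncation order of
#' the Legendre series (50 terms; the series converges to well below 1e-10
#' for m = 4).
#'
#' @param m_constant Spline flexibility order (>= 2).
#' @param smoothing_lambda Ridge constant added to `diag(G)` (>= 0).
#' @param head_radius Scalp sphere radius (cm).
#' @param legendre_terms Series truncation order (>= 20).
#' @return An object of class `csd_config`.
#' @export
csd_config <- function(m_constant = 4, smoothing_lambda = 1e-5,
                       head_radius = 10, legendre_terms = 50) {
  stopifnot_scalar(m_constant, "m_constant", 2)
  stopifnot_scalar(smoothing_lambda, "smoothing_lambda", 0)
  stopifnot_scalar(head_radius, "head_radius", .Machine$double.eps)
  stopifnot_scalar(legendre_terms, "legendre_terms", 20)
  structure(list(m_constant = m_constant, smoothing_lambda = smoothing_lambda,
                 head_radius = head_radius, legendre_terms = legendre_terms),
            class = "csd_config")
}

# Legendre polynomials P_1..P_nmax evaluated at every entry of matrix X,
# accumulated against coefficient vectors. Bonnet recurrence, vectorized over
# the electrode-pair matrix.
legendre_series <- function(X, coef_g, coef_h) {
  nmax <- length(coef_g)
  Pm1 <- matrix(1, nrow(X), ncol(X))   # P_0
  P <- X                               # P_1
  G <- coef_g[1] * P
  H <- coef_h[1] * P
  for (n in 2:nmax) {
    Pn <- ((2 * n - 1) * X * P - (n - 1) * Pm1) / n
    G <- G + coef_g[n] * Pn
    H <- H + coef_h[n] * Pn
    Pm1 <- P
    P <- Pn
  }
  list(G = G, H = H)
}

#' Build the spherical-spline G and H matrices
#'
#' For electrodes i, j with angular separation `theta_ij`,
#' `G(i,j) = sum_n (2n+1) / (n(n+1))^m  P_n(cos theta_ij) / (4 pi)` and
#' `H(i,j) = sum_n (2n+1) / (n(n+1))^(m-1)  P_n(cos theta_ij) / (4 pi r^2)`,
#' truncated at `legendre_terms`, with the smoothing constant added to G's
#' diagonal. G interpolates the potential; H yields the surface Laplacian
#' (CSD) of the interpolant, carrying the `1/r^2` head-radius scaling.
#'
#' @param montage An `eeg_montage` (>= 8 channels, positions distinct).
#' @param config A [csd_config()].
#' @return List with symmetric matrices `G` and `H` (channels x channels).
#' @export
build_spline_matrices <- function(montage, config = csd_config()) {
  xyz <- montage_xyz(montage)
  if (nrow(xyz) < 8) stop("spherical spline needs >= 8 electrodes", call. = FALSE)
  C <- xyz %*% t(xyz)                 # cos(theta_ij)
  C[C > 1] <- 1
  C[C < -1] <- -1
  off <- C[upper.tri(C)]
  if (any(off > 1 - 1e-12)) stop("coincident electrodes in montage", call. = FALSE)
  n <- seq_len(config$legendre_terms)
  coef_g <- (2 * n + 1) / (n * (n + 1))^config$m_constant
  coef_h <- (2 * n + 1) / (n * (n + 1))^(config$m_constant - 1)
  s <- legendre_series(C, coef_g, coef_h)
  G <- s$G / (4 * pi)
  H <- s$H / (4 * pi * config$head_radius^2)
  diag(G) <- diag(G) + config$smoothing_lambda
  list(G = G, H = H)
}

#' Linear operator mapping scalp potentials to CSD
#'
#' Solves the constrained spherical-spline system once and returns the
#' channels x channels matrix `T` such that `CSD = T %*% potentials` for any
#' per-sample potential vector. The constrained formulation (spline weights
#' sum to zero, with a free constant) makes the output independent of the
#' recording reference: adding a constant across channels leaves the CSD
#' unchanged.
#'
#' @param montage An `eeg_montage`.
#' @param config A [csd_config()].
#' @return Matrix (channels x channels) with dimnames set to channel labels.
#' @export
csd_transform_matrix <- function(montage, config = csd_config()) {
  mats <- build_spline_matrices(montage, config)
  Gi <- tryCatch(solve(mats$G), error = function(e) {
    stop("singular spline system (degenerate montage): ", conditionMessage(e),
         call. = FALSE)
  })
  one <- rep(1, nrow(Gi))
  g1 <- Gi %*% one
  ## weights c = Gi (v - c0 * 1), with c0 chosen so that sum(c) = 0
  Tm <- mats$H %*% (Gi - (g1 %*% t(g1)) / sum(g1))
  dimnames(Tm) <- list(montage$label, montage$label)
  Tm
}

#' Transform an epoch set to current source density
#'
#' Applies the spherical-spline surface Laplacian to every trial and sample.
#' The transform is linear and deterministic; output unit is microvolts per
#' square centimeter.
#'
#' @param epochs An `epoch_set` with `unit == "potential"`; channel labels
#'   must match the montage.
#' @param montage An `eeg_montage`.
#' @param config A [csd_config()].
#' @return The `epoch_set` with CSD data and `unit == "csd"`.
#' @export
apply_laplacian <- function(epochs, montage, config = csd_config()) {
  if (!identical(epochs$unit, "potential")) {
    stop("input epochs must be scalp potentials (unit = 'potential')", call. = FALSE)
  }
  if (!identical(as.character(epochs$labels), as.character(montage$label))) {
    stop("epoch channel set/order must match the montage", call. = FALSE)
  }
  Tm <- csd_transform_matrix(montage, config)
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    epochs$data[i, , ] <- Tm %*% epochs$data[i, , ]
  }
  epochs$unit <- "csd"
  epochs
}
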