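# Complex Morlet wavelet decomposition, robust (median) trial aggregation,
# and decibel baseline normalization of event-related spectral perturbations.

# Vectorized per-column medians. Columns containing NA (edge-contaminated
# samples, which are NA for every trial at once) give NA.
col_medians <- function(m) {
  n <- nrow(m)
  na_col <- colSums(is.na(m)) > 0
  m[is.na(m)] <- Inf
  o <- order(col(m), m)
  ms <- matrix(m[o], n)
  out <- if (n %% 2 == 1) ms[(n + 1) / 2, ] else (ms[n / 2, ] + ms[n / 2 + 1, ]) / 2
  out[na_col] <- NA_real_
  out
}

#' Morlet wavelet family
#'
#' Complex Morlet wavelets spanning 1-100 Hz in 1 Hz intervals with a cycle
#' count increasing linearly from 3 at 1 Hz to 12.9 at 100 Hz in 0.1 steps
#' (`cycles(f) = 3 + 0.1 * (grid index of f)`), limiting frequency smoothing
#' at high frequencies. Each kernel is a Gaussian-windowed complex
#' exponential with temporal SD `sigma_t = cycles / (2 pi f)`, truncated at
#' +/- 3 sigma and normalized to unit energy.
#'
#' @param rate Sampling rate (Hz).
#' @param freqs Frequency grid (Hz).
#' @param cycles Per-frequency cycle counts; the default is the linear
#'   3..12.9 schedule over the default grid.
#' @return An object of class `wavelet_family`: list with `freqs`, `cycles`,
#'   `rate`, `sigma_t` (s), `half_support` (samples), and `kernels` (list of
#'   complex vectors of odd length `2 * half_support + 1`).
#' @examples
#' fam <- wavelet_family()
#' fam$cycles[c(1, 50, 100)]  # 3, 7.9, 12.9
#' @export
wavelet_family <- function(rate = 500, freqs = 1:100,
                           cycles = 3 + 0.1 * (seq_along(freqs) - 1)) {
  if (length(cycles) != length(freqs)) {
    stop("`cycles` must match `freqs` in length", call. = FALSE)
  }
  sigma_t <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * sigma_t * rate)
  kernels <- lapply(seq_along(freqs), function(i) {
    t_s <- (-half[i]:half[i]) / rate
    w <- exp(2i * pi * freqs[i] * t_s) * exp(-t_s^2 / (2 * sigma_t[i]^2))
    w / sqrt(sum(Mod(w)^2))            # unit energy
  })
  structure(list(freqs = freqs, cycles = cycles, rate = rate,
                 sigma_t = sigma_t, half_support = half, kernels = kernels),
            class = "wavelet_family")
}

#' @export
print.wavelet_family <- function(x, ...) {
  cat(sprintf("Morlet wavelet family: %d frequencies (%g..%g Hz), cycles %g..%g @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              min(x$cycles), max(x$cycles), x$rate))
  invisible(x)
}

#' Single-trial wavelet power
#'
#' Convolves every requested trial/channel with the requested wavelets
#' (spectral-domain convolution) and squares the magnitude of the complex
#' result. Output samples closer to an epoch edge than a wavelet's half
#' support are edge-contaminated and set to `NA`; the wide epoch
#' (+/- 2500 ms) exists precisely to buffer the analysis window from these
#' edges.
#'
#' @param epochs An `epoch_set` (potential or CSD).
#' @param family A [wavelet_family()] matching the epoch sampling rate.
#' @param freqs Frequencies (Hz) to compute; must be members of the family
#'   grid. Default: the full family.
#' @param channels Channel labels to compute (default all).
#' @param times Optional numeric length-2 window (ms) restricting the output
#'   samples.
#' @return An object of class `trial_power`: list with `power` (array
#'   trials x channels x freqs x times; unit squared input units), `freqs`,
#'   `times` (ms), `channels`, `condition`, `unit`.
#' @export
wavelet_power <- function(epochs, family, freqs = family$freqs,
                          channels = NULL, times = NULL) {
  if (!isTRUE(all.equal(family$rate, epochs$rate))) {
    stop("wavelet family rate must match epoch rate", call. = FALSE)
  }
  fi <- match(freqs, family$freqs)
  if (anyNA(fi)) stop("requested frequencies not in the wavelet family", call. = FALSE)
  if (is.null(channels)) channels <- epochs$labels
  ci <- match(channels, epochs$labels)
  if (anyNA(ci)) stop("requested channels not in the epoch set", call. = FALSE)

  et <- epochs$times
  out_sel <- if (is.null(times)) rep(TRUE, length(et)) else et >= times[1] & et <= times[2]
  if (!any(out_sel)) stop("requested time window contains no samples", call. = FALSE)
  out_idx <- which(out_sel)

  half <- family$half_support[fi]
  hmax <- max(half)
  n_ep <- length(et)
  ## restrict the convolution input to the support of the requested outputs
  seg <- max(1L, min(out_idx) - hmax):min(n_ep, max(out_idx) + hmax)
  nseg <- length(seg)
  Lmax <- 2L * hmax + 1L
  nfft <- stats::nextn(nseg + Lmax - 1L, c(2, 3, 5))
  if (nseg < min(2L * half + 1L)) {
    stop("epoch too short for the lowest requested frequency", call. = FALSE)
  }

  Kf <- lapply(seq_along(fi), function(k) {
    stats::fft(c(family$kernels[[fi[k]]], rep(0, nfft - (2L * half[k] + 1L))))
  })

  nt <- dim(epochs$data)[1]
  pw <- array(NA_real_, c(nt, length(ci), length(fi), length(out_idx)))
  ## validity relative to the true epoch edges
  for (tr in seq_len(nt)) {
    for (c2 in seq_along(ci)) {
      X <- stats::fft(c(epochs$data[tr, ci[c2], seg], rep(0, nfft - nseg)))
      for (k in seq_along(fi)) {
        y <- stats::fft(X * Kf[[k]], inverse = TRUE) / nfft
        ## full convolution index j corresponds to kernel center at
        ## seg[1] + j - 1 - half[k]
        centers <- out_idx - seg[1] + 1L + half[k]
        pw[tr, c2, k, ] <- Mod(y[centers])^2
      }
    }
  }
  for (k in seq_along(fi)) {
    invalid <- out_idx <= half[k] | out_idx > n_ep - half[k]
    if (any(invalid)) pw[, , k, invalid] <- NA_real_
  }
  structure(list(power = pw, freqs = freqs, times = et[out_idx],
                 channels = channels, condition = epochs$condition,
                 unit = if (identical(epochs$unit, "csd")) "(uV/cm^2)^2" else "uV^2"),
            class = "trial_power")
}

#' @export
print.trial_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("Trial power: %d trials x %d channels x %d freqs x %d samples [%s]\n",
              d[1], d[2], d[3], d[4], x$unit))
  invisible(x)
}

#' Median-aggregated, dB-normalized power time-course
#'
#' Aggregates single-trial power with the median across trials (robust to
#' outlier trials), yielding the raw power `RP` per channel, frequency and
#' time. The baseline power `BP` is the time-mean of `RP` over the baseline
#' window, and the normalized time-course is `dB = 10 * log10(RP / BP)`.
#' When trials from several conditions are present, call once per condition
#' (normalization is strictly per condition).
#'
#' @param power A [wavelet_power()] result (optionally trial-subsetted).
#' @param baseline Baseline window (ms), half-open, default `[-500, 0)`.
#' @param trials Optional logical/integer trial subset.
#' @return An object of class `power_timecourse`: list with `raw`
#'   (channels x freqs x times median power), `baseline_mean`
#'   (channels x freqs), `db` (channels x freqs x times), `freqs`, `times`,
#'   `channels`, `n_trials`.
#' @export
median_ersp <- function(power, baseline = c(-500, 0), trials = NULL) {
  pw <- power$power
  if (!is.null(trials)) pw <- pw[trials, , , , drop = FALSE]
  if (dim(pw)[1] < 1) stop("at least one trial required", call. = FALSE)
  d <- dim(pw)
  m <- matrix(pw, nrow = d[1])
  raw <- array(col_medians(m), d[2:4])

  bl <- power$times >= baseline[1] & power$times < baseline[2]
  if (!any(bl)) stop("baseline window contains no samples", call. = FALSE)
  bp <- apply(raw[, , bl, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  if (any(!is.finite(bp)) || any(bp <= 0)) {
    stop("non-positive baseline power; cannot dB-normalize", call. = FALSE)
  }
  db <- 10 * log10(raw / array(bp, d[2:4]))
  structure(list(raw = raw, baseline_mean = bp, db = db,
                 freqs = power$freqs, times = power$times,
                 channels = power$channels, n_trials = d[1]),
            class = "power_timecourse")
}

#' Per-condition median ERSPs
#'
#' Convenience wrapper computing [median_ersp()] independently for each
#' condition present in a [wavelet_power()] result.
#'
#' @param power A `trial_power`.
#' @param baseline Baseline window (ms).
#' @return Named list of `power_timecourse` objects, one per condition.
#' @export
ersp_by_condition <- function(power, baseline = c(-500, 0)) {
  conds <- unique(power$condition)
  out <- lapply(conds, function(cn) {
    median_ersp(power, baseline = baseline, trials = power$condition == cn)
  })
  names(out) <- conds
  out
}

#' Band-averaged dB power time-course
#'
#' Averages the dB time-course over a frequency band (inclusive) and over
#' channels, yielding one value per time sample.
#'
#' @param ersp A [median_ersp()] result.
#' @param band Length-2 frequency band (Hz), inclusive.
#' @param channels Channel labels to pool (default all present).
#' @return Numeric time series (named by time in ms).
#' @export
band_power_timecourse <- function(ersp, band, channels = ersp$channels) {
  ci <- match(channels, ersp$channels)
  if (anyNA(ci)) stop("requested channels not present", call. = FALSE)
  fsel <- ersp$freqs >= band[1] & ersp$freqs <= band[2]
  if (!any(fsel)) stop("band contains no family frequencies", call. = FALSE)
  out <- apply(ersp$db[ci, fsel, , drop = FALSE], 3, mean)
  names(out) <- ersp$times
  out
}
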