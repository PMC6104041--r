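# Continuous-EEG preprocessing: zero-phase filtering, average reference,
# epoching with baseline correction, amplitude screening, and heuristic
# scoring of independent components.

# Squared magnitude response |H|^2 of an IIR filter on the two-sided nfft
# frequency grid (the transfer function of zero-phase forward-backward
# application of the filter).
iir_mag2_response <- function(flt, nfft) {
  ez <- exp(-2i * pi * (seq_len(nfft) - 1) / nfft)
  horner <- function(cf) {
    acc <- rep(cf[length(cf)] + 0i, nfft)
    for (k in rev(seq_len(length(cf) - 1))) acc <- acc * ez + cf[k]
    acc
  }
  Mod(horner(flt$b) / horner(flt$a))^2
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a zero-phase (phase-free) Butterworth band-pass (4th order) plus
#' a Butterworth band-stop notch (2nd order) to every channel: the signal
#' spectrum is multiplied by the squared magnitude response of each filter,
#' which is the transfer function of forward-backward (filtfilt)
#' application, realized in the frequency domain. Zero phase preserves ERP
#' latencies; pass-band gain is near 1 and DC is removed. Boundary effects
#' are confined to the filters' impulse-response length at the recording
#' edges, as with forward-backward filtering.
#'
#' @param eeg A `continuous_eeg`.
#' @param band Pass band edges (Hz), default 1-100.
#' @param notch Stop band edges (Hz), default 59-61; `NULL` disables.
#' @return The filtered `continuous_eeg`.
#' @export
filter_continuous <- function(eeg, band = c(1, 100), notch = c(59, 61)) {
  nyq <- eeg$rate / 2
  if (any(band <= 0) || any(band >= nyq) || band[1] >= band[2]) {
    stop("band edges must lie strictly inside (0, rate/2)", call. = FALSE)
  }
  N <- ncol(eeg$signal)
  nfft <- stats::nextn(N, c(2, 3, 5))
  H2 <- iir_mag2_response(signal::butter(4, band / nyq, type = "pass"), nfft)
  if (!is.null(notch)) {
    if (any(notch <= 0) || any(notch >= nyq)) {
      stop("notch edges must lie strictly inside (0, rate/2)", call. = FALSE)
    }
    H2 <- H2 * iir_mag2_response(signal::butter(2, notch / nyq, type = "stop"), nfft)
  }
  ## H2 is real and (circularly) symmetric, so its impulse response is real:
  ## two real channels can ride one complex FFT (one in Re, one in Im).
  nch <- nrow(eeg$signal)
  pairs <- seq_len(ceiling(nch / 2))
  x <- matrix(0i, nfft, length(pairs))
  for (p in pairs) {
    i1 <- 2 * p - 1
    im <- if (2 * p <= nch) eeg$signal[2 * p, ] else rep(0, N)
    x[seq_len(N), p] <- complex(real = eeg$signal[i1, ], imaginary = im)
  }
  y <- stats::mvfft(stats::mvfft(x) * H2, inverse = TRUE)[seq_len(N), , drop = FALSE] / nfft
  for (p in pairs) {
    eeg$signal[2 * p - 1, ] <- Re(y[, p])
    if (2 * p <= nch) eeg$signal[2 * p, ] <- Im(y[, p])
  }
  eeg
}

#' Re-reference to the average scalp potential
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at every sample. Idempotent.
#'
#' @param eeg A `continuous_eeg`.
#' @return The re-referenced `continuous_eeg`.
#' @export
rereference_average <- function(eeg) {
  if (nrow(eeg$signal) < 2) stop("average reference needs >= 2 channels", call. = FALSE)
  eeg$signal <- sweep(eeg$signal, 2, colMeans(eeg$signal))
  eeg
}

#' Epoch around movement onsets and baseline-correct
#'
#' Cuts fixed-length epochs around each event (default -2500 to +2500 ms,
#' half-open `[t0 + window[1], t0 + window[2])` so a 5 s window holds exactly
#' 2500 samples at 500 Hz, with the onset sample on the post-onset side) and
#' subtracts, per trial and channel, the mean potential over the baseline
#' window (default the 500 ms preceding onset, `[-500, 0)`). Events too close
#' to a recording edge are dropped and logged.
#'
#' @param eeg A `continuous_eeg` (events taken from `eeg$events` unless
#'   `onsets` is given).
#' @param onsets Optional event sample indices overriding `eeg$events$sample`.
#' @param window Epoch window (ms relative to onset), half-open.
#' @param baseline Baseline window (ms), half-open.
#' @return An object of class `epoch_set`: list with `data` (array
#'   trials x channels x samples), `times` (ms), `rate`, `labels`,
#'   `condition` (per retained trial), `trial` (original trial numbers),
#'   `unit`, `baseline`, and `dropped` (`data.frame` log of skipped events,
#'   reason `"NO_CONTEXT"`).
#' @export
epoch_and_baseline <- function(eeg, onsets = NULL, window = c(-2500, 2500),
                               baseline = c(-500, 0)) {
  if (is.null(onsets)) onsets <- eeg$events$sample
  conditions <- if (!is.null(eeg$events) && length(onsets) == nrow(eeg$events)) {
    eeg$events$code
  } else rep(NA_character_, length(onsets))
  trial_ids <- if (!is.null(eeg$events) && length(onsets) == nrow(eeg$events)) {
    eeg$events$trial
  } else seq_along(onsets)

  step <- 1000 / eeg$rate
  rel <- seq(window[1] / step, window[2] / step - 1)   # half-open sample grid
  times <- rel * step
  N <- ncol(eeg$signal)
  ok <- (onsets + min(rel)) >= 1 & (onsets + max(rel)) <= N
  dropped <- data.frame(trial = trial_ids[!ok], sample = onsets[!ok],
                        reason = rep("NO_CONTEXT", sum(!ok)),
                        stringsAsFactors = FALSE)
  onsets <- onsets[ok]
  nt <- length(onsets)
  nch <- nrow(eeg$signal)
  data <- array(NA_real_, c(nt, nch, length(rel)))
  for (i in seq_len(nt)) data[i, , ] <- eeg$signal[, onsets[i] + rel]

  bl <- times >= baseline[1] & times < baseline[2]
  if (!any(bl)) stop("baseline window contains no samples", call. = FALSE)
  bl_mean <- rowMeans(data[, , bl, drop = FALSE], dims = 2)
  data <- data - array(bl_mean, c(nt, nch, length(rel)))

  ep <- list(data = data, times = times, rate = eeg$rate, labels = eeg$labels,
             condition = conditions[ok], trial = trial_ids[ok],
             unit = "potential", baseline = baseline, dropped = dropped)
  class(ep) <- "epoch_set"
  ep
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples (%g..%g ms), unit=%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$unit))
  if (!all(is.na(x$condition))) print(table(condition = x$condition))
  invisible(x)
}

#' Subset an epoch set by trial
#'
#' @param epochs An `epoch_set`.
#' @param keep Logical mask or integer indices over trials.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$condition <- epochs$condition[keep]
  epochs$trial <- epochs$trial[keep]
  epochs
}

#' Amplitude-based artifact screening
#'
#' Rejects trials whose scalp potential exceeds the threshold in magnitude on
#' any channel at any sample (strictly greater than; a deflection of exactly
#' the threshold is retained).
#'
#' @param epochs An `epoch_set` with `unit == "potential"`.
#' @param threshold Rejection threshold (microvolts).
#' @return Logical retention mask over trials with attribute `peak`
#'   (per-trial maximum absolute amplitude).
#' @export
reject_amplitude <- function(epochs, threshold = 150) {
  if (!identical(epochs$unit, "potential")) {
    stop("amplitude screening operates on scalp potentials (unit = 'potential')",
         call. = FALSE)
  }
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold
  attr(keep, "peak") <- peak
  keep
}

#' Score independent components against artifact criteria
#'
#' Quantifies, for each externally supplied component, the three artifact
#' criteria: (1) a power spectrum that does not generally decrease with
#' frequency, flagged when the log-log spectral slope over 2-40 Hz is >= 0;
#' (2) a topography concentrated at the far edges of the scalp, flagged when
#' more than half of the squared-weight energy lies on electrodes beyond the
#' rim polar angle; and (3) spurious bursts in the time course, flagged when
#' the excess kurtosis exceeds the burst threshold. A component is artifactual
#' when at least two flags are raised.
#'
#' @param timecourses Matrix components x samples (component activations).
#' @param topographies Matrix components x channels (mixing weights), columns
#'   ordered as `montage`.
#' @param montage An `eeg_montage` supplying electrode polar angles.
#' @param rate Sampling rate (Hz) of the timecourses.
#' @param rim_angle Polar angle (degrees from vertex) beyond which electrodes
#'   count as scalp rim.
#' @param slope_band Frequency band (Hz) for the spectral-slope fit.
#' @param kurtosis_threshold Excess-kurtosis threshold for the burst flag.
#' @return `data.frame` (class `component_scores`) with logical columns
#'   `spectral_slope_flag`, `edge_topography_flag`, `burst_flag`, `artifact`,
#'   and the underlying numeric scores.
#' @export
score_components <- function(timecourses, topographies, montage, rate = 500,
                             rim_angle = 65, slope_band = c(2, 40),
                             kurtosis_threshold = 5) {
  timecourses <- rbind(timecourses)
  topographies <- rbind(topographies)
  if (any(apply(timecourses, 1, stats::var) == 0)) {
    stop("component with zero variance", call. = FALSE)
  }
  if (ncol(topographies) != nrow(montage)) {
    stop("topography columns must match montage channels", call. = FALSE)
  }
  rim <- montage$theta > rim_angle
  out <- lapply(seq_len(nrow(timecourses)), function(i) {
    x <- timecourses[i, ]
    ## criterion 1: log-log spectral slope
    sp <- stats::spec.pgram(x, spans = c(11, 11), plot = FALSE, detrend = TRUE)
    f <- sp$freq * rate
    sel <- f >= slope_band[1] & f <= slope_band[2]
    slope <- stats::coef(stats::lm(log10(sp$spec[sel]) ~ log10(f[sel])))[2]
    ## criterion 2: rim-concentrated topography energy
    w2 <- topographies[i, ]^2
    rim_energy <- sum(w2[rim]) / sum(w2)
    ## criterion 3: excess kurtosis of the timecourse
    z <- (x - mean(x)) / stats::sd(x)
    kurt <- mean(z^4) - 3
    data.frame(component = i,
               spectral_slope = unname(slope), spectral_slope_flag = slope >= 0,
               rim_energy = rim_energy, edge_topography_flag = rim_energy > 0.5,
               kurtosis = kurt, burst_flag = kurt > kurtosis_threshold)
  })
  out <- do.call(rbind, out)
  out$artifact <- (out$spectral_slope_flag + out$edge_topography_flag +
                     out$burst_flag) >= 2
  class(out) <- c("component_scores", "data.frame")
  out
}
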