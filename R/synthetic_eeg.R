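# Synthetic continuous EEG with known, condition-dependent ground-truth
# effects: spatially correlated 1/f background, line noise, evoked parietal
# and mid-frontal deflections, band-limited oscillatory bursts, and optional
# blink-like artifacts.

#' Ground-truth effect configuration for the EEG generator
#'
#' Defines the injected neural effects per condition. Oscillatory effects are
#' expressed as decibel gains applied to a base burst amplitude
#' (`amp = base * 10^(gain_db / 20)`), evoked deflections as absolute scalp
#' amplitudes in microvolts. The defaults give STR-specific increases in the
#' parietal visual N1, the mid-frontal FRN-like deflection, parietal low-theta
#' (2-4 Hz, 0-500 ms), frontal theta (5-7 Hz, 80-440 ms) and parietal
#' alpha/low-beta (8-18 Hz, 100-1000 ms); they are tuning choices sized so
#' that group effect sizes land in the moderate-to-large range reported for
#' this paradigm (Pearson r around 0.4-0.6 at n = 15), not measured
#' physiological values.
#'
#' @param n1_uv Named per-condition amplitudes (microvolts) of the parietal
#'   negativity at ~170 ms.
#' @param frn_uv Named per-condition amplitudes of the mid-frontal negativity
#'   at ~220 ms.
#' @param theta_parietal_db Named per-condition dB gains of the parietal
#'   2-4 Hz burst (0-500 ms window).
#' @param theta_frontal_db Named per-condition dB gains of the mid-frontal
#'   5-7 Hz burst (80-440 ms window).
#' @param alphabeta_db Named per-condition dB gains of the parietal 8-18 Hz
#'   modulation (100-1000 ms window).
#' @param base_amp Base burst amplitudes (microvolts) for
#'   `theta_parietal`, `theta_frontal`, `alphabeta`.
#' @param subject_gain_sd Between-subject SD (dB) added once per call to each
#'   effect family, emulating inter-individual effect-size variability.
#' @param latency_jitter_sd Trial-to-trial latency jitter SD (ms) of the
#'   evoked deflections.
#' @param artifact_trials Indices of trials receiving a blink-like transient.
#' @param artifact_amp Peak amplitude (microvolts) of the blink transient.
#' @param noise_sd Average channel SD (microvolts) of the 1/f background.
#' @param sensor_noise_sd SD of independent per-channel white noise.
#' @param n_sources Number of spatially mixed pink-noise sources.
#' @param line_amp,line_freq Amplitude (microvolts) and frequency (Hz) of the
#'   power-line component.
#' @return An object of class `eeg_effects`.
#' @export
eeg_effects <- function(n1_uv = c(STR = 6, POST = 4.5, ADAPT = 4.5,
                                  NULL_L = 4.5, NULL_R = 4.5),
                        frn_uv = c(STR = 4, POST = 2.3, ADAPT = 2.3,
                                   NULL_L = 2.3, NULL_R = 2.3),
                        theta_parietal_db = c(STR = 3, POST = 0, ADAPT = 0,
                                              NULL_L = 0, NULL_R = 0),
                        theta_frontal_db = c(STR = 3, POST = 0, ADAPT = 0,
                                             NULL_L = 0, NULL_R = 0),
                        alphabeta_db = c(STR = 2, POST = 0, ADAPT = 0,
                                         NULL_L = 0, NULL_R = 0),
                        base_amp = c(theta_parietal = 4, theta_frontal = 3,
                                     alphabeta = 4),
                        subject_gain_sd = 0.75,
                        latency_jitter_sd = 10,
                        artifact_trials = integer(0),
                        artifact_amp = 300,
                        noise_sd = 10,
                        sensor_noise_sd = 1,
                        n_sources = 12,
                        line_amp = 2,
                        line_freq = 60) {
  eff <- list(
    n1_uv = n1_uv, frn_uv = frn_uv,
    theta_parietal_db = theta_parietal_db,
    theta_frontal_db = theta_frontal_db,
    alphabeta_db = alphabeta_db,
    base_amp = base_amp,
    subject_gain_sd = subject_gain_sd,
    latency_jitter_sd = latency_jitter_sd,
    artifact_trials = as.integer(artifact_trials),
    artifact_amp = artifact_amp,
    noise_sd = noise_sd,
    sensor_noise_sd = sensor_noise_sd,
    n_sources = n_sources,
    line_amp = line_amp,
    line_freq = line_freq,
    # Injection windows (ms relative to movement onset) and carrier
    # frequencies (Hz); fixed features of the generator.
    windows = list(theta_parietal = c(0, 500), theta_frontal = c(80, 440),
                   alphabeta = c(100, 1000)),
    carriers = c(theta_parietal = 3, theta_frontal = 6, alphabeta = 13),
    latencies = c(n1 = 170, frn = 220)
  )
  class(eff) <- "eeg_effects"
  eff
}

#' Null (condition-independent) effect configuration
#'
#' Identical background and burst structure across all conditions: every
#' per-condition gain is 0 dB and evoked amplitudes are equal, so condition
#' epochs are draws from the same distribution. Used for false-positive-rate
#' checks.
#'
#' @param ... Passed on to [eeg_effects()] to override generator parameters
#'   other than the condition gains.
#' @return An `eeg_effects` object.
#' @export
null_effects <- function(...) {
  flat <- function(v) c(STR = v, POST = v, ADAPT = v, NULL_L = v, NULL_R = v)
  eeg_effects(n1_uv = flat(4.5), frn_uv = flat(2.3),
              theta_parietal_db = flat(0), theta_frontal_db = flat(0),
              alphabeta_db = flat(0), ...)
}

cond_value <- function(vec, cond) {
  out <- unname(vec[cond])
  if (anyNA(out)) {
    stop("effect configuration has no entry for condition: ",
         paste(unique(cond[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

# Half-cosine (Hann) envelope over [0, 1].
hann_env <- function(u) ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)

# k independent pink (1/f amplitude-shaped) noise series of length n, unit
# variance, via frequency-domain synthesis with random phases (rows).
pink_noise <- function(n, k = 1) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- seq_len(nfft) - 1
  f <- pmin(f, nfft - f) / nfft          # two-sided frequency index
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  z <- matrix(complex(real = rnorm(nfft * k), imaginary = rnorm(nfft * k)) * shape,
              nfft, k)
  x <- Re(stats::mvfft(z, inverse = TRUE))[seq_len(n), , drop = FALSE]
  t(x) / apply(x, 2, stats::sd)
}

#' Simulate continuous multichannel EEG for a trial sequence
#'
#' Builds a continuous recording containing one movement-onset event per
#' trial. The signal is the sum of (i) spatially correlated 1/f background
#' noise (pink-noise sources projected through smooth random scalp
#' topographies), (ii) a power-line component, (iii) per-trial injected
#' components scaled by the per-condition gains in `effects` and projected
#' with smooth topographies peaked over the right-parietal or mid-frontal
#' ROI, and (iv) optional high-amplitude blink-like transients on configured
#' trials. Identical seeds reproduce bit-identical output.
#'
#' @param conditions Per-trial condition labels (character vector, `"POST"`
#'   allowed), or a [generate_schedule()] result (labels taken via
#'   [schedule_conditions()]).
#' @param montage An [acticap_montage()]; must contain the ROI electrodes
#'   P2, P4, PO4, Fz, FC1 and FC2.
#' @param effects An [eeg_effects()] configuration.
#' @param seed Integer seed.
#' @param rate Sampling rate (Hz).
#' @param trial_spacing Movement-onset-to-onset interval (s). The default
#'   reflects the task's trial timing (pre-cue delay, reaction, movement and
#'   hold phases).
#' @param pad Padding (s) before the first and after the last onset; must
#'   exceed half the epoch length.
#' @return An object of class `continuous_eeg`: list with `signal`
#'   (channels x samples matrix, microvolts), `rate`, `labels`, `events`
#'   (`data.frame` with `sample`, `trial`, `code`), `unit`, and
#'   `ground_truth` (injected gains, realized subject jitters, artifact
#'   trials and seed).
#' @examples
#' mon <- acticap_montage(32)
#' eeg <- simulate_eeg(c("STR", "POST"), mon, seed = 1, trial_spacing = 5.5)
#' dim(eeg$signal)
#' @export
simulate_eeg <- function(conditions,
                         montage,
                         effects = eeg_effects(),
                         seed = 1,
                         rate = 500,
                         trial_spacing = 5.5,
                         pad = 2.7) {
  if (inherits(conditions, "reach_schedule")) {
    conditions <- schedule_conditions(conditions)
  }
  conditions <- as.character(conditions)
  n_trials <- length(conditions)
  if (n_trials < 1) stop("at least one trial required", call. = FALSE)
  roi_needed <- c("P2", "P4", "PO4", "Fz", "FC1", "FC2")
  missing_roi <- setdiff(roi_needed, montage$label)
  if (length(missing_roi)) {
    stop("montage is missing ROI channels: ", paste(missing_roi, collapse = ", "),
         call. = FALSE)
  }
  nch <- nrow(montage)
  spacing <- round(trial_spacing * rate)
  pad_s <- round(pad * rate)
  N <- 2L * pad_s + spacing * (n_trials - 1L) + 1L
  onsets <- pad_s + 1L + (seq_len(n_trials) - 1L) * spacing

  with_seed(seed, {
    ## spatially correlated 1/f background
    S <- pink_noise(N, effects$n_sources)
    xyz <- montage_xyz(montage)
    A <- matrix(0, nch, effects$n_sources)
    for (s in seq_len(effects$n_sources)) {
      # random source direction in the upper hemisphere
      v <- c(rnorm(2), abs(rnorm(1)) + 0.2)
      v <- v / sqrt(sum(v^2))
      ang <- rad2deg(acos(pmax(-1, pmin(1, as.vector(xyz %*% v)))))
      width <- runif(1, 30, 70)
      A[, s] <- sample(c(-1, 1), 1) * runif(1, 0.5, 1.5) * exp(-0.5 * (ang / width)^2)
    }
    sig <- A %*% S
    sig <- sig * (effects$noise_sd / mean(apply(sig[, seq_len(min(N, 5000L)), drop = FALSE], 1, stats::sd)))
    if (effects$sensor_noise_sd > 0) {
      sig <- sig + matrix(rnorm(nch * N, 0, effects$sensor_noise_sd), nch, N)
    }

    ## power line
    tt <- (seq_len(N) - 1) / rate
    line <- sin(2 * pi * effects$line_freq * tt + runif(1, 0, 2 * pi))
    sig <- sig + (effects$line_amp * runif(nch, 0.5, 1.5)) %o% line

    ## subject-level effect-size jitter (dB), one draw per effect family
    jit <- rnorm(5, 0, effects$subject_gain_sd)
    names(jit) <- c("n1", "frn", "theta_parietal", "theta_frontal", "alphabeta")

    topo_par <- gaussian_topography(montage, c("P2", "P4", "PO4"), fwhm = 50)
    topo_fro <- gaussian_topography(montage, c("Fz", "FC1", "FC2"), fwhm = 50)
    topo_eye <- gaussian_topography(montage, intersect(c("Fp1", "Fp2"), montage$label),
                                    fwhm = 60)

    amp_scale <- function(db) 10^(db / 20)
    ## per-trial injected components are accumulated on a common block grid
    ## (-300..1100 ms around onset) and added to the signal in one pass
    step <- 1000 / rate
    block_ms <- seq(-300, 1100, by = step)
    nb <- length(block_ms)
    at <- function(wave_ms, wave) {
      # resample a component defined on wave_ms onto the block grid
      out <- numeric(nb)
      j <- round((wave_ms - block_ms[1]) / step) + 1L
      keep <- j >= 1 & j <= nb
      out[j[keep]] <- wave[keep]
      out
    }
    for (i in seq_len(n_trials)) {
      cnd <- conditions[i]
      block <- matrix(0, nch, nb)
      ## evoked deflections (Gaussian envelopes, jittered latency)
      t_n1 <- effects$latencies[["n1"]] + rnorm(1, 0, effects$latency_jitter_sd)
      t_frn <- effects$latencies[["frn"]] + rnorm(1, 0, effects$latency_jitter_sd)
      n1_amp <- cond_value(effects$n1_uv, cnd) * amp_scale(jit[["n1"]])
      frn_amp <- cond_value(effects$frn_uv, cnd) * amp_scale(jit[["frn"]])
      block <- block + topo_par %o% (-n1_amp * exp(-0.5 * ((block_ms - t_n1) / 25)^2))
      block <- block + topo_fro %o% (-frn_amp * exp(-0.5 * ((block_ms - t_frn) / 30)^2))

      ## oscillatory bursts
      for (fam in c("theta_parietal", "theta_frontal", "alphabeta")) {
        win <- effects$windows[[fam]]
        f0 <- effects$carriers[[fam]]
        gain <- switch(fam,
                       theta_parietal = cond_value(effects$theta_parietal_db, cnd),
                       theta_frontal = cond_value(effects$theta_frontal_db, cnd),
                       alphabeta = cond_value(effects$alphabeta_db, cnd))
        amp <- effects$base_amp[[fam]] * amp_scale(gain + jit[[fam]])
        ms <- seq(win[1], win[2], by = step)
        env <- hann_env((ms - win[1]) / (win[2] - win[1]))
        wave <- amp * env * sin(2 * pi * f0 * ms / 1000 + runif(1, 0, 2 * pi))
        topo <- if (fam == "theta_frontal") topo_fro else topo_par
        block <- block + topo %o% at(ms, wave)
      }

      ## blink-like artifact
      if (i %in% effects$artifact_trials) {
        bt <- runif(1, 0, 300)
        block <- block + topo_eye %o%
          (effects$artifact_amp * exp(-0.5 * ((block_ms - bt) / 50)^2))
      }

      idx <- onsets[i] + round(block_ms / step)
      keep <- idx >= 1 & idx <= N
      sig[, idx[keep]] <- sig[, idx[keep]] + block[, keep]
    }

    eeg <- list(
      signal = sig,
      rate = rate,
      labels = montage$label,
      events = data.frame(sample = onsets, trial = seq_len(n_trials),
                          code = conditions, stringsAsFactors = FALSE),
      unit = "uV",
      ground_truth = list(
        conditions = conditions,
        effects = effects,
        subject_jitter_db = jit,
        artifact_trials = effects$artifact_trials,
        noise_seed = seed
      )
    )
    class(eeg) <- "continuous_eeg"
    eeg
  })
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("Continuous EEG: %d channels x %d samples @ %g Hz (%.1f s), %d events [%s]\n",
              nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate,
              nrow(x$events), x$unit))
  invisible(x)
}
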