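# End-to-end orchestration: simulate (or accept) a multi-subject session,
# run the preprocessing / CSD / ERP / time-frequency branches, and compute
# the group-level binned statistics.

#' Frequency-band selection from a condition-averaged spectrogram
#'
#' Selects contiguous frequency bands whose mean absolute dB power over the
#' post-onset window exceeds a quantile of the per-frequency scores. The
#' input is the average spectrogram of the two contrasted conditions, so the
#' selection is orthogonal to the ensuing condition contrast. When nothing
#' prominent is found (degenerate or flat spectrogram) the configured
#' fallback bands are returned with a log attribute.
#'
#' @param db Matrix freqs x times of condition-averaged dB power.
#' @param freqs,times Axes of `db` (Hz, ms).
#' @param window Post-onset scoring window (ms).
#' @param threshold_quantile Quantile of the per-frequency score used as the
#'   selection threshold.
#' @param min_prominence Minimum peak score (dB); below it the selection is
#'   deemed empty.
#' @param fallback List of length-2 frequency bands returned when selection
#'   is empty.
#' @return List of length-2 numeric bands (Hz), with attribute
#'   `fallback_used`.
#' @export
select_bands <- function(db, freqs, times, window = c(0, 1000),
                         threshold_quantile = 0.75, min_prominence = 0.5,
                         fallback = list()) {
  sel <- times >= window[1] & times <= window[2]
  score <- rowMeans(abs(db[, sel, drop = FALSE]), na.rm = TRUE)
  score[!is.finite(score)] <- 0
  if (max(score) <= min_prominence) {
    out <- fallback
    attr(out, "fallback_used") <- TRUE
    return(out)
  }
  above <- score >= stats::quantile(score, threshold_quantile) & score > min_prominence
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  bands <- lapply(which(runs$values), function(i) c(freqs[starts[i]], freqs[ends[i]]))
  if (!length(bands)) {
    bands <- fallback
    attr(bands, "fallback_used") <- TRUE
  } else {
    attr(bands, "fallback_used") <- FALSE
  }
  bands
}

#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' full study conditions: 15 subjects, the 596-trial schedule, the 64-channel
#' montage, STR vs POST as the primary contrast, the printed analysis bands
#' (right parietal 2-4 and 8-18 Hz; mid-frontal 5-7 and 10-35 Hz), the CSD
#' statistics window 100-400 ms (15 bins) and the ERSP window 0-1000 ms
#' (50 bins) at 20 ms bin width, alpha = 0.05. Scaled runs override
#' `n_subjects`, the schedule counts, `montage_channels`, `rois` and `bands`.
#'
#' @param seed Master seed; all per-subject streams derive from it.
#' @param n_subjects Number of simulated subjects entering group statistics.
#' @param montage_channels 64 or 32.
#' @param schedule_args Arguments for [generate_schedule()] (minus `seed`).
#' @param contrast Length-2 character: conditions contrasted (first minus
#'   second), e.g. `c("STR", "POST")` or `c("STR", "NULL_L")`.
#' @param eeg_trials `"contrast"` to synthesize EEG only for trials of the
#'   contrasted conditions (scaled runs), or `"all"`.
#' @param effects An [eeg_effects()] configuration.
#' @param geometry A [task_geometry()].
#' @param adapt Reach-model parameters passed to [simulate_reaches()]
#'   (`retention`, `learning_rate`, `motor_noise_sd`).
#' @param rois Character subset of `c("right_parietal", "mid_frontal")`.
#' @param bands Named list (by ROI) of lists of length-2 bands (Hz).
#' @param band_selection `"configured"` uses `bands` directly; `"auto"` runs
#'   [select_bands()] on the condition-averaged ROI spectrogram with `bands`
#'   as fallback.
#' @param csd_window,ersp_window Statistics windows (ms).
#' @param bin_width Bin width (ms).
#' @param alpha Significance threshold.
#' @param filter_band,notch Filtering parameters (Hz).
#' @param epoch_window,baseline Epoching windows (ms).
#' @param amplitude_threshold Artifact screening threshold (microvolts).
#' @param csd A [csd_config()].
#' @param trial_spacing EEG onset-to-onset spacing (s).
#' @param compute_erp,compute_ersp,compute_kinematics Branch switches.
#' @param scalp_maps `"none"` or `"csd"`: compute per-electrode z-maps for
#'   the significant CSD windows.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1,
                            n_subjects = 15,
                            montage_channels = 64,
                            schedule_args = list(),
                            contrast = c("STR", "POST"),
                            eeg_trials = c("contrast", "all"),
                            effects = eeg_effects(),
                            geometry = task_geometry(),
                            adapt = list(retention = 0.98, learning_rate = 0.012,
                                         motor_noise_sd = 2),
                            rois = c("right_parietal", "mid_frontal"),
                            bands = list(right_parietal = list(c(2, 4), c(8, 18)),
                                         mid_frontal = list(c(5, 7), c(10, 35))),
                            band_selection = c("configured", "auto"),
                            csd_window = c(100, 400),
                            ersp_window = c(0, 1000),
                            bin_width = 20,
                            alpha = 0.05,
                            filter_band = c(1, 100),
                            notch = c(59, 61),
                            epoch_window = c(-2500, 2500),
                            baseline = c(-500, 0),
                            amplitude_threshold = 150,
                            csd = csd_config(),
                            trial_spacing = 5.5,
                            compute_erp = TRUE,
                            compute_ersp = TRUE,
                            compute_kinematics = TRUE,
                            scalp_maps = c("none", "csd")) {
  bad_bands <- unlist(bands)
  if (length(bad_bands) && (any(bad_bands < 1) || any(bad_bands > 100))) {
    stop("analysis bands must lie within 1-100 Hz", call. = FALSE)
  }
  if (csd_window[1] < epoch_window[1] || csd_window[2] > epoch_window[2] ||
      ersp_window[1] < epoch_window[1] || ersp_window[2] > epoch_window[2]) {
    stop("statistics windows must lie within the epoch window", call. = FALSE)
  }
  cfg <- list(seed = seed, n_subjects = n_subjects,
              montage_channels = montage_channels,
              schedule_args = schedule_args, contrast = contrast,
              eeg_trials = match.arg(eeg_trials),
              effects = effects, geometry = geometry, adapt = adapt,
              rois = match.arg(rois, several.ok = TRUE),
              bands = bands, band_selection = match.arg(band_selection),
              csd_window = csd_window, ersp_window = ersp_window,
              bin_width = bin_width, alpha = alpha,
              filter_band = filter_band, notch = notch,
              epoch_window = epoch_window, baseline = baseline,
              amplitude_threshold = amplitude_threshold, csd = csd,
              trial_spacing = trial_spacing,
              compute_erp = compute_erp, compute_ersp = compute_ersp,
              compute_kinematics = compute_kinematics,
              scalp_maps = match.arg(scalp_maps))
  class(cfg) <- "analysis_config"
  cfg
}

# Per-subject processing: simulate, preprocess, CSD, and extract the
# summaries entering group statistics.
process_subject <- function(s, cfg, montage, family, freq_need) {
  sched <- do.call(generate_schedule,
                   c(list(seed = derive_seed(cfg$seed, s)), cfg$schedule_args))
  conds <- schedule_conditions(sched)

  kin <- NULL
  keep_kin <- rep(TRUE, nrow(sched))
  drift <- NULL
  if (cfg$compute_kinematics) {
    reaches <- do.call(simulate_reaches,
                       c(list(schedule = sched, geometry = cfg$geometry,
                              seed = derive_seed(cfg$seed, 1000L + s)),
                         cfg$adapt))
    kin <- summarize_trials(reaches$trials, cfg$geometry)
    keep_kin <- reject_trials(kin)
    drift <- drift_contrast(kin, sched, retained = keep_kin)
  }

  eeg_idx <- if (cfg$eeg_trials == "contrast") which(conds %in% cfg$contrast) else seq_along(conds)
  eeg <- simulate_eeg(conds[eeg_idx], montage, cfg$effects,
                      seed = derive_seed(cfg$seed, 2000L + s),
                      trial_spacing = cfg$trial_spacing)
  eeg$events$trial <- eeg_idx
  eeg <- filter_continuous(eeg, cfg$filter_band, cfg$notch)
  eeg <- rereference_average(eeg)
  ep <- epoch_and_baseline(eeg, window = cfg$epoch_window, baseline = cfg$baseline)

  ## stage order contract: kinematic rejection first, then amplitude screening
  keep <- keep_kin[ep$trial]
  n_kin_rej <- sum(!keep)
  amp_keep <- reject_amplitude(ep, cfg$amplitude_threshold)
  n_amp_rej <- sum(keep & !amp_keep)
  keep <- keep & amp_keep
  ep <- subset_epochs(ep, keep)
  csd_ep <- apply_laplacian(ep, montage, cfg$csd)

  out <- list(rejections = data.frame(subject = s, kinematic = n_kin_rej,
                                      amplitude = n_amp_rej,
                                      retained = sum(keep)),
              drift = drift)

  conds_kept <- csd_ep$condition
  if (cfg$compute_erp || cfg$scalp_maps == "csd") {
    ## per-condition subject-average CSD (channels x samples)
    out$csd_avg <- lapply(cfg$contrast, function(cn) {
      sel <- conds_kept == cn
      if (!any(sel)) stop("no retained trials for condition ", cn, call. = FALSE)
      colMeans(csd_ep$data[sel, , , drop = FALSE], dims = 1)
    })
    names(out$csd_avg) <- cfg$contrast
  }

  if (cfg$compute_ersp) {
    roi_chans <- unique(unlist(lapply(cfg$rois, function(r) roi_definition(r)$electrodes)))
    tf_window <- c(min(cfg$baseline[1], cfg$ersp_window[1]) - 2,
                   cfg$ersp_window[2] + 2)
    pw <- wavelet_power(csd_ep, family, freqs = freq_need,
                        channels = roi_chans, times = tf_window)
    ersps <- lapply(cfg$contrast, function(cn) {
      median_ersp(pw, baseline = cfg$baseline, trials = pw$condition == cn)
    })
    names(ersps) <- cfg$contrast
    out$band_tc <- lapply(cfg$rois, function(r) {
      el <- roi_definition(r)$electrodes
      lapply(cfg$bands[[r]], function(bd) {
        lapply(ersps, function(e) band_power_timecourse(e, bd, channels = el))
      })
    })
    names(out$band_tc) <- cfg$rois
    out$ersp_times <- ersps[[1]]$times
  }
  out$times <- csd_ep$times
  out
}

#' Run the full analysis
#'
#' Executes the complete pipeline on simulated data: per subject, schedule
#' generation, reach simulation and kinematic rejection, EEG synthesis,
#' zero-phase filtering, average reference, epoching with baseline
#' correction, amplitude screening (after the kinematic-rejection
#' intersection), surface-Laplacian CSD, ROI ERP extraction and
#' Morlet-wavelet band power; then, across subjects, binned Wilcoxon
#' signed-rank contrasts with step-up FDR correction for the CSD (100-400
#' ms, 15 bins) and ERSP (0-1000 ms, 50 bins) time-courses, N1 and FRN
#' peak-to-peak tests, the implicit-adaptation drift contrast, and optional
#' scalp z-maps over the significant CSD windows. Fully reproducible from
#' the configuration seed.
#'
#' @param config An [analysis_config()].
#' @return Object of class `pe_analysis`: list with elements `config`,
#'   `csd` (per-ROI [binned_contrast()] results), `ersp` (per ROI, per
#'   band), `n1` / `frn` (per-subject amplitude tables and group tests),
#'   `drift` (per-target tests and means), `rejections` (per-subject log),
#'   `scalp` (z-maps per significant CSD window, when requested).
#' @export
run_analysis <- function(config = analysis_config()) {
  cfg <- config
  montage <- acticap_montage(cfg$montage_channels)
  freq_need <- if (cfg$compute_ersp) {
    sort(unique(unlist(lapply(cfg$rois, function(r) {
      unlist(lapply(cfg$bands[[r]], function(bd) seq(ceiling(bd[1]), floor(bd[2]))))
    }))))
  } else integer(0)
  family <- if (cfg$compute_ersp) wavelet_family(rate = 500) else NULL

  subjects <- lapply(seq_len(cfg$n_subjects), process_subject,
                     cfg = cfg, montage = montage, family = family,
                     freq_need = freq_need)

  res <- list(config = cfg,
              rejections = do.call(rbind, lapply(subjects, `[[`, "rejections")))

  ## ---- CSD branch -------------------------------------------------------
  if (cfg$compute_erp) {
    times <- subjects[[1]]$times
    res$csd <- list()
    res$n1 <- res$frn <- NULL
    roi_tc <- lapply(cfg$rois, function(r) {
      el <- roi_definition(r)$electrodes
      ci <- match(el, montage$label)
      lapply(cfg$contrast, function(cn) {
        t(vapply(subjects, function(sb) colMeans(sb$csd_avg[[cn]][ci, , drop = FALSE]),
                 numeric(length(times))))
      })
    })
    names(roi_tc) <- cfg$rois
    for (r in cfg$rois) {
      a <- bin_timecourse(roi_tc[[r]][[1]], times = times,
                          window = cfg$csd_window, width = cfg$bin_width)
      b <- bin_timecourse(roi_tc[[r]][[2]], times = times,
                          window = cfg$csd_window, width = cfg$bin_width)
      res$csd[[r]] <- binned_contrast(a, b, alpha = cfg$alpha)
    }
    if ("right_parietal" %in% cfg$rois) {
      tab <- vapply(roi_tc$right_parietal,
                    function(m) apply(m, 1, n1_amplitude, times = times),
                    numeric(cfg$n_subjects))
      colnames(tab) <- cfg$contrast
      res$n1 <- list(amplitudes = tab,
                     test = wilcoxon_signed_rank(tab[, 1], tab[, 2]))
    }
    if ("mid_frontal" %in% cfg$rois) {
      tab <- vapply(roi_tc$mid_frontal,
                    function(m) apply(m, 1, frn_amplitude, times = times),
                    numeric(cfg$n_subjects))
      colnames(tab) <- cfg$contrast
      res$frn <- list(amplitudes = tab,
                      test = wilcoxon_signed_rank(tab[, 1], tab[, 2]))
    }
  }

  ## ---- ERSP branch ------------------------------------------------------
  if (cfg$compute_ersp) {
    res$ersp <- list()
    et <- subjects[[1]]$ersp_times
    for (r in cfg$rois) {
      res$ersp[[r]] <- list()
      for (bi in seq_along(cfg$bands[[r]])) {
        bd <- cfg$bands[[r]][[bi]]
        mats <- lapply(seq_along(cfg$contrast), function(k) {
          t(vapply(subjects, function(sb) sb$band_tc[[r]][[bi]][[k]],
                   numeric(length(et))))
        })
        a <- bin_timecourse(mats[[1]], times = et, window = cfg$ersp_window,
                            width = cfg$bin_width)
        b <- bin_timecourse(mats[[2]], times = et, window = cfg$ersp_window,
                            width = cfg$bin_width)
        res$ersp[[r]][[sprintf("%g-%g Hz", bd[1], bd[2])]] <-
          binned_contrast(a, b, alpha = cfg$alpha)
      }
    }
  }

  ## ---- kinematic drift --------------------------------------------------
  if (cfg$compute_kinematics) {
    pre_l <- vapply(subjects, function(sb) attr(sb$drift$left, "pre_mean"), numeric(1))
    post_l <- vapply(subjects, function(sb) attr(sb$drift$left, "post_mean"), numeric(1))
    pre_r <- vapply(subjects, function(sb) attr(sb$drift$right, "pre_mean"), numeric(1))
    post_r <- vapply(subjects, function(sb) attr(sb$drift$right, "post_mean"), numeric(1))
    res$drift <- list(
      left = if (all(is.finite(c(pre_l, post_l))))
        list(test = wilcoxon_signed_rank(post_l, pre_l),
             pre_mean = mean(pre_l), post_mean = mean(post_l)),
      right = if (all(is.finite(c(pre_r, post_r))))
        list(test = wilcoxon_signed_rank(post_r, pre_r),
             pre_mean = mean(pre_r), post_mean = mean(post_r))
    )
  }

  ## ---- scalp z-maps over significant CSD windows ------------------------
  if (cfg$scalp_maps == "csd" && cfg$compute_erp) {
    res$scalp <- list()
    for (r in names(res$csd)) {
      w <- attr(res$csd[[r]], "windows")
      if (!nrow(w)) next
      res$scalp[[r]] <- lapply(seq_len(nrow(w)), function(i) {
        sel <- times >= w$start[i] & times < w$end[i]
        m <- lapply(cfg$contrast, function(cn) {
          t(vapply(subjects, function(sb) rowMeans(sb$csd_avg[[cn]][, sel, drop = FALSE]),
                   numeric(nrow(montage))))
        })
        z <- scalp_zmap(m[[1]], m[[2]], labels = montage$label)
        list(window = c(w$start[i], w$end[i]), z = z)
      })
    }
  }

  class(res) <- "pe_analysis"
  res
}

#' @export
print.pe_analysis <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Prediction-error EEG analysis: %s vs %s, %d subjects\n",
              cfg$contrast[1], cfg$contrast[2], cfg$n_subjects))
  cat(sprintf("  trials retained per subject: %s (kinematic+amplitude rejection applied)\n",
              paste(range(x$rejections$retained), collapse = "-")))
  for (r in names(x$csd %||% list())) {
    cat(sprintf("CSD %s (%g-%g ms): ", r, cfg$csd_window[1], cfg$csd_window[2]))
    w <- attr(x$csd[[r]], "windows")
    if (nrow(w)) cat("significant", paste(sprintf("%g-%g ms", w$start, w$end), collapse = ", "), "\n")
    else cat("no significant bins\n")
  }
  for (r in names(x$ersp %||% list())) {
    for (bn in names(x$ersp[[r]])) {
      w <- attr(x$ersp[[r]][[bn]], "windows")
      cat(sprintf("ERSP %s %s: ", r, bn))
      if (nrow(w)) cat("significant", paste(sprintf("%g-%g ms", w$start, w$end), collapse = ", "), "\n")
      else cat("no significant bins\n")
    }
  }
  if (!is.null(x$n1)) { cat("N1: "); print(x$n1$test) }
  if (!is.null(x$frn)) { cat("FRN: "); print(x$frn$test) }
  if (!is.null(x$drift$left)) {
    cat(sprintf("Drift (NULL-left): pre %.2f, post %.2f deg; ",
                x$drift$left$pre_mean, x$drift$left$post_mean))
    print(x$drift$left$test)
  }
  invisible(x)
}
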