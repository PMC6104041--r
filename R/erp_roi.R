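# Region-of-interest pooling and peak-to-peak ERP component scoring.

#' Analysis regions of interest
#'
#' The two fixed electrode groupings used for the prediction-error contrasts:
#' a right parietal ROI (P2, P4, PO4), lying over the superior parietal
#' lobule, and a mid-frontal ROI (Fz, FC1, FC2), capturing the
#' feedback-related negativity.
#'
#' @param name `"right_parietal"` or `"mid_frontal"`.
#' @return List with `name` and `electrodes`.
#' @export
roi_definition <- function(name = c("right_parietal", "mid_frontal")) {
  name <- match.arg(name)
  electrodes <- switch(name,
                       right_parietal = c("P2", "P4", "PO4"),
                       mid_frontal = c("Fz", "FC1", "FC2"))
  list(name = name, electrodes = electrodes)
}

#' Pool ROI electrodes
#'
#' Simple mean across the ROI electrodes, per trial and sample.
#'
#' @param epochs An `epoch_set` (typically CSD).
#' @param roi A [roi_definition()] or character vector of electrode labels.
#' @return Matrix trials x samples with attribute `times`.
#' @export
pool_roi <- function(epochs, roi) {
  labels <- if (is.list(roi)) roi$electrodes else roi
  ci <- match(labels, epochs$labels)
  if (anyNA(ci)) {
    stop("ROI electrodes missing from epochs: ",
         paste(labels[is.na(ci)], collapse = ", "), call. = FALSE)
  }
  out <- colMeans(aperm(epochs$data[, ci, , drop = FALSE], c(2, 1, 3)), dims = 1)
  out <- matrix(out, nrow = dim(epochs$data)[1])
  attr(out, "times") <- epochs$times
  out
}

window_values <- function(timecourse, times, window) {
  if (min(times) > window[1] || max(times) < window[2]) {
    stop("timecourse does not cover the scoring window", call. = FALSE)
  }
  timecourse[times >= window[1] & times <= window[2]]
}

#' Visual N1 peak-to-baseline amplitude
#'
#' Scores the visual N1 as the peak CSD negativity (window minimum) between
#' 125 and 200 ms minus the average CSD activity 0-50 ms after movement
#' onset. Negative values indicate an N1-like deflection; the measure is
#' invariant to constant offsets. Windows are closed intervals on the sample
#' grid.
#'
#' @param timecourse Numeric ROI-average CSD time-course.
#' @param times Sample times (ms); taken from `attr(timecourse, "times")`
#'   when omitted.
#' @param peak_window,ref_window Scoring windows (ms).
#' @return N1 amplitude (same unit as the input).
#' @export
n1_amplitude <- function(timecourse, times = attr(timecourse, "times"),
                         peak_window = c(125, 200), ref_window = c(0, 50)) {
  min(window_values(timecourse, times, peak_window)) -
    mean(window_values(timecourse, times, ref_window))
}

#' FRN peak-to-peak amplitude
#'
#' Scores the feedback-related negativity as the difference between the most
#' negative and most positive CSD peaks within 200-600 ms after movement
#' onset (minimum minus maximum), so the result is always <= 0 and a greater
#' FRN is more negative.
#'
#' @inheritParams n1_amplitude
#' @param window Scoring window (ms), closed.
#' @return FRN amplitude (<= 0).
#' @export
frn_amplitude <- function(timecourse, times = attr(timecourse, "times"),
                          window = c(200, 600)) {
  v <- window_values(timecourse, times, window)
  min(v) - max(v)
}
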