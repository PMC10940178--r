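#' Zero-phase band-pass filter a 12-lead recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass per lead.
#' The default 0.67--150 Hz passband follows clinical ECG guideline
#' recommendations.
#'
#' @param recording a `multi_lead_recording`.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth prototype order.
#' @return filtered `multi_lead_recording`.
#' @export
bandpass_filter <- function(recording, low = 0.67, high = 150, order = 2) {
  fs <- recording$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("invalid band: need 0 < low < high < sampling rate / 2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- apply(recording$signals, 2,
               function(x) signal::filtfilt(bf, x))
  colnames(out) <- colnames(recording$signals)
  multi_lead_recording(out, fs, recording$meta)
}

#' Threshold QRS detection
#'
#' Finds one peak (the local extremum of absolute amplitude) per contiguous
#' run of samples whose magnitude reaches the threshold, then merges peaks
#' closer than the refractory period, keeping the larger one. The threshold
#' must be set between the T-wave peak and the QRS peak (as in manual
#' threshold placement); a threshold below the T-wave amplitude over-counts
#' beats.
#'
#' @param recording a `multi_lead_recording`.
#' @param lead lead used for detection (default II).
#' @param threshold detection threshold in mV (applied to |signal|).
#' @param refractory_ms minimum separation between detected peaks.
#' @return sorted integer vector of peak sample indices (possibly empty,
#'   with a warning).
#' @export
detect_qrs <- function(recording, lead = "II", threshold,
                       refractory_ms = 200) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  x <- recording$signals[, lead]
  supra <- abs(x) >= abs(threshold)
  if (!any(supra)) {
    warning("no supra-threshold samples; no beats detected")
    return(integer(0))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(k) {
    i <- starts[k]:ends[k]
    i[which.max(abs(x[i]))]
  }, integer(1))
  peaks <- sort(peaks)
  # merge peaks within the refractory period, keeping the larger extremum
  ref_n <- round(refractory_ms * recording$fs / 1000)
  keep <- peaks[1]
  for (p in peaks[-1]) {
    last <- keep[length(keep)]
    if (p - last < ref_n) {
      if (abs(x[p]) > abs(x[last])) keep[length(keep)] <- p
    } else {
      keep <- c(keep, p)
    }
  }
  keep
}

#' Define the beat window from the PR interval and mean R-R
#'
#' The pre-peak offset covers the measured PR interval (P onset to QRS
#' peak) plus a margin for the TP baseline; the total window length equals
#' the mean R-R interval.
#'
#' @param pr_interval_ms measured PR interval (ms), P onset to QRS peak.
#' @param mean_rr_ms average R-R interval (ms); must exceed the PR
#'   interval.
#' @param sampling_rate Hz.
#' @param margin_ms extra pre-peak margin beyond the PR interval.
#' @return integer vector `c(pre = , post = )` in samples; the window for a
#'   peak at index `i` is `[i - pre, i + post - 1]`.
#' @export
define_beat_window <- function(pr_interval_ms, mean_rr_ms,
                               sampling_rate, margin_ms = 40) {
  if (pr_interval_ms <= 0) stop("PR interval must be positive")
  if (mean_rr_ms <= pr_interval_ms) {
    stop("mean R-R must exceed the PR interval")
  }
  pre <- as.integer(round((pr_interval_ms + margin_ms) *
                            sampling_rate / 1000))
  total <- as.integer(round(mean_rr_ms * sampling_rate / 1000))
  c(pre = pre, post = total - pre)
}

#' Segment a recording into beat windows
#'
#' @param recording a `multi_lead_recording`.
#' @param peaks QRS peak indices from [detect_qrs()].
#' @param window `c(pre, post)` from [define_beat_window()].
#' @param qrs_onset_to_peak_samp distance from QRS onset to the QRS peak in
#'   samples; used to detect windows running into the next beat's QRS.
#' @return a `beat_set`: list with `peaks` (beats whose full window lies in
#'   the recording), `pre`, `post`, `fs`. When the window would overlap the
#'   next beat's QRS onset (window longer than the shortest observed R-R
#'   allows), it is truncated there with a warning.
#' @export
extract_beats <- function(recording, peaks, window,
                          qrs_onset_to_peak_samp = 0L) {
  n <- nrow(recording$signals)
  pre <- window[["pre"]]; post <- window[["post"]]
  if (length(peaks) >= 2) {
    gap <- min(diff(peaks))
    if (post - 1L + qrs_onset_to_peak_samp >= gap) {
      warning("beat window overlaps the next beat's QRS onset; ",
              "truncating the window there")
      post <- gap - qrs_onset_to_peak_samp
    }
  }
  ok <- peaks - pre >= 1L & peaks + post - 1L <= n
  peaks <- peaks[ok]
  structure(list(peaks = peaks, pre = pre, post = post,
                 fs = recording$fs, labels = NULL),
            class = "beat_set")
}

# samples x 12 matrix for beat i, optionally shifted by `shift` samples
beat_matrix <- function(recording, beats, i, shift = 0L) {
  p <- beats$peaks[i] + shift
  recording$signals[(p - beats$pre):(p + beats$post - 1L), , drop = FALSE]
}

#' Template library of representative beats
#'
#' @param templates named list of samples x 12 matrices sharing the beat
#'   window geometry; names are labels such as "sinus", "PVC".
#' @param sinus the designated sinus label (must be present).
#' @return object of class `template_library`.
#' @export
template_library <- function(templates, sinus = "sinus") {
  if (length(templates) == 0) stop("template library must not be empty")
  if (!sinus %in% names(templates)) {
    stop("designated sinus template '", sinus, "' not in library")
  }
  structure(list(templates = templates, sinus = sinus),
            class = "template_library")
}

#' Build a template library from chosen beat indices
#'
#' Stand-in for manual template selection: the caller names which detected
#' beats exemplify each morphology.
#'
#' @param recording a `multi_lead_recording`.
#' @param beats a `beat_set`.
#' @param index_by_label named list/vector mapping labels to beat indices,
#'   e.g. `list(sinus = 1, PVC = 7)`.
#' @param sinus designated sinus label.
#' @return a `template_library`.
#' @export
build_template_library <- function(recording, beats, index_by_label,
                                   sinus = "sinus") {
  tpl <- lapply(index_by_label, function(i)
    beat_matrix(recording, beats, i))
  template_library(tpl, sinus = sinus)
}

# centred normalised cross-correlation (cosine similarity of centred
# vectors); scale-invariant
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Assign each beat to the template with maximal cross-correlation
#'
#' Normalised (amplitude-invariant) cross-correlation is computed over the
#' QRS region (QRS onset - pad to J + pad) across all 12 leads; ties break
#' toward the designated sinus template.
#'
#' @param beats a `beat_set`.
#' @param recording the `multi_lead_recording` the beats index into.
#' @param library a `template_library`.
#' @param marks `interval_marks` in window coordinates.
#' @param pad_ms padding around the QRS region.
#' @return character vector of labels, one per beat.
#' @export
assign_templates <- function(beats, recording, library, marks,
                             pad_ms = 20) {
  stopifnot(inherits(library, "template_library"))
  fs <- recording$fs
  nwin <- beats$pre + beats$post
  region <- idx_range(marks$qrs_onset_ms - pad_ms, marks$j_ms + pad_ms,
                      fs, nwin)
  tvecs <- lapply(library$templates, function(m)
    as.vector(m[region, , drop = FALSE]))
  labs <- names(library$templates)
  vapply(seq_along(beats$peaks), function(i) {
    v <- as.vector(beat_matrix(recording, beats, i)[region, , drop = FALSE])
    cc <- vapply(tvecs, function(tv) ncc(v, tv), numeric(1))
    best <- max(cc)
    cand <- labs[cc >= best - 1e-12]
    if (library$sinus %in% cand) library$sinus else cand[1]
  }, character(1))
}

#' Align beats to a template and average them
#'
#' Beats carrying the requested label are shifted by the integer sample
#' offset (within `max_shift_ms`) that maximises normalised
#' cross-correlation of the QRS region on the alignment lead against the
#' template, then averaged per sample and per lead; the per-sample standard
#' deviation over the aligned beats is returned alongside.
#'
#' @param beats a `beat_set`.
#' @param recording the `multi_lead_recording`.
#' @param library a `template_library`; the template for `label` drives
#'   alignment.
#' @param labels per-beat labels from [assign_templates()].
#' @param marks `interval_marks` in window coordinates.
#' @param label which template's beats to average (default the library's
#'   sinus label).
#' @param max_shift_ms alignment search range.
#' @param align_lead lead used for the alignment correlation.
#' @param pad_ms QRS region padding for the correlation.
#' @param time_range_s optional `c(from, to)` in seconds: only beats whose
#'   peak falls inside are averaged (e.g. 10-s blocks for stress ECGs).
#' @return an `averaged_beat`: list with `mean` and `sd` (samples x 12
#'   matrices, mV), `n` contributing beats, `pre`, `post`, `fs`,
#'   `peak_sample`, and attribute `shifts` (applied shifts in samples).
#' @export
align_and_average <- function(beats, recording, library, labels,
                              label = NULL, max_shift_ms = 50,
                              align_lead = "II", pad_ms = 20,
                              marks, time_range_s = NULL) {
  if (is.null(label)) label <- library$sinus
  sel <- which(labels == label)
  if (!is.null(time_range_s)) {
    t_s <- (beats$peaks[sel] - 1) / beats$fs
    sel <- sel[t_s >= time_range_s[1] & t_s <= time_range_s[2]]
  }
  if (length(sel) == 0) stop("no beats with label '", label, "'")
  fs <- recording$fs
  nwin <- beats$pre + beats$post
  region <- idx_range(marks$qrs_onset_ms - pad_ms, marks$j_ms + pad_ms,
                      fs, nwin)
  tvec <- library$templates[[label]][region, align_lead]
  smax <- as.integer(round(max_shift_ms * fs / 1000))
  x <- recording$signals[, align_lead]
  n <- nrow(recording$signals)

  shifts <- integer(length(sel))
  for (k in seq_along(sel)) {
    p <- beats$peaks[sel[k]]
    lo <- max(-smax, 1L - (p - beats$pre))
    hi <- min(smax, n - (p + beats$post - 1L))
    cand <- lo:hi
    cc <- vapply(cand, function(d) {
      seg <- x[(p - beats$pre + d):(p + beats$post - 1L + d)][region]
      ncc(seg, tvec)
    }, numeric(1))
    shifts[k] <- cand[which.max(cc)]
  }

  nl <- ncol(recording$signals)
  s1 <- matrix(0, nwin, nl)
  s2 <- matrix(0, nwin, nl)
  for (k in seq_along(sel)) {
    m <- beat_matrix(recording, beats, sel[k], shift = shifts[k])
    s1 <- s1 + m
    s2 <- s2 + m^2
  }
  nb <- length(sel)
  mu <- s1 / nb
  sdm <- if (nb > 1) sqrt(pmax((s2 - nb * mu^2) / (nb - 1), 0))
         else matrix(0, nwin, nl)
  colnames(mu) <- colnames(recording$signals)
  colnames(sdm) <- colnames(recording$signals)
  structure(list(mean = mu, sd = sdm, n = nb, pre = beats$pre,
                 post = beats$post, fs = fs,
                 peak_sample = beats$pre + 1L),
            class = "averaged_beat", shifts = shifts)
}

#' Construct an averaged beat directly from matrices
#'
#' @param mean,sd samples x 12 matrices (mV); `sd` must be non-negative.
#' @param n contributing beat count (>= 1).
#' @param pre,post window offsets in samples.
#' @param fs sampling rate (Hz).
#' @return an `averaged_beat`.
#' @export
averaged_beat <- function(mean, sd, n, pre, post, fs) {
  stopifnot(all(dim(mean) == dim(sd)), n >= 1, all(sd >= 0))
  structure(list(mean = mean, sd = sd, n = n, pre = pre, post = post,
                 fs = fs, peak_sample = pre + 1L),
            class = "averaged_beat")
}

#' Run the full beat pipeline on one recording
#'
#' Convenience wrapper: band-pass filter, threshold QRS detection on the
#' detection lead, beat windowing from the PR interval and the mean
#' detected R-R, template assignment, and aligned averaging of sinus beats.
#' Templates are seeded from supplied beat indices or, if `truth` is given,
#' from the first beat of each ground-truth label.
#'
#' @param recording a `multi_lead_recording`.
#' @param marks_rel named numeric fiducials relative to the QRS peak
#'   (`p_onset`, `qrs_onset`, `j`, `t_end`), e.g. from simulator ground
#'   truth or an annotation file.
#' @param threshold_mv QRS detection threshold.
#' @param truth optional simulator ground truth used to seed templates.
#' @param template_idx optional named list of beat indices per label.
#' @param filter_band `c(low, high)` Hz, or `NULL` to skip filtering.
#' @param detect_lead detection/alignment lead.
#' @param margin_ms pre-window margin beyond the PR interval.
#' @param refractory_ms QRS detection refractory period.
#' @param time_range_s optional averaging block, see [align_and_average()].
#' @return list with `averaged` (an `averaged_beat`), `beats`, `labels`,
#'   `marks` (window coordinates, `interval_marks`), `window`, and the
#'   filtered `recording`.
#' @export
process_recording <- function(recording, marks_rel, threshold_mv = 0.6,
                              truth = NULL, template_idx = NULL,
                              filter_band = c(0.67, 150),
                              detect_lead = "II", margin_ms = 40,
                              refractory_ms = 200, time_range_s = NULL) {
  rec <- if (is.null(filter_band)) recording
         else bandpass_filter(recording, filter_band[1], filter_band[2])
  peaks <- detect_qrs(rec, lead = detect_lead, threshold = threshold_mv,
                      refractory_ms = refractory_ms)
  if (length(peaks) < 2) stop("fewer than two beats detected")
  mean_rr_ms <- mean(diff(peaks)) * 1000 / rec$fs
  pr_ms <- -marks_rel[["p_onset"]]
  window <- define_beat_window(pr_ms, mean_rr_ms, rec$fs,
                               margin_ms = margin_ms)
  on2pk <- as.integer(round(-marks_rel[["qrs_onset"]] * rec$fs / 1000))
  beats <- extract_beats(rec, peaks, window,
                         qrs_onset_to_peak_samp = on2pk)
  pre_ms <- beats$pre * 1000 / rec$fs
  marks <- interval_marks(pre_ms + marks_rel[["p_onset"]],
                          pre_ms + marks_rel[["qrs_onset"]],
                          pre_ms + marks_rel[["j"]],
                          min(pre_ms + marks_rel[["t_end"]],
                              (beats$pre + beats$post - 1) * 1000 / rec$fs),
                          qrs_peak_ms = pre_ms)

  if (is.null(template_idx)) {
    if (!is.null(truth)) {
      # seed one template per ground-truth label from the nearest detected
      # beat (emulating manual template selection)
      template_idx <- list()
      for (lab in unique(truth$labels)) {
        bt <- truth$beat_ms[truth$labels == lab][1]
        i <- which.min(abs(beats$peaks - (bt * rec$fs / 1000 + 1)))
        template_idx[[if (lab == "sinus") "sinus" else lab]] <- i
      }
      if (!"sinus" %in% names(template_idx)) {
        template_idx$sinus <- 1L
      }
    } else {
      template_idx <- list(sinus = 1L)
    }
  }
  library <- build_template_library(rec, beats, template_idx)
  labels <- assign_templates(beats, rec, library, marks)
  avg <- align_and_average(beats, rec, library, labels, marks = marks,
                           align_lead = detect_lead,
                           time_range_s = time_range_s)
  list(averaged = avg, beats = beats, labels = labels, marks = marks,
       window = window, recording = rec)
}
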