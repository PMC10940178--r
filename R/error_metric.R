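#' Settings for the multi-stage beat-comparison error metric
#'
#' The error between a test and a reference averaged beat is computed in
#' three stages: (1) vertical alignment minimising the total absolute
#' difference over the quiet early window (P onset to the first third of
#' the QRS complex), (2) sign-aware clipping of the QRS peak at
#' `(1 - truncation_fraction)` of the reference QRS extremum, suppressing
#' sub-threshold QRS amplitude differences, and (3) per-sample fine time
#' alignment taking the minimum difference within `fine_tol_ms`.
#'
#' @param truncation_fraction QRS peak truncation fraction in \[0, 0.5).
#' @param fine_tol_ms fine time-alignment tolerance (ms, >= 0).
#' @param truncation_mode `"reference"` clips both waveforms at the
#'   reference extremum's level (default); `"each"` clips each waveform at
#'   its own extremum's level.
#' @return object of class `alignment_settings`.
#' @export
alignment_settings <- function(truncation_fraction = 0.05,
                               fine_tol_ms = 5,
                               truncation_mode = c("reference", "each")) {
  if (truncation_fraction < 0 || truncation_fraction >= 0.5) {
    stop("truncation fraction must be in [0, 0.5)")
  }
  if (fine_tol_ms < 0) stop("fine-alignment tolerance must be >= 0")
  structure(list(truncation_fraction = truncation_fraction,
                 fine_tol_ms = fine_tol_ms,
                 truncation_mode = match.arg(truncation_mode)),
            class = "alignment_settings")
}

#' Optimal vertical offset between two waveforms
#'
#' Finds the offset minimising the total absolute difference
#' `sum(|test - offset - ref|)` over the vertical-alignment window
#' (P onset to the first third of the QRS complex). The L1 optimum is the
#' median of the pointwise differences over that window.
#'
#' @param test,ref numeric waveforms (mV) on the same sample grid.
#' @param marks `interval_marks` in window coordinates.
#' @param fs sampling rate (Hz).
#' @return offset in mV.
#' @export
vertical_offset <- function(test, ref, marks, fs) {
  idx <- idx_range(marks$p_onset_ms, qrs_first_third(marks), fs,
                   min(length(test), length(ref)))
  if (length(idx) == 0) stop("empty vertical-alignment window")
  stats::median(test[idx] - ref[idx])
}

#' Sign-aware QRS peak truncation
#'
#' Within the QRS interval, both waveforms are clipped at
#' `(1 - fraction) * |reference QRS extremum|` toward the extremum's sign
#' (mode "reference"), so amplitude differences smaller than the fraction
#' vanish at the peak. Samples outside the QRS interval are untouched.
#'
#' @param test,ref numeric waveforms on the same grid.
#' @param marks `interval_marks` in window coordinates.
#' @param fraction truncation fraction in \[0, 0.5).
#' @param fs sampling rate (Hz).
#' @param mode `"reference"` or `"each"`, see [alignment_settings()].
#' @return list with clipped `test` and `ref`.
#' @export
truncate_qrs_peak <- function(test, ref, marks, fraction = 0.05, fs,
                              mode = "reference") {
  if (fraction < 0 || fraction >= 0.5) {
    stop("truncation fraction must be in [0, 0.5)")
  }
  if (fraction == 0) return(list(test = test, ref = ref))
  qrs <- idx_range(marks$qrs_onset_ms, marks$j_ms, fs,
                   min(length(test), length(ref)))
  ext <- ref[qrs][which.max(abs(ref[qrs]))]
  if (abs(ext) < 1e-12) {
    warning("flat QRS in reference; truncation is a no-op")
    return(list(test = test, ref = ref))
  }
  clip <- function(x, bound_abs, s) {
    if (s > 0) pmin(x, bound_abs) else pmax(x, -bound_abs)
  }
  s <- sign(ext)
  bound <- (1 - fraction) * abs(ext)
  ref[qrs] <- clip(ref[qrs], bound, s)
  if (mode == "each") {
    ext_t <- test[qrs][which.max(abs(test[qrs]))]
    test[qrs] <- clip(test[qrs], (1 - fraction) * abs(ext_t), sign(ext_t))
  } else {
    test[qrs] <- clip(test[qrs], bound, s)
  }
  list(test = test, ref = ref)
}

#' Per-sample error with fine time alignment
#'
#' `e[t] = min over |delta| <= tolerance of |test[t + delta] - ref[t]|`,
#' with out-of-range indices clamped to the waveform boundary. Tolerance 0
#' reduces to the plain absolute difference.
#'
#' @param test,ref numeric waveforms of equal length.
#' @param tol_ms fine-alignment tolerance (ms).
#' @param fs sampling rate (Hz).
#' @return non-negative error trace, same length as the inputs.
#' @export
pointwise_error <- function(test, ref, tol_ms = 5, fs) {
  stopifnot(length(test) == length(ref))
  n <- length(test)
  k <- as.integer(round(tol_ms * fs / 1000))
  if (k >= n) stop("tolerance exceeds the window length")
  err <- rep(Inf, n)
  base <- seq_len(n)
  for (d in (-k):k) {
    idx <- pmin(pmax(base + d, 1L), n)
    err <- pmin(err, abs(test[idx] - ref))
  }
  err
}

# crop two averaged beats to their common window around the QRS peak;
# returns the cropped beats plus marks shifted into the common coordinates
# (input marks are in the reference beat's window coordinates)
crop_common <- function(test_ab, ref_ab, marks) {
  pre <- min(test_ab$pre, ref_ab$pre)
  post <- min(test_ab$post, ref_ab$post)
  crop <- function(ab) {
    rows <- (ab$pre - pre + 1L):(ab$pre + post)
    ab$mean <- ab$mean[rows, , drop = FALSE]
    ab$sd <- ab$sd[rows, , drop = FALSE]
    ab$pre <- pre; ab$post <- post; ab$peak_sample <- pre + 1L
    ab
  }
  shift_ms <- -(ref_ab$pre - pre) * 1000 / ref_ab$fs
  list(test = crop(test_ab), ref = crop(ref_ab),
       marks = shift_marks(marks, shift_ms))
}

#' Interval-wise error report between two averaged beats
#'
#' Per lead, applies the three metric stages (vertical offset, QRS peak
#' truncation, fine-aligned pointwise error) and reports the maximum of the
#' error trace over the whole beat (P onset to T end), the PR interval, the
#' QRS interval, the ST segment (J to J+80 ms) and the T interval, plus the
#' error at the J point. Standard-deviation maxima over the same intervals
#' are taken from the test beat's per-sample SD. The subject-level summary
#' takes, per interval, the maximum over the 12 leads (the lead that most
#' compromises interpretation).
#'
#' @param test_ab,ref_ab `averaged_beat` objects with the same lead set;
#'   windows may differ and are compared over their overlap anchored at the
#'   QRS peak.
#' @param marks `interval_marks` in the reference beat's window
#'   coordinates.
#' @param settings an `alignment_settings`.
#' @return object of class `interval_error_report`: list with `per_lead`
#'   (data.frame lead x interval of `max_error` and `max_sd`), `j_point`
#'   (data.frame of per-lead J-point error), and `summary` (per-interval
#'   max-lead values).
#' @export
compute_error_report <- function(test_ab, ref_ab, marks,
                                 settings = alignment_settings()) {
  stopifnot(identical(colnames(test_ab$mean), colnames(ref_ab$mean)),
            test_ab$fs == ref_ab$fs)
  cc <- crop_common(test_ab, ref_ab, marks)
  test_ab <- cc$test; ref_ab <- cc$ref; marks <- cc$marks
  fs <- ref_ab$fs
  n <- nrow(ref_ab$mean)
  win_end_ms <- (n - 1) * 1000 / fs
  if (marks$p_onset_ms < 0 || marks$t_end_ms > win_end_ms) {
    stop("interval mark outside the common beat window")
  }
  st <- st_window(marks)
  intervals <- list(
    whole = c(marks$p_onset_ms, marks$t_end_ms),
    PR = c(marks$p_onset_ms, marks$qrs_onset_ms),
    QRS = c(marks$qrs_onset_ms, marks$j_ms),
    ST = c(st[1], min(st[2], marks$t_end_ms)),
    T = c(min(st[2], marks$t_end_ms), marks$t_end_ms)
  )
  leads <- colnames(ref_ab$mean)
  j_idx <- ms_idx(marks$j_ms, fs)

  per_lead <- list()
  j_err <- stats::setNames(numeric(length(leads)), leads)
  for (ld in leads) {
    tst <- test_ab$mean[, ld]
    ref <- ref_ab$mean[, ld]
    off <- vertical_offset(tst, ref, marks, fs)
    tr <- truncate_qrs_peak(tst - off, ref, marks,
                            settings$truncation_fraction, fs,
                            mode = settings$truncation_mode)
    e <- pointwise_error(tr$test, tr$ref, settings$fine_tol_ms, fs)
    sdw <- test_ab$sd[, ld]
    for (iv in names(intervals)) {
      idx <- idx_range(intervals[[iv]][1], intervals[[iv]][2], fs, n)
      if (length(idx) == 0) next
      per_lead[[length(per_lead) + 1L]] <- data.frame(
        lead = ld, interval = iv,
        max_error = max(e[idx]), max_sd = max(sdw[idx]),
        stringsAsFactors = FALSE)
    }
    j_err[ld] <- e[j_idx]
  }
  per_lead <- do.call(rbind, per_lead)

  summ <- do.call(rbind, lapply(c("whole", "PR", "QRS", "ST"), function(iv) {
    sub <- per_lead[per_lead$interval == iv, ]
    data.frame(interval = iv,
               max_error = max(sub$max_error),
               max_error_lead = sub$lead[which.max(sub$max_error)],
               max_sd = max(sub$max_sd),
               max_sd_lead = sub$lead[which.max(sub$max_sd)],
               stringsAsFactors = FALSE)
  }))
  summ <- rbind(summ, data.frame(
    interval = "J", max_error = max(j_err),
    max_error_lead = names(j_err)[which.max(j_err)],
    max_sd = NA_real_, max_sd_lead = NA_character_,
    stringsAsFactors = FALSE))

  structure(list(
    per_lead = per_lead,
    j_point = data.frame(lead = names(j_err), error = as.numeric(j_err),
                         stringsAsFactors = FALSE),
    summary = summ,
    settings = settings),
    class = "interval_error_report")
}

#' Timing of MHD distortion relative to aortic flow
#'
#' Registers the flow curve to the averaged beat (first flow frame at the
#' QRS trigger, 10 ms before the QRS peak), computes the distortion as the
#' per-lead absolute difference between the isocenter and home-position
#' averaged beats after vertical alignment, and returns the timing of peak
#' flow relative to the J point and of peak distortion relative to peak
#' flow.
#'
#' @param flow a `flow_curve`.
#' @param iso_ab,home_ab `averaged_beat` objects (isocenter and home).
#' @param marks `interval_marks` in the home beat's window coordinates,
#'   with `qrs_peak_ms` set.
#' @return named numeric `c(flow_peak_after_j_ms, dist_peak_after_flow_ms)`.
#' @export
flow_distortion_timing <- function(flow, iso_ab, home_ab, marks) {
  stopifnot(inherits(flow, "flow_curve"))
  if (is.null(marks$qrs_peak_ms)) {
    stop("marks must carry qrs_peak_ms to register the flow curve")
  }
  cc <- crop_common(iso_ab, home_ab, marks)
  iso <- cc$test; home <- cc$ref; marks <- cc$marks
  fs <- home$fs
  n <- nrow(home$mean)
  dist <- matrix(0, n, ncol(home$mean))
  for (k in seq_len(ncol(home$mean))) {
    off <- vertical_offset(iso$mean[, k], home$mean[, k], marks, fs)
    dist[, k] <- abs(iso$mean[, k] - off - home$mean[, k])
  }
  if (max(dist) < 1e-9) stop("no measurable distortion between beats")
  i_max <- unname(which(dist == max(dist), arr.ind = TRUE)[1, "row"])
  t_dist <- (i_max - 1) * 1000 / fs
  t_flow <- flow$time_ms + (marks$qrs_peak_ms - 10)
  t_flow_peak <- t_flow[which.max(flow$flow)]
  c(flow_peak_after_j_ms = t_flow_peak - marks$j_ms,
    dist_peak_after_flow_ms = t_dist - t_flow_peak)
}
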