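#' Interval marks for an averaged or windowed heartbeat
#'
#' Fiducial points used to split a beat into clinically interpreted
#' intervals. All times are milliseconds relative to the start of the beat
#' window (0 ms = first sample). The derived quantities are the first-third
#' QRS boundary, `qrs_onset + (j - qrs_onset)/3`, used as the right edge of
#' the vertical-alignment window, and the ST window `[j, j + 80)` ms used
#' for ischemic ST assessment.
#'
#' @param p_onset_ms onset of the P wave.
#' @param qrs_onset_ms onset of the QRS complex.
#' @param j_ms the J point (end of the QRS complex).
#' @param t_end_ms end of the T wave.
#' @param qrs_peak_ms optional position of the QRS peak within the window;
#'   required by operations that register other signals (e.g. an aortic
#'   flow curve) against the beat.
#' @return an object of class `interval_marks`.
#' @export
interval_marks <- function(p_onset_ms, qrs_onset_ms, j_ms, t_end_ms,
                           qrs_peak_ms = NULL) {
  vals <- c(p_onset_ms = p_onset_ms, qrs_onset_ms = qrs_onset_ms,
            j_ms = j_ms, t_end_ms = t_end_ms)
  if (any(!is.finite(vals))) {
    stop("interval marks must be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  bad <- character(0)
  if (!(p_onset_ms < qrs_onset_ms)) bad <- c(bad, "p_onset_ms >= qrs_onset_ms")
  if (!(qrs_onset_ms < j_ms)) bad <- c(bad, "qrs_onset_ms >= j_ms")
  if (!(j_ms < t_end_ms)) bad <- c(bad, "j_ms >= t_end_ms")
  if (length(bad)) {
    stop("interval mark ordering violated: ", paste(bad, collapse = "; "))
  }
  m <- list(p_onset_ms = p_onset_ms, qrs_onset_ms = qrs_onset_ms,
            j_ms = j_ms, t_end_ms = t_end_ms, qrs_peak_ms = qrs_peak_ms)
  class(m) <- "interval_marks"
  m
}

#' @rdname interval_marks
#' @param marks an `interval_marks` object.
#' @export
qrs_first_third <- function(marks) {
  marks$qrs_onset_ms + (marks$j_ms - marks$qrs_onset_ms) / 3
}

#' @rdname interval_marks
#' @export
st_window <- function(marks) {
  c(marks$j_ms, marks$j_ms + 80)
}

#' Shift interval marks by a fixed time offset
#'
#' @param marks an `interval_marks` object.
#' @param by_ms offset added to every mark (ms).
#' @return shifted `interval_marks`.
#' @export
shift_marks <- function(marks, by_ms) {
  interval_marks(marks$p_onset_ms + by_ms, marks$qrs_onset_ms + by_ms,
                 marks$j_ms + by_ms, marks$t_end_ms + by_ms,
                 qrs_peak_ms = if (is.null(marks$qrs_peak_ms)) NULL
                               else marks$qrs_peak_ms + by_ms)
}

#' @export
print.interval_marks <- function(x, ...) {
  cat(sprintf(
    "interval marks (ms): P onset %.1f | QRS onset %.1f | J %.1f | T end %.1f\n",
    x$p_onset_ms, x$qrs_onset_ms, x$j_ms, x$t_end_ms))
  if (!is.null(x$qrs_peak_ms)) {
    cat(sprintf("  QRS peak at %.1f ms; ST window [%.1f, %.1f) ms\n",
                x$qrs_peak_ms, st_window(x)[1], st_window(x)[2]))
  }
  invisible(x)
}
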