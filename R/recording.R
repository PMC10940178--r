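#' Multi-lead ECG recording container
#'
#' @param signals numeric matrix, samples x 12 leads (mV); column names
#'   must be the 12 standard leads.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param meta list of acquisition context: `subject`, `location` (one of
#'   outside, home, isocenter), `field_t` (nominal static field, tesla) and
#'   anything else worth carrying (e.g. the generator seed).
#' @return object of class `multi_lead_recording`.
#' @export
multi_lead_recording <- function(signals, sampling_rate, meta = list()) {
  leads <- ecg_leads()
  if (is.null(colnames(signals)) || !setequal(colnames(signals), leads)) {
    missing <- setdiff(leads, colnames(signals))
    stop("recording must contain exactly the 12 standard leads",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")))
  }
  signals <- signals[, leads, drop = FALSE]
  if (anyNA(signals)) stop("recording contains missing samples")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling rate must be positive")
  }
  if (!is.null(meta$location) &&
      !meta$location %in% c("outside", "home", "isocenter")) {
    stop("location must be one of outside, home, isocenter")
  }
  structure(list(signals = signals, fs = sampling_rate, meta = meta),
            class = "multi_lead_recording")
}

#' @export
print.multi_lead_recording <- function(x, ...) {
  cat(sprintf("12-lead ECG recording: %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), x$fs, nrow(x$signals) / x$fs))
  if (length(x$meta)) {
    cat(sprintf("  subject=%s location=%s field=%s T\n",
                x$meta$subject %||% "?", x$meta$location %||% "?",
                x$meta$field_t %||% "?"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of the nominal static field experienced at each table location
#'
#' Outside the scanner room the field is negligible; at table home position
#' the subject sits in the decaying fringe field; at isocenter the full
#' nominal field applies.
#'
#' @param location one of `"outside"`, `"home"`, `"isocenter"`.
#' @param fringe_fraction fraction of the nominal field at home position.
#' @return numeric scalar in \[0, 1\].
#' @export
location_field_factor <- function(location, fringe_fraction = 0.15) {
  switch(location,
         outside = 0,
         home = fringe_fraction,
         isocenter = 1,
         stop("unknown location: ", location))
}
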