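#' Magnetohydrodynamic (MHD) distortion model
#'
#' Blood flowing through the scanner's static field induces a voltage (the
#' MHD effect) superimposed on the surface ECG, largest during systolic
#' aortic flow. The model is deliberately simple: the per-beat MHD trace on
#' each lead is a lag-shifted copy of the (unit-peak normalised) aortic
#' flow curve, scaled by a per-lead coupling coefficient and linearly by
#' the static field strength. Default timing follows observed physiology:
#' peak aortic flow 114 ms after the J point, peak ECG distortion 29 ms
#' after peak aortic flow.
#'
#' @param field_t static field strength in tesla (>= 0).
#' @param coupling named numeric, mV of distortion per unit normalised flow
#'   at 1 T, for the independent leads. Lateral leads default to larger
#'   couplings (leads roughly perpendicular to aortic-arch flow pick up the
#'   most MHD voltage).
#' @param lag_ms delay of peak distortion after peak flow (ms).
#' @param flow_delay_ms delay of peak flow after the J point (ms).
#' @return an object of class `mhd_model`.
#' @export
mhd_model <- function(field_t = 0.55,
                      coupling = c(I = 0.30, II = 0.15, V1 = 0.10,
                                   V2 = 0.12, V3 = 0.15, V4 = 0.18,
                                   V5 = 0.22, V6 = 0.25),
                      lag_ms = 29, flow_delay_ms = 114) {
  if (!is.finite(field_t) || field_t < 0) {
    stop("field strength must be finite and non-negative")
  }
  if (!all(is.finite(c(lag_ms, flow_delay_ms)))) {
    stop("lag and flow delay must be finite")
  }
  cpl <- stats::setNames(numeric(length(independent_leads())),
                         independent_leads())
  cpl[names(coupling)] <- coupling
  structure(list(field_t = field_t, coupling = cpl, lag_ms = lag_ms,
                 flow_delay_ms = flow_delay_ms),
            class = "mhd_model")
}

#' Generate a per-beat aortic flow curve
#'
#' Emulates a phase-contrast flow measurement: 30 frames per heartbeat,
#' first frame at the QRS trigger (10 ms before the QRS peak), a single
#' unimodal non-negative pulse whose peak falls `flow_delay_ms` after the
#' J point, scaled so the flow integral over the beat equals a configured
#' stroke volume.
#'
#' @param model an `mhd_model` (supplies `flow_delay_ms`).
#' @param marks `interval_marks` with `qrs_peak_ms` set (window
#'   coordinates).
#' @param heart_rate heart rate in bpm; sets the beat length (R-R).
#' @param stroke_volume flow integral over the beat (arbitrary units).
#' @param width_ms Gaussian width (sigma) of the flow pulse.
#' @param frames number of flow frames per heartbeat.
#' @return object of class `flow_curve`: list with `time_ms` (ms from the
#'   QRS trigger), `flow` (non-negative), `frame_ms`.
#' @export
generate_flow_curve <- function(model, marks, heart_rate,
                                stroke_volume = 70, width_ms = 60,
                                frames = 30) {
  stopifnot(inherits(model, "mhd_model"), inherits(marks, "interval_marks"))
  if (is.null(marks$qrs_peak_ms)) {
    stop("marks must carry qrs_peak_ms to register the flow trigger")
  }
  rr_ms <- 60000 / heart_rate
  frame_ms <- rr_ms / frames
  time_ms <- seq(0, by = frame_ms, length.out = frames)
  # trigger = QRS peak - 10 ms, so the J point sits at (j - peak) + 10 ms
  j_rel_trigger <- (marks$j_ms - marks$qrs_peak_ms) + 10
  peak_t <- j_rel_trigger + model$flow_delay_ms
  if (peak_t > max(time_ms)) {
    stop("flow-peak delay places the peak beyond the beat window")
  }
  flow <- exp(-(time_ms - peak_t)^2 / (2 * width_ms^2))
  # trapezoidal integral -> stroke volume (flow units * ms)
  integ <- sum(diff(time_ms) * (flow[-1] + flow[-length(flow)]) / 2)
  flow <- flow * stroke_volume / integ
  structure(list(time_ms = time_ms, flow = flow, frame_ms = frame_ms,
                 peak_time_ms = peak_t),
            class = "flow_curve")
}

#' Generate the per-beat additive MHD distortion trace for one lead
#'
#' The trace is the flow curve normalised to unit peak, shifted later in
#' time by the model lag, and scaled by `coupling[lead] * field_t`. The
#' derived limb leads get the trace implied by the lead identities applied
#' to the I and II traces.
#'
#' @param flow a `flow_curve`.
#' @param model an `mhd_model`.
#' @param lead lead name.
#' @param sampling_rate ECG sampling rate (Hz) for the output trace.
#' @param window ms relative to the QRS peak, as in [render_beat()].
#' @return numeric trace (mV) with attribute `t_ms`.
#' @export
generate_mhd_distortion <- function(flow, model, lead, sampling_rate = 1000,
                                    window = c(-400, 700)) {
  stopifnot(inherits(flow, "flow_curve"), inherits(model, "mhd_model"))
  if (model$field_t < 0) stop("field strength must be non-negative")
  t_ms <- seq(window[1], window[2], by = 1000 / sampling_rate)
  if (lead %in% derived_leads()) {
    I <- generate_mhd_distortion(flow, model, "I", sampling_rate, window)
    II <- generate_mhd_distortion(flow, model, "II", sampling_rate, window)
    x <- derive_limb_leads(as.numeric(I), as.numeric(II))[[lead]]
    attr(x, "t_ms") <- t_ms
    return(x)
  }
  if (!lead %in% independent_leads()) stop("unknown lead name: ", lead)
  fn <- flow$flow / max(flow$flow)
  # flow time is ms from the trigger (QRS peak - 10 ms); convert to ms
  # relative to the QRS peak, then delay by the distortion lag
  src_t <- flow$time_ms - 10 + model$lag_ms
  y <- stats::approx(src_t, fn, xout = t_ms, rule = 1)$y
  y[is.na(y)] <- 0
  x <- model$coupling[[lead]] * model$field_t * y
  attr(x, "t_ms") <- t_ms
  x
}
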