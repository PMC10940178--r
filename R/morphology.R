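#' Sum-of-Gaussians beat morphology for the eight independent leads
#'
#' A heartbeat is modelled per lead as a sum of Gaussian wave components
#' (P, Q, R, S, T), each with a centre (ms relative to the QRS peak), an
#' amplitude (mV) and a width (the Gaussian sigma, ms). Morphologies are
#' defined on the eight independent leads (I, II, V1--V6); the remaining
#' limb leads are rendered through the Einthoven/Goldberger identities.
#'
#' The object also carries the beat's ground-truth fiducial marks relative
#' to the QRS peak and an optional per-lead ST deviation (an injected
#' J-point shift emulating ischemia; see [inject_st_deviation()]).
#'
#' @param components named list over independent leads; each element a
#'   `data.frame` with columns `label` (one of P, Q, R, S, T), `center_ms`,
#'   `amplitude_mv`, `width_ms`.
#' @param marks_rel named numeric with `p_onset`, `qrs_onset`, `j`, `t_end`
#'   in ms relative to the QRS peak.
#' @param st_dev named numeric of injected J-point deviations (mV) per
#'   independent lead; default all zero.
#' @return an object of class `lead_morphology`.
#' @export
lead_morphology <- function(components, marks_rel, st_dev = NULL) {
  indep <- independent_leads()
  if (!all(names(components) %in% indep)) {
    stop("morphology components defined for unknown leads: ",
         paste(setdiff(names(components), indep), collapse = ", "))
  }
  wave_order <- c(P = 1, Q = 2, R = 3, S = 4, T = 5)
  for (ld in names(components)) {
    cmp <- components[[ld]]
    if (nrow(cmp) == 0) next
    if (any(cmp$width_ms <= 0)) {
      stop("component widths must be strictly positive (lead ", ld, ")")
    }
    o <- order(wave_order[cmp$label])
    cc <- cmp$center_ms[o]
    if (is.unsorted(cc)) {
      stop("component centers must be ordered P < Q <= R <= S < T (lead ",
           ld, ")")
    }
  }
  need <- c("p_onset", "qrs_onset", "j", "t_end")
  if (!all(need %in% names(marks_rel))) {
    stop("marks_rel must name ", paste(need, collapse = ", "))
  }
  sd0 <- stats::setNames(numeric(length(indep)), indep)
  if (!is.null(st_dev)) sd0[names(st_dev)] <- st_dev
  structure(list(components = components, marks_rel = marks_rel,
                 st_dev = sd0),
            class = "lead_morphology")
}

#' Default human-like 12-lead beat morphology
#'
#' Typical adult amplitudes and timings; QRS peak at 0 ms. Ground-truth
#' marks place P onset at -220 ms, QRS onset at -45 ms, the J point at
#' +50 ms and T end at +395 ms relative to the QRS peak.
#'
#' @param amplitude_scale overall multiplicative scale applied to every
#'   component amplitude (emulates between-subject amplitude variation).
#' @return a `lead_morphology`.
#' @export
default_morphology <- function(amplitude_scale = 1) {
  mk <- function(p, q, r, s, t) {
    data.frame(
      label = c("P", "Q", "R", "S", "T"),
      center_ms = c(-170, -25, 0, 25, 280),
      amplitude_mv = amplitude_scale * c(p, q, r, s, t),
      width_ms = c(20, 7, 11, 8, 45),
      stringsAsFactors = FALSE
    )
  }
  comps <- list(
    I  = mk(0.08, -0.05, 0.70, -0.15, 0.25),
    II = mk(0.12, -0.08, 1.10, -0.20, 0.35),
    V1 = mk(0.05, -0.02, 0.25, -0.80, 0.08),
    V2 = mk(0.06, -0.02, 0.50, -0.70, 0.25),
    V3 = mk(0.07, -0.03, 0.80, -0.45, 0.30),
    V4 = mk(0.08, -0.05, 1.20, -0.30, 0.35),
    V5 = mk(0.08, -0.06, 1.00, -0.20, 0.30),
    V6 = mk(0.07, -0.06, 0.80, -0.15, 0.25)
  )
  lead_morphology(comps,
                  marks_rel = c(p_onset = -220, qrs_onset = -45,
                                j = 50, t_end = 395))
}

#' Default premature-ventricular-complex morphology
#'
#' A wide, inverted-polarity QRS with discordant T wave and no P wave,
#' derived from a sinus morphology so PVC beats remain separable from sinus
#' beats by QRS cross-correlation.
#'
#' @param base the sinus `lead_morphology` to derive amplitudes from.
#' @return a `lead_morphology`.
#' @export
pvc_morphology <- function(base = default_morphology()) {
  comps <- lapply(base$components, function(cmp) {
    r_amp <- cmp$amplitude_mv[cmp$label == "R"]
    t_amp <- cmp$amplitude_mv[cmp$label == "T"]
    data.frame(
      label = c("R", "T"),
      center_ms = c(0, 310),
      amplitude_mv = c(-1.2 * r_amp, -0.8 * t_amp),
      width_ms = c(26, 55),
      stringsAsFactors = FALSE
    )
  })
  lead_morphology(comps, marks_rel = base$marks_rel)
}

# smoothed ST-deviation waveform: 0 before QRS onset, raised-cosine ramp to
# exactly `dev` at the J point, raised-cosine decay back to 0 at T end
st_component <- function(t_ms, dev, marks_rel) {
  if (dev == 0) return(numeric(length(t_ms)))
  q <- marks_rel[["qrs_onset"]]
  j <- marks_rel[["j"]]
  te <- marks_rel[["t_end"]]
  out <- numeric(length(t_ms))
  ramp <- t_ms > q & t_ms < j
  out[ramp] <- dev * (1 - cos(pi * (t_ms[ramp] - q) / (j - q))) / 2
  decay <- t_ms >= j & t_ms <= te
  out[decay] <- dev * (1 + cos(pi * (t_ms[decay] - j) / (te - j))) / 2
  out
}

#' Render one heartbeat for a given lead
#'
#' Evaluates the sum of Gaussian components (plus any injected ST-deviation
#' waveform) on a uniform sample grid. The derived limb leads III, aVR, aVL
#' and aVF are computed from the rendered leads I and II.
#'
#' @param morphology a `lead_morphology`.
#' @param lead lead name (any of the 12 standard leads).
#' @param sampling_rate sampling rate in Hz.
#' @param window length-2 numeric, window in ms relative to the QRS peak
#'   (`c(pre, post)`, pre usually negative); samples are taken at
#'   `seq(window[1], window[2], by = 1000/sampling_rate)`.
#' @return numeric waveform (mV) with attribute `t_ms` (sample times).
#' @export
render_beat <- function(morphology, lead, sampling_rate = 1000,
                        window = c(-400, 700)) {
  stopifnot(inherits(morphology, "lead_morphology"), sampling_rate > 0)
  t_ms <- seq(window[1], window[2], by = 1000 / sampling_rate)
  if (lead %in% derived_leads()) {
    I <- render_beat(morphology, "I", sampling_rate, window)
    II <- render_beat(morphology, "II", sampling_rate, window)
    x <- derive_limb_leads(as.numeric(I), as.numeric(II))[[lead]]
    attr(x, "t_ms") <- t_ms
    return(x)
  }
  if (!lead %in% independent_leads()) {
    stop("unknown lead name: ", lead)
  }
  cmp <- morphology$components[[lead]]
  x <- numeric(length(t_ms))
  if (is.null(cmp) || nrow(cmp) == 0) {
    warning("empty morphology for lead ", lead, "; rendering zero waveform")
  } else {
    for (k in seq_len(nrow(cmp))) {
      x <- x + cmp$amplitude_mv[k] *
        exp(-(t_ms - cmp$center_ms[k])^2 / (2 * cmp$width_ms[k]^2))
    }
  }
  x <- x + st_component(t_ms, morphology$st_dev[[lead]], morphology$marks_rel)
  attr(x, "t_ms") <- t_ms
  x
}

#' Inject an ischemic ST (J-point) deviation into a morphology
#'
#' Adds a smoothed-step deviation anchored at the J point: zero before QRS
#' onset, exactly `deviation` mV at the J point, decaying smoothly to zero
#' by T end. Injection is only defined on the eight independent leads; the
#' derived limb leads change according to the lead identities.
#'
#' @param morphology a `lead_morphology`.
#' @param lead an independent lead name.
#' @param deviation J-point shift in mV (signed, finite).
#' @return the modified `lead_morphology`.
#' @export
inject_st_deviation <- function(morphology, lead, deviation) {
  stopifnot(inherits(morphology, "lead_morphology"))
  if (!is.finite(deviation)) stop("deviation must be finite")
  if (lead %in% derived_leads()) {
    stop("cannot inject on derived lead ", lead,
         "; inject on independent leads only")
  }
  if (!lead %in% independent_leads()) stop("unknown lead name: ", lead)
  morphology$st_dev[[lead]] <- morphology$st_dev[[lead]] + deviation
  morphology
}
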