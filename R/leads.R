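#' Standard 12-lead ECG lead names
#'
#' Lead order used throughout the package: limb leads I, II, III, the
#' augmented leads aVR, aVL, aVF, and precordial leads V1--V6. Eight of
#' these are electrically independent; III, aVR, aVL and aVF are linear
#' combinations of I and II (Einthoven/Goldberger relations).
#'
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @rdname ecg_leads
#' @export
independent_leads <- function() {
  c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @rdname ecg_leads
#' @export
derived_leads <- function() {
  c("III", "aVR", "aVL", "aVF")
}

#' Compute the derived limb leads from leads I and II
#'
#' Applies the Einthoven and Goldberger identities:
#' III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2.
#'
#' @param I,II numeric vectors (mV), equal length.
#' @return named list with elements `III`, `aVR`, `aVL`, `aVF`.
#' @export
derive_limb_leads <- function(I, II) {
  stopifnot(length(I) == length(II))
  list(
    III = II - I,
    aVR = -(I + II) / 2,
    aVL = I - II / 2,
    aVF = II - I / 2
  )
}

#' Anatomically contiguous lead groups
#'
#' Groups of leads viewing the same myocardial territory, used both by the
#' contiguous-lead ischemia rule and by lead-group error summaries. aVR
#' belongs to no group.
#'
#' @return named list of character vectors.
#' @export
lead_groups <- function() {
  list(
    lateral  = c("I", "aVL", "V5", "V6"),
    inferior = c("II", "III", "aVF"),
    septal   = c("V1", "V2"),
    anterior = c("V3", "V4")
  )
}

# ms (relative to window start, 0 ms = first sample) -> 1-based sample index
ms_idx <- function(ms, fs) {
  as.integer(round(ms * fs / 1000)) + 1L
}

# half-open [from, to) interval of sample indices, clipped to [1, n]
idx_range <- function(from_ms, to_ms, fs, n) {
  i0 <- max(1L, ms_idx(from_ms, fs))
  i1 <- min(n, ms_idx(to_ms, fs) - 1L)
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1)
}
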