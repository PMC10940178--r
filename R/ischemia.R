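#' Per-lead ST (J-point) deviation from the TP baseline
#'
#' The primary ECG marker of myocardial ischemia: the signed difference
#' between the averaged beat's value at the J point and the TP-baseline
#' estimate, per lead. The TP baseline is the mean over the electrically
#' quiet window from the window start to 10 ms before P onset.
#'
#' @param beat an `averaged_beat`.
#' @param marks `interval_marks` in the beat's window coordinates.
#' @return named numeric over the 12 leads (mV, signed), class
#'   `st_deviation_map`.
#' @export
st_deviation <- function(beat, marks) {
  fs <- beat$fs
  base_end <- marks$p_onset_ms - 10
  idx <- idx_range(0, base_end, fs, nrow(beat$mean))
  if (length(idx) == 0) {
    stop("insufficient TP baseline: P onset too close to the window start")
  }
  j_idx <- ms_idx(marks$j_ms, fs)
  dev <- beat$mean[j_idx, ] - colMeans(beat$mean[idx, , drop = FALSE])
  structure(dev, class = "st_deviation_map")
}

#' Contiguous-lead ischemia rule
#'
#' The ECG is called ischemic when at least two leads within one anatomic
#' group (anatomically contiguous leads) both show a J-point deviation of
#' at least the threshold. aVR participates in no group.
#'
#' @param devs named numeric of per-lead J-point deviations (mV), e.g. an
#'   `st_deviation_map`.
#' @param groups contiguity groups, see [lead_groups()].
#' @param threshold_mv deviation threshold (default 0.1 mV, > 0).
#' @param elevation_only if `TRUE`, only positive deviations (ST elevation)
#'   qualify; default uses absolute deviation.
#' @return object of class `ischemia_call`: list with `ischemic` flag,
#'   `pairs` (data.frame of qualifying lead pairs) and `threshold_mv`.
#' @export
classify_ischemia <- function(devs, groups = lead_groups(),
                              threshold_mv = 0.1,
                              elevation_only = FALSE) {
  if (threshold_mv <= 0) stop("threshold must be positive")
  mag <- if (elevation_only) as.numeric(devs) else abs(as.numeric(devs))
  names(mag) <- names(devs)
  pairs <- list()
  for (g in names(groups)) {
    leads <- intersect(groups[[g]], names(mag))
    hot <- leads[mag[leads] >= threshold_mv]
    if (length(hot) >= 2) {
      cmb <- utils::combn(hot, 2)
      for (k in seq_len(ncol(cmb))) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          group = g, lead_a = cmb[1, k], lead_b = cmb[2, k],
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(group = character(0), lead_a = character(0),
                           lead_b = character(0), stringsAsFactors = FALSE)
  structure(list(ischemic = nrow(pairs) > 0, pairs = pairs,
                 threshold_mv = threshold_mv,
                 elevation_only = elevation_only),
            class = "ischemia_call")
}

#' Representative error per anatomic lead group
#'
#' For every unordered pair of leads within a group the pair's value is the
#' smaller of the two lead errors (a single hot lead never represents a
#' group, mirroring the two-contiguous-leads rule); the group value is the
#' maximum over its pairs.
#'
#' @param errors named numeric of per-lead errors (>= 0).
#' @param groups contiguity groups, see [lead_groups()].
#' @return named numeric, one value per group.
#' @export
pair_group_error <- function(errors, groups = lead_groups()) {
  out <- stats::setNames(numeric(length(groups)), names(groups))
  for (g in names(groups)) {
    leads <- groups[[g]]
    if (!all(leads %in% names(errors))) {
      stop("errors missing for leads ",
           paste(setdiff(leads, names(errors)), collapse = ", "),
           " in group ", g)
    }
    if (length(leads) < 2) stop("group ", g, " has fewer than 2 leads")
    v <- sort(as.numeric(errors[leads]), decreasing = TRUE)
    # max over pairs of pairwise minima = second-largest value
    out[g] <- v[2]
  }
  out
}
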