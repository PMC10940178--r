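#' Write a 12-lead recording to a delimited waveform file
#'
#' Dialect: line 1 is the tab-separated lead names; line 2 is the metadata
#' line of `key=value` pairs (must include `sampling_rate_hz` and
#' `units=mV`); every following line is one sample, tab-separated, in the
#' lead order of line 1. Values are written with enough digits for an
#' exact round trip.
#'
#' @param recording a `multi_lead_recording`.
#' @param path output file path.
#' @export
write_recording <- function(recording, path) {
  meta <- recording$meta
  meta_line <- paste(c(
    sprintf("sampling_rate_hz=%.10g", recording$fs),
    "units=mV",
    if (!is.null(meta$subject)) sprintf("subject=%s", meta$subject),
    if (!is.null(meta$location)) sprintf("location=%s", meta$location),
    if (!is.null(meta$field_t)) sprintf("field_t=%.10g", meta$field_t),
    if (!is.null(meta$seed)) sprintf("seed=%d", as.integer(meta$seed))
  ), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(recording$signals), collapse = "\t"), con)
  writeLines(meta_line, con)
  rows <- apply(recording$signals, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(rows, con)
}

parse_kv <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  stats::setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' Read a 12-lead recording from a delimited waveform file
#'
#' @param path input file path (see [write_recording()] for the format).
#' @return a `multi_lead_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- readLines(path, n = 2)
  if (length(header) < 2) stop("truncated waveform file: ", path)
  leads <- strsplit(header[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(ecg_leads(), leads)
  if (length(missing)) {
    stop("waveform file missing lead(s): ", paste(missing, collapse = ", "))
  }
  kv <- parse_kv(header[2])
  if (!"sampling_rate_hz" %in% names(kv)) {
    stop("waveform file does not declare sampling_rate_hz")
  }
  if (!identical(unname(kv["units"]), "mV")) {
    stop("waveform units must be mV")
  }
  fs <- as.numeric(kv[["sampling_rate_hz"]])
  dat <- tryCatch(
    utils::read.table(path, skip = 2, sep = "\t", header = FALSE,
                      col.names = leads, colClasses = "numeric"),
    error = function(e) stop("non-uniform sample rows in ", path, ": ",
                             conditionMessage(e)))
  meta <- list()
  for (k in c("subject", "location")) {
    if (k %in% names(kv)) meta[[k]] <- unname(kv[[k]])
  }
  if ("field_t" %in% names(kv)) meta$field_t <- as.numeric(kv[["field_t"]])
  if ("seed" %in% names(kv)) meta$seed <- as.integer(kv[["seed"]])
  multi_lead_recording(as.matrix(dat), fs, meta)
}

#' Write / read interval-mark annotation files
#'
#' Annotation files hold one `key=value` pair per line with keys
#' `p_onset_ms`, `qrs_onset_ms`, `j_ms`, `t_end_ms` and optionally
#' `qrs_peak_ms`; all values are milliseconds from the beat-window start.
#' Reading validates the mark ordering and reports which fields offend.
#'
#' @param marks an `interval_marks`.
#' @param path file path.
#' @return `read_marks()` returns an `interval_marks`.
#' @export
write_marks <- function(marks, path) {
  lines <- c(sprintf("p_onset_ms=%.10g", marks$p_onset_ms),
             sprintf("qrs_onset_ms=%.10g", marks$qrs_onset_ms),
             sprintf("j_ms=%.10g", marks$j_ms),
             sprintf("t_end_ms=%.10g", marks$t_end_ms))
  if (!is.null(marks$qrs_peak_ms)) {
    lines <- c(lines, sprintf("qrs_peak_ms=%.10g", marks$qrs_peak_ms))
  }
  writeLines(lines, path)
}

#' @rdname write_marks
#' @export
read_marks <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  kv <- parse_kv(paste(readLines(path), collapse = "\t"))
  need <- c("p_onset_ms", "qrs_onset_ms", "j_ms", "t_end_ms")
  if (!all(need %in% names(kv))) {
    stop("annotation file missing field(s): ",
         paste(setdiff(need, names(kv)), collapse = ", "))
  }
  interval_marks(as.numeric(kv[["p_onset_ms"]]),
                 as.numeric(kv[["qrs_onset_ms"]]),
                 as.numeric(kv[["j_ms"]]),
                 as.numeric(kv[["t_end_ms"]]),
                 qrs_peak_ms = if ("qrs_peak_ms" %in% names(kv))
                   as.numeric(kv[["qrs_peak_ms"]]) else NULL)
}

#' Write / read simulator ground truth as a sidecar text file
#'
#' Key=value header (seed, fiducials relative to the QRS peak, injected
#' ST deviations) followed by a tab-separated beat table (`beat_ms`,
#' `label`).
#'
#' @param truth ground-truth list from [generate_recording()].
#' @param path file path.
#' @return `read_ground_truth()` returns the ground-truth list (without
#'   the waveform-sized elements).
#' @export
write_ground_truth <- function(truth, path) {
  hdr <- c(sprintf("seed=%d", as.integer(truth$seed)),
           sprintf("marks_rel=%s",
                   paste(sprintf("%s:%.10g", names(truth$marks_rel),
                                 truth$marks_rel), collapse = ",")),
           sprintf("st_injection=%s",
                   paste(sprintf("%s:%.10g", names(truth$st_injection),
                                 truth$st_injection), collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("beat_ms\tlabel", con)
  writeLines(sprintf("%.10g\t%s", truth$beat_ms, truth$labels), con)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  tab_at <- which(lines == "beat_ms\tlabel")
  kv <- parse_kv(paste(lines[seq_len(tab_at - 1)], collapse = "\t"))
  parse_named <- function(s) {
    if (identical(s, "")) return(stats::setNames(numeric(0), character(0)))
    items <- strsplit(s, ",", fixed = TRUE)[[1]]
    kvp <- strsplit(items, ":", fixed = TRUE)
    stats::setNames(vapply(kvp, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kvp, `[`, character(1), 1))
  }
  beats <- utils::read.table(path, skip = tab_at, sep = "\t",
                             col.names = c("beat_ms", "label"))
  list(seed = as.integer(kv[["seed"]]),
       marks_rel = parse_named(kv[["marks_rel"]]),
       st_injection = parse_named(kv[["st_injection"]]),
       beat_ms = beats$beat_ms, labels = as.character(beats$label))
}

#' Write / read an averaged beat as a delimited table
#'
#' Line 1: metadata `key=value` pairs (`sampling_rate_hz`, `n_beats`,
#' `pre`, `post`); line 2: column names (`<lead>.mean`, `<lead>.sd`); then
#' one row per sample.
#'
#' @param beat an `averaged_beat`.
#' @param path file path.
#' @return `read_averaged_beat()` returns an `averaged_beat`.
#' @export
write_averaged_beat <- function(beat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "sampling_rate_hz=%.10g\tn_beats=%d\tpre=%d\tpost=%d",
    beat$fs, beat$n, beat$pre, beat$post), con)
  cols <- c(paste0(colnames(beat$mean), ".mean"),
            paste0(colnames(beat$sd), ".sd"))
  writeLines(paste(cols, collapse = "\t"), con)
  m <- cbind(beat$mean, beat$sd)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
}

#' @rdname write_averaged_beat
#' @export
read_averaged_beat <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  kv <- parse_kv(readLines(path, n = 1))
  dat <- utils::read.table(path, skip = 1, sep = "\t", header = TRUE,
                           check.names = FALSE)
  leads <- sub("\\.mean$", "", grep("\\.mean$", names(dat), value = TRUE))
  mu <- as.matrix(dat[, paste0(leads, ".mean")])
  sdm <- as.matrix(dat[, paste0(leads, ".sd")])
  colnames(mu) <- leads; colnames(sdm) <- leads
  averaged_beat(mu, sdm, n = as.integer(kv[["n_beats"]]),
                pre = as.integer(kv[["pre"]]),
                post = as.integer(kv[["post"]]),
                fs = as.numeric(kv[["sampling_rate_hz"]]))
}

#' Read a study configuration from a YAML file
#'
#' Schema: `subjects` (list of `id`/`seed`), `conditions` (list of
#' `location`/`field_t`), optional `simulator` (overrides for
#' [synthetic_config()] fields), optional `pipeline` (overrides for
#' [process_recording()] parameters) and optional `output_dir`.
#'
#' @param path YAML file path.
#' @return a study-config list for [run_study()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$subjects) || is.null(cfg$conditions)) {
    stop("study config must declare subjects and conditions")
  }
  for (s in cfg$subjects) {
    if (is.null(s$seed)) stop("every subject needs a seed (subject ",
                              s$id %||% "?", ")")
  }
  cfg
}
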