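# shared fixtures: all generated in code, no files

# quiet generator: no jitter, no respiration, no noise, no field
quiet_config <- function(...) {
  args <- list(duration_s = 20, rr_jitter_sd_ms = 0, resp_baseline_mv = 0,
               resp_mhd_frac = 0, noise_sd_mv = 0, pvc_prob = 0,
               location = "outside", field_t = 0, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# standard marks for the default morphology in a window with the QRS peak
# at `pre_ms` (window coordinates)
default_marks <- function(pre_ms = 260) {
  mr <- default_morphology()$marks_rel
  interval_marks(pre_ms + mr[["p_onset"]], pre_ms + mr[["qrs_onset"]],
                 pre_ms + mr[["j"]], pre_ms + mr[["t_end"]],
                 qrs_peak_ms = pre_ms)
}

# wrap one per-lead waveform matrix (or a single vector replicated across
# leads) into an averaged_beat for metric tests
as_avg_beat <- function(x, pre, fs = 1000, sd = NULL, n = 10) {
  if (is.null(dim(x))) {
    x <- matrix(rep(x, 12), ncol = 12, dimnames = list(NULL, ecg_leads()))
  }
  if (is.null(sd)) sd <- matrix(0, nrow(x), ncol(x),
                                dimnames = dimnames(x))
  averaged_beat(x, sd, n = n, pre = pre, post = nrow(x) - pre, fs = fs)
}

# render the default morphology into a 12-lead averaged beat with the QRS
# peak at sample pre+1
rendered_avg_beat <- function(morph = default_morphology(), pre_ms = 260,
                              post_ms = 700, fs = 1000) {
  m <- sapply(ecg_leads(), function(ld)
    as.numeric(render_beat(morph, ld, fs, c(-pre_ms, post_ms))))
  as_avg_beat(m, pre = as.integer(pre_ms * fs / 1000), fs = fs)
}

# injected deviations on independent leads -> implied 12-lead deviations
injection_on_12_leads <- function(inj) {
  full <- stats::setNames(numeric(8), independent_leads())
  full[names(inj)] <- inj
  dl <- derive_limb_leads(full[["I"]], full[["II"]])
  out <- c(I = full[["I"]], II = full[["II"]], III = dl$III, aVR = dl$aVR,
           aVL = dl$aVL, aVF = dl$aVF,
           full[c("V1", "V2", "V3", "V4", "V5", "V6")])
  out[ecg_leads()]
}

# generate + process an occlusion recording; returns measured and injected
# 12-lead J-point deviations (unfiltered average: diagnostic bandwidth)
occlusion_run <- function(seed, location = "outside", field_t = 0,
                          duration_s = 120) {
  set.seed(seed)
  inj <- stats::setNames(round(stats::runif(8, -0.4, 0.4), 3),
                         independent_leads())
  cfg <- synthetic_config(duration_s = duration_s, seed = seed + 100,
                          location = location, field_t = field_t,
                          st_injection = as.list(inj))
  g <- generate_recording(cfg)
  p <- process_recording(g$recording, g$truth$marks_rel, truth = g$truth,
                         filter_band = NULL)
  list(measured = as.numeric(st_deviation(p$averaged, p$marks)),
       injected = as.numeric(injection_on_12_leads(inj)))
}
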