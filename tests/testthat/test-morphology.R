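test_that("rendering is the closed-form Gaussian sum", {
  comps <- list(II = data.frame(
    label = c("R", "T"), center_ms = c(0, 300),
    amplitude_mv = c(1.0, 0.3), width_ms = c(10, 40)))
  m <- lead_morphology(comps, marks_rel = c(p_onset = -200, qrs_onset = -40,
                                            j = 40, t_end = 420))
  w <- render_beat(m, "II", 1000, c(-400, 600))
  t_ms <- attr(w, "t_ms")

  # peak of a single dominant Gaussian sits at its centre sample
  expect_equal(t_ms[which.max(w)], 0)

  # closed-form two-Gaussian oracle at both centres
  oracle <- function(t) 1.0 * exp(-t^2 / (2 * 10^2)) +
    0.3 * exp(-(t - 300)^2 / (2 * 40^2))
  expect_equal(w[t_ms == 0], oracle(0), tolerance = 1e-6)
  expect_equal(w[t_ms == 300], oracle(300), tolerance = 1e-6)

  # single-component peak amplitude
  comps1 <- list(II = data.frame(label = "R", center_ms = 0,
                                 amplitude_mv = 1.0, width_ms = 10))
  m1 <- lead_morphology(comps1, marks_rel = m$marks_rel)
  w1 <- render_beat(m1, "II", 1000, c(-100, 100))
  expect_equal(max(w1), 1.0)
  expect_equal(attr(w1, "t_ms")[which.max(w1)], 0)
})

test_that("empty morphology renders zero with a warning; bad leads error", {
  m <- lead_morphology(list(II = data.frame(label = character(0),
                                            center_ms = numeric(0),
                                            amplitude_mv = numeric(0),
                                            width_ms = numeric(0))),
                       marks_rel = c(p_onset = -200, qrs_onset = -40,
                                     j = 40, t_end = 420))
  expect_warning(w <- render_beat(m, "II", 1000, c(-50, 50)),
                 "empty morphology")
  expect_true(all(w == 0))
  expect_error(render_beat(m, "X7", 1000, c(-50, 50)), "unknown lead")
})

test_that("morphology invariants are enforced", {
  bad_width <- list(II = data.frame(label = "R", center_ms = 0,
                                    amplitude_mv = 1, width_ms = -1))
  expect_error(lead_morphology(bad_width,
                               c(p_onset = -200, qrs_onset = -40,
                                 j = 40, t_end = 420)),
               "strictly positive")
  bad_order <- list(II = data.frame(label = c("P", "R"),
                                    center_ms = c(10, 0),
                                    amplitude_mv = c(0.1, 1),
                                    width_ms = c(20, 10)))
  expect_error(lead_morphology(bad_order,
                               c(p_onset = -200, qrs_onset = -40,
                                 j = 40, t_end = 420)),
               "ordered")
})

test_that("derived limb leads obey the lead identities when rendered", {
  morph <- default_morphology()
  fs <- 1000; win <- c(-260, 700)
  I <- as.numeric(render_beat(morph, "I", fs, win))
  II <- as.numeric(render_beat(morph, "II", fs, win))
  for (ld in derived_leads()) {
    got <- as.numeric(render_beat(morph, ld, fs, win))
    want <- derive_limb_leads(I, II)[[ld]]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ST injection shifts the J sample exactly and leaves baseline", {
  morph <- default_morphology()
  fs <- 1000; win <- c(-260, 700)
  j_rel <- morph$marks_rel[["j"]]
  t_ms <- attr(render_beat(morph, "II", fs, win), "t_ms")
  j_at <- which(t_ms == j_rel)

  # zero deviation is the identity
  m0 <- inject_st_deviation(morph, "II", 0)
  expect_identical(as.numeric(render_beat(m0, "II", fs, win)),
                   as.numeric(render_beat(morph, "II", fs, win)))

  # +0.20 mV on II: J sample of II rises by exactly 0.20; derived leads
  # respond per the identities (III += 0.2, aVF += 0.2, aVL -= 0.1)
  m2 <- inject_st_deviation(morph, "II", 0.20)
  for (ld in c("II", "III", "aVF", "aVL", "aVR")) {
    base <- as.numeric(render_beat(morph, ld, fs, win))[j_at]
    new <- as.numeric(render_beat(m2, ld, fs, win))[j_at]
    want <- c(II = 0.2, III = 0.2, aVF = 0.2, aVL = -0.1, aVR = -0.1)[ld]
    expect_equal(new - base, unname(want), tolerance = 1e-12)
  }

  # -0.15 mV on V3: J falls by 0.15; pre-P baseline untouched
  m3 <- inject_st_deviation(morph, "V3", -0.15)
  v3_old <- as.numeric(render_beat(morph, "V3", fs, win))
  v3_new <- as.numeric(render_beat(m3, "V3", fs, win))
  expect_equal(v3_new[j_at] - v3_old[j_at], -0.15, tolerance = 1e-12)
  pre_p <- t_ms < morph$marks_rel[["p_onset"]]
  expect_lt(max(abs(v3_new[pre_p] - v3_old[pre_p])), 1e-6)

  expect_error(inject_st_deviation(morph, "aVF", 0.1), "derived lead")
  expect_error(inject_st_deviation(morph, "II", NaN), "finite")
})
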