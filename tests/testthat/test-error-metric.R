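# compact geometry for waveform-level metric tests: 1000 Hz, window 500 ms,
# P onset 40, QRS onset 190, J 285, T end 450
mk <- interval_marks(40, 190, 285, 450, qrs_peak_ms = 235)
fs <- 1000

test_that("vertical offset is the L1 median over the alignment window", {
  n <- 500
  ref <- sin(seq(0, 3, length.out = n)) * 0.2
  expect_equal(vertical_offset(ref, ref, mk, fs), 0)
  expect_equal(vertical_offset(ref + 0.5, ref, mk, fs), 0.5)

  # pointwise differences {0.1,0.1,0.1,0.4,0.4} over a 5-sample window
  mk5 <- interval_marks(0, 4, 7, 10)  # alignment window [0, 5) ms
  ref5 <- numeric(12)
  test5 <- c(0.1, 0.1, 0.1, 0.4, 0.4, rep(0, 7))
  off <- vertical_offset(test5, ref5, mk5, fs)
  expect_equal(off, 0.1)
  # brute-force grid-search oracle over candidate offsets
  grid <- seq(-0.5, 0.5, by = 1e-4)
  obj <- vapply(grid, function(o) sum(abs(test5[1:5] - o - ref5[1:5])),
                numeric(1))
  expect_lte(sum(abs(test5[1:5] - off - ref5[1:5])), min(obj) + 1e-12)

  expect_error(vertical_offset(ref5, ref5,
                               interval_marks(-50, -10, 7, 10), fs),
               "empty vertical-alignment window")
})

test_that("L1 offset matches brute-force grid search on random pairs", {
  set.seed(101)
  for (k in 1:100) {
    n <- 400
    ref <- cumsum(rnorm(n, 0, 0.02))
    test <- ref + rnorm(1, 0, 0.3) + rnorm(n, 0, 0.05)
    off <- vertical_offset(test, ref, mk, fs)
    win <- idx_range(mk$p_onset_ms, qrs_first_third(mk), fs, n)
    d <- test[win] - ref[win]
    grid <- seq(min(d), max(d), length.out = 2001)
    obj <- vapply(grid, function(o) sum(abs(d - o)), numeric(1))
    expect_lte(sum(abs(d - off)), min(obj) + 1e-10)
  }
})

test_that("QRS truncation clips sign-aware at the reference extremum", {
  n <- 500
  ref <- numeric(n)
  qrs <- 191:285
  ref[qrs] <- sin(seq(0, pi, length.out = length(qrs)))  # peak 1.0 mV
  test <- 1.04 * ref

  tr <- truncate_qrs_peak(test, ref, mk, fraction = 0.05, fs = fs)
  expect_equal(max(tr$ref[qrs]), 0.95)
  # clip bound applied by hand: both waveforms meet at the bound, so the
  # post-clipping difference at the peak sample is exactly 0
  pk <- qrs[which.max(ref[qrs])]
  expect_equal(tr$test[pk] - tr$ref[pk], 0)
  # samples outside the QRS untouched
  expect_identical(tr$test[-(191:285)], test[-(191:285)])

  # fraction 0 is the identity
  tr0 <- truncate_qrs_peak(test, ref, mk, fraction = 0, fs = fs)
  expect_identical(tr0$test, test)
  expect_identical(tr0$ref, ref)

  # negative-extremum reference clips toward the negative side
  trn <- truncate_qrs_peak(-test, -ref, mk, fraction = 0.05, fs = fs)
  expect_equal(min(trn$ref[qrs]), -0.95)

  expect_warning(truncate_qrs_peak(test, numeric(n), mk, 0.05, fs),
                 "flat QRS")
  expect_error(truncate_qrs_peak(test, ref, mk, fraction = 0.6, fs = fs),
               "fraction")
})

test_that("pointwise error takes the minimum difference within the
           tolerance", {
  n <- 500
  ref <- 0.8 * exp(-(seq_len(n) - 235)^2 / (2 * 11^2)) +
    0.25 * exp(-(seq_len(n) - 380)^2 / (2 * 30^2))
  expect_identical(pointwise_error(ref, ref, 5, fs), numeric(n))

  # 3-ms delay is absorbed: exhaustive search oracle
  delayed <- c(numeric(3), ref[1:(n - 3)])
  e <- pointwise_error(delayed, ref, 5, fs)
  expect_lt(max(e[10:(n - 10)]), 0.01 * max(ref))
  # oracle: for each t the minimum over shifts is <= the |delta|=3 match
  expect_true(all(e <= abs(delayed - ref) + 1e-15))

  # a flat offset on a flat reference is unaffected by the time search
  flat <- rep(0.3, n)
  e2 <- pointwise_error(flat + 0.1, flat, 5, fs)
  expect_equal(e2, rep(0.1, n))
  # on a curved reference the search can only reduce the error (delta = 0
  # is always a candidate)
  e2c <- pointwise_error(ref + 0.1, ref, 5, fs)
  expect_true(all(e2c <= 0.1 + 1e-15))

  # tolerance 0 is the plain absolute difference
  test <- ref + rnorm(n, 0, 0.05)
  expect_identical(pointwise_error(test, ref, 0, fs), abs(test - ref))

  expect_error(pointwise_error(ref, ref, 600, fs), "tolerance")
})

test_that("error metric is a premetric with the stated invariances", {
  beat <- rendered_avg_beat()
  marks <- default_marks(260)
  settings <- alignment_settings()

  rep0 <- compute_error_report(beat, beat, marks, settings)
  expect_true(all(rep0$per_lead$max_error == 0))
  expect_true(all(rep0$j_point$error == 0))

  # DC offset invariance
  shifted <- beat
  shifted$mean <- shifted$mean + 0.25
  repdc <- compute_error_report(shifted, beat, marks, settings)
  expect_lt(max(repdc$per_lead$max_error), 1e-12)

  # time shifts <= 5 ms absorbed within 1% of QRS amplitude
  lagged <- beat
  lagged$mean <- rbind(matrix(0, 5, 12), beat$mean[1:(nrow(beat$mean) - 5), ])
  colnames(lagged$mean) <- colnames(beat$mean)
  replag <- compute_error_report(lagged, beat, marks, settings)
  qrs_amp <- max(abs(beat$mean[, "II"]))
  expect_lt(max(replag$per_lead$max_error), 0.01 * qrs_amp)

  expect_true(all(rep0$per_lead$max_error >= 0))
})

test_that("interval error report recovers an injected ST-confined trace", {
  beat <- rendered_avg_beat()
  marks <- default_marks(260)
  fs <- 1000
  n <- nrow(beat$mean)
  t_ms <- (seq_len(n) - 1)

  # known MHD-like bump confined to [J+20, T end]: peak 0.3 mV at
  # J + 143 ms with the aortic-flow pulse width (sigma 60 ms)
  center <- marks$j_ms + 143
  bump <- 0.3 * exp(-(t_ms - center)^2 / (2 * 60^2))
  bump[t_ms < marks$j_ms + 20 | t_ms > marks$t_end_ms] <- 0
  test <- beat
  test$mean <- beat$mean + bump

  rep <- compute_error_report(test, beat, marks)
  st_idx <- idx_range(marks$j_ms, marks$j_ms + 80, fs, n)
  want <- max(bump[st_idx])
  got <- rep$summary$max_error[rep$summary$interval == "ST"]
  expect_lt(abs(got - want) / want, 0.10)
  pr <- rep$summary$max_error[rep$summary$interval == "PR"]
  expect_lt(pr, 0.03)

  # J-point error <= ST error for every lead (J is one point of the ST max)
  st_lead <- rep$per_lead[rep$per_lead$interval == "ST", ]
  expect_true(all(rep$j_point$error <=
                    st_lead$max_error[match(rep$j_point$lead,
                                            st_lead$lead)] + 1e-12))
})

test_that("an injected J-point step is recovered at the J sample", {
  # construction oracle: a morphology whose QRS has fully decayed at the J
  # point, so the reference is locally flat there and the error trace at J
  # reads the injected step directly
  mk_nar <- function(p, q, r, s, t) data.frame(
    label = c("P", "Q", "R", "S", "T"),
    center_ms = c(-170, -20, 0, 18, 280),
    amplitude_mv = c(p, q, r, s, t),
    width_ms = c(20, 5, 9, 5, 45), stringsAsFactors = FALSE)
  comps <- stats::setNames(lapply(seq_len(8), function(i) {
    s <- 0.7 + 0.08 * i  # distinct amplitudes so derived leads are not flat
    mk_nar(0.1 * s, -0.05 * s, 1.0 * s, -0.2 * s, 0.3 * s)
  }), independent_leads())
  morph <- lead_morphology(comps, marks_rel = c(p_onset = -220,
                                                qrs_onset = -45, j = 50,
                                                t_end = 395))
  ref <- rendered_avg_beat(morph)
  test <- rendered_avg_beat(inject_st_deviation(morph, "V4", 0.12))
  marks <- default_marks(260)
  rep <- compute_error_report(test, ref, marks)
  expect_equal(rep$j_point$error[rep$j_point$lead == "V4"], 0.12,
               tolerance = 0.01 / 0.12)
})

test_that("beats with different windows are compared over the overlap", {
  beat <- rendered_avg_beat()
  short <- rendered_avg_beat(post_ms = 350)
  marks <- default_marks(260)
  # T end (655 ms) exceeds the common window (610 ms) -> error
  expect_error(compute_error_report(short, beat, marks), "outside")
  marks2 <- interval_marks(40, 215, 310, 550, qrs_peak_ms = 260)
  rep <- compute_error_report(short, beat, marks2)
  expect_lt(max(rep$per_lead$max_error), 1e-12)
})
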