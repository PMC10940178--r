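test_that("ST deviation reads the J value against the TP baseline", {
  marks <- default_marks(260)
  n <- 960
  flat <- matrix(0, n, 12, dimnames = list(NULL, ecg_leads()))
  j_idx <- round(marks$j_ms) + 1
  flat[j_idx, ] <- 0.2
  beat <- as_avg_beat(flat, pre = 260)
  dev <- st_deviation(beat, marks)
  expect_equal(unname(unclass(dev)), rep(0.2, 12))

  # a constant added to the whole beat cancels in the baseline
  beat2 <- beat
  beat2$mean <- beat2$mean + 0.3
  dev2 <- st_deviation(beat2, marks)
  expect_equal(unclass(dev2), unclass(dev), tolerance = 1e-12)

  # P onset too close to the window start
  early <- interval_marks(5, 215, 310, 655)
  expect_error(st_deviation(beat, early), "insufficient TP baseline")
})

test_that("simulator-injected deviations are recovered with MHD off", {
  inj <- c(II = 0.15, V3 = -0.12)
  cfg <- quiet_config(duration_s = 30, noise_sd_mv = 0.01, seed = 5,
                      st_injection = as.list(inj))
  g <- generate_recording(cfg)
  p <- process_recording(g$recording, g$truth$marks_rel, truth = g$truth,
                         threshold_mv = 0.7, filter_band = NULL)
  dev <- st_deviation(p$averaged, p$marks)
  want <- injection_on_12_leads(inj)
  expect_lt(max(abs(as.numeric(dev) - as.numeric(want))), 0.02)
})

test_that("ischemia rule matches the contiguous-pair definition", {
  base <- stats::setNames(numeric(12), ecg_leads())

  d1 <- base; d1["II"] <- 0.12; d1["aVF"] <- 0.11
  c1 <- classify_ischemia(d1)
  expect_true(c1$ischemic)
  expect_true(all(c1$pairs$group == "inferior"))

  d2 <- base; d2["V3"] <- 0.25
  expect_false(classify_ischemia(d2)$ischemic)

  expect_false(classify_ischemia(base)$ischemic)

  # negative deviations count unless elevation_only
  d3 <- base; d3["V1"] <- -0.15; d3["V2"] <- -0.2
  expect_true(classify_ischemia(d3)$ischemic)
  expect_false(classify_ischemia(d3, elevation_only = TRUE)$ischemic)

  # aVR participates in no group
  d4 <- base; d4["aVR"] <- 0.5; d4["I"] <- 0.5
  expect_false(classify_ischemia(d4)$ischemic)

  expect_error(classify_ischemia(base, threshold_mv = 0), "positive")
})

test_that("ischemia rule agrees with brute-force pair enumeration", {
  groups <- lead_groups()
  brute <- function(devs, thr) {
    for (g in names(groups)) {
      leads <- groups[[g]]
      for (a in seq_along(leads)) for (b in seq_along(leads)) {
        if (a < b && abs(devs[[leads[a]]]) >= thr &&
            abs(devs[[leads[b]]]) >= thr) return(TRUE)
      }
    }
    FALSE
  }
  set.seed(77)
  agree <- vapply(1:2000, function(k) {
    devs <- stats::setNames(round(stats::rnorm(12, 0, 0.12), 3),
                            ecg_leads())
    identical(classify_ischemia(devs)$ischemic, brute(devs, 0.1))
  }, logical(1))
  expect_true(all(agree))
})

test_that("lead-group error takes the max over pairwise minima", {
  groups <- lead_groups()
  err <- stats::setNames(numeric(12), ecg_leads())
  err[c("II", "III", "aVF")] <- c(0.5, 0.1, 0.3)
  # pairs: min(II,III)=0.1, min(II,aVF)=0.3, min(III,aVF)=0.1 -> max 0.3
  expect_equal(pair_group_error(err, groups)[["inferior"]], 0.3)

  err2 <- err; err2[c("V1", "V2")] <- 0.2
  expect_equal(pair_group_error(err2, groups)[["septal"]], 0.2)

  err3 <- stats::setNames(numeric(12), ecg_leads())
  err3["I"] <- 1.0
  expect_equal(pair_group_error(err3, groups)[["lateral"]], 0.0)

  # brute-force enumeration oracle + permutation invariance + monotonicity
  set.seed(31)
  brute_group <- function(vals) {
    best <- -Inf
    for (a in seq_along(vals)) for (b in seq_along(vals)) {
      if (a < b) best <- max(best, min(vals[a], vals[b]))
    }
    best
  }
  ok <- vapply(1:200, function(k) {
    e <- stats::setNames(round(stats::runif(12, 0, 1), 3), ecg_leads())
    got <- pair_group_error(e, groups)
    oracle_ok <- all(vapply(names(groups), function(g)
      isTRUE(all.equal(got[[g]], brute_group(as.numeric(e[groups[[g]]])))),
      logical(1)))
    # permuting leads within groups changes nothing
    e2 <- e
    e2[groups$lateral] <- e[sample(groups$lateral)]
    perm_ok <- pair_group_error(e2, groups)[["lateral"]] == got[["lateral"]]
    # raising any one lead never decreases any group value
    e3 <- e
    bump_lead <- sample(ecg_leads(), 1)
    e3[bump_lead] <- e3[bump_lead] + 0.5
    mono_ok <- all(pair_group_error(e3, groups) >= got - 1e-12)
    oracle_ok && perm_ok && mono_ok
  }, logical(1))
  expect_true(all(ok))

  expect_error(pair_group_error(err[1:3], groups), "missing")
  expect_error(pair_group_error(err, list(solo = "II")), "fewer than 2")
})
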