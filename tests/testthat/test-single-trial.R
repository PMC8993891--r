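# Single-trial detector: persistence rule, metric extraction, test
# calibration, ground-truth recovery.

test_that("enforce_min_run keeps 50-ms runs and clears 49-ms runs", {
  m <- logical(300)
  m[101:149] <- TRUE                       # 49 samples = 49 ms
  expect_false(any(enforce_min_run(m, 50, 1)))
  m2 <- logical(300)
  m2[101:150] <- TRUE                      # 50 samples = 50 ms
  expect_identical(enforce_min_run(m2, 50, 1), m2)
  expect_identical(enforce_min_run(logical(0)), logical(0))
  # runs broken by NA (invalid) timepoints
  m3 <- logical(300)
  m3[101:200] <- TRUE
  m3[150] <- NA
  out <- enforce_min_run(m3, 50, 1)
  expect_true(all(out[151:200]))           # 50-ms fragment kept
  expect_false(any(out[101:149]))          # 49-ms fragment cleared
  # on a 2-ms grid, 25 samples = 50 ms are kept
  m4 <- logical(100); m4[11:35] <- TRUE
  expect_identical(enforce_min_run(m4, 50, 2), m4)
  m5 <- logical(100); m5[11:34] <- TRUE
  expect_false(any(enforce_min_run(m5, 50, 2)))
})

test_that("extract_metrics follows the metric definitions", {
  tm <- 0:1000
  trace <- rep(0.2, 1001)
  trace[tm %in% 300:600] <- 3
  trace[tm == 420] <- 3.1
  mask <- tm >= 300 & tm <= 600
  m <- extract_metrics(mask, trace, tm, rt_ms = 900)
  expect_true(m$has_activation)
  expect_equal(m$onset_ms, 300)
  expect_equal(m$offset_ms, 600)
  expect_equal(m$duration_ms, 301)
  expect_equal(m$peak_ms, 420)
  expect_equal(m$peak_power_z, 3.1)
  # two runs accumulate duration; onset/offset span both
  mask2 <- (tm >= 300 & tm <= 360) | (tm >= 500 & tm <= 580)
  m2 <- extract_metrics(mask2, trace, tm, rt_ms = 900)
  expect_equal(m2$onset_ms, 300)
  expect_equal(m2$offset_ms, 580)
  expect_equal(m2$duration_ms, 61 + 81)
  # peak ties break to the earliest timepoint
  tr3 <- rep(0, 1001); tr3[tm %in% c(350, 450)] <- 2
  m3 <- extract_metrics(tm >= 300 & tm <= 500, tr3, tm, rt_ms = 900)
  expect_equal(m3$peak_ms, 350)
  # empty mask: fallback peak power over valid [0, rt]
  tr4 <- rep(0, 1001); tr4[tm == 150] <- 0.4; tr4[tm == 950] <- 9
  m4 <- extract_metrics(rep(FALSE, 1001), tr4, tm, rt_ms = 900)
  expect_false(m4$has_activation)
  expect_true(is.na(m4$onset_ms) && is.na(m4$duration_ms))
  expect_equal(m4$peak_power_z, 0.4)       # the 9 at 950 ms is past RT
})

test_that("sliding-window p-values are calibrated on independent noise", {
  # iid gaussian HFB (no smoothing): correction factors ~ 1, p ~ uniform
  ep <- synthetic_epochs(function(n, onsets) rnorm(n), n_trials = 20,
                         rt_ms = 1500, smooth_ms = 1, seed = 31)
  ps <- unlist(lapply(1:20, function(j)
    sliding_window_pvals(ep, 1, j)$p))
  expect_gt(length(ps), 10000)
  # near-uniform: the shared kappa estimate adds a little per-site
  # miscalibration noise, so allow a modest band around the nominal rate
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.06)
})

test_that("a +3 z step yields tiny p-values throughout the step", {
  ep <- synthetic_epochs(function(n, onsets) {
    x <- rnorm(n, 0, 0.25)
    for (s in onsets) x[(s + 300):(s + 599)] <- x[(s + 300):(s + 599)] + 3
    x
  }, n_trials = 5, rt_ms = 1500, smooth_ms = 50, seed = 32)
  for (j in 1:5) {
    pw <- sliding_window_pvals(ep, 1, j)
    tm <- ep$time_ms[pw$time_idx]
    expect_true(all(pw$p[tm >= 315 & tm <= 585] < 1e-4))
    expect_true(all(pw$t[tm >= 315 & tm <= 585] > 0))
  }
  # all-invalid trial -> empty result
  ep$valid[1, 1, ep$time_ms >= 0] <- FALSE
  expect_equal(nrow(sliding_window_pvals(ep, 1, 1)), 0)
})

test_that("detector recovers injected bursts on the single-burst fixture", {
  run <- single_burst_run()
  mt <- run$metrics[run$metrics$site_id == "P01_s01", ]
  expect_true(all(mt$has_activation))
  err <- mt$onset_ms - 300
  expect_lte(median(abs(err)), 40)
  # window + persistence can delay, smoothing can slightly lead
  expect_true(median(err) > -30 && median(err) < 60)
  expect_lte(median(abs(mt$duration_ms - 400)) / 400, 0.15)
  # offsets never exceed rt + 200 (masking invariant)
  expect_true(all(mt$offset_ms <= mt$rt_ms + 200))
  # null channels stay quiet
  null_mt <- run$metrics[run$metrics$roi == "none", ]
  expect_lt(mean(null_mt$has_activation), 0.05)
})

test_that("detector output is deterministic given the same epochs", {
  run <- single_burst_run()
  again <- run_single_trial(run$epochs)
  expect_identical(run$metrics, again)
})

test_that("increasing burst amplitude never shortens detected duration", {
  mk <- function(a) {
    bs <- transform(default_burst_spec(), active_probability = 0)
    sel <- bs$roi == "TPJ" & bs$condition == "self"
    bs$active_probability[sel] <- 1
    bs$onset_mean[sel] <- 300; bs$onset_sd[sel] <- 0
    bs$duration_mean[sel] <- 400; bs$duration_sd[sel] <- 0
    bs$amplitude[sel] <- a
    cfg <- sim_config(n_participants = 1,
                      sites_per_roi = c(TPJ = 1, none = 5),
                      trials_per_condition = c(self = 15),
                      burst_spec = bs,
                      artifacts = list(p_hfo = 0, p_no_response = 0,
                                       p_irrelevant = 0),
                      inter_trial_gap_ms = 6500, seed = 77)
    ses <- simulate_session(cfg, "P01")   # same seed: matched noise draws
    ep <- preprocess_session(ses, mask_outliers = FALSE)
    mt <- run_single_trial(ep)
    mt$duration_ms[mt$site_id == "P01_s01"]
  }
  d2 <- mk(2); d3 <- mk(3)
  d2[is.na(d2)] <- 0; d3[is.na(d3)] <- 0
  expect_gte(median(d3), median(d2))
})
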