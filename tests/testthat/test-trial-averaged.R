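# Trial-averaged estimation, labeling, time-window summaries, grand
# averages.

test_that("per-timepoint estimate equals the mixed model's beta (oracle)", {
  # small stacked fit: baseline pool + one dummy per timepoint, per-trial
  # random intercept; its fixed effect must equal the paired estimate
  set.seed(41)
  n_tr <- 12; n_base <- 30
  base <- matrix(rnorm(n_tr * n_base, 0, 1), n_tr)
  tp <- rnorm(n_tr, 0.8, 1) + rowMeans(base)   # trial offsets shared
  # center each trial the way the pipeline does (baseline correction)
  bmeans <- rowMeans(base)
  basec <- base - bmeans
  tpc <- tp - bmeans
  ours <- mean(tpc)
  df_ <- data.frame(
    y = c(as.vector(t(basec)), tpc),
    dummy = rep(c(0, 1), c(n_tr * n_base, n_tr)),
    trial = c(rep(seq_len(n_tr), each = n_base), seq_len(n_tr)))
  fit <- lme4::lmer(y ~ dummy + (1 | trial), data = df_, REML = TRUE)
  expect_equal(unname(lme4::fixef(fit)["dummy"]), ours, tolerance = 1e-6)
})

test_that("fit_site_timecourse recovers a constructed mean shift", {
  ep <- synthetic_epochs(function(n, onsets) {
    x <- rnorm(n, 0, 0.4)
    for (s in onsets) x[(s + 300):(s + 799)] <- x[(s + 300):(s + 799)] + 1
    x
  }, n_trials = 20, rt_ms = 2000, smooth_ms = 50, seed = 42)
  tc <- fit_site_timecourse(ep, 1, "self", step_ms = 2)
  inwin <- tc$time_ms >= 320 & tc$time_ms <= 780
  expect_true(mean(tc$beta[inwin]) > 0.8 && mean(tc$beta[inwin]) < 1.2)
  # too few trials -> NULL with warning
  ep4 <- synthetic_epochs(function(n, onsets) rnorm(n), n_trials = 4,
                          smooth_ms = 1, seed = 43)
  expect_warning(out <- fit_site_timecourse(ep4, 1, "self"), "skipped")
  expect_null(out)
})

test_that("null epochs produce no labeled responses", {
  ep <- synthetic_epochs(function(n, onsets) rnorm(n, 0, 0.4),
                         n_trials = 20, n_sites = 4, rt_ms = 2000,
                         smooth_ms = 50, seed = 44)
  out <- site_response_labels(ep, conditions = "self")
  expect_true(all(out$labels$label == "nonresponsive"))
})

test_that("label_response covers the full sign truth table", {
  est <- function(beta, sig) data.frame(beta = beta, sig = sig)
  expect_equal(label_response(NULL), "nonresponsive")
  expect_equal(label_response(est(c(1, 2), c(FALSE, FALSE))),
               "nonresponsive")
  expect_equal(label_response(est(c(1, 2), c(TRUE, TRUE))), "active")
  expect_equal(label_response(est(c(-1, -2), c(TRUE, TRUE))), "deactive")
  # mixed polarity: greatest |beta| decides
  expect_equal(label_response(est(c(-3, 2), c(TRUE, TRUE))), "deactive")
  expect_equal(label_response(est(c(-2, 3), c(TRUE, TRUE))), "active")
  expect_equal(label_response(est(c(-3, 2), c(FALSE, TRUE))), "active")
})

test_that("time-window summary localises a burst to its window", {
  ep <- synthetic_epochs(function(n, onsets) {
    x <- rnorm(n, 0, 0.4)
    for (s in onsets) x[(s + 300):(s + 599)] <- x[(s + 300):(s + 599)] + 2
    x
  }, n_trials = 15, rt_ms = 2500, smooth_ms = 50, seed = 45)
  out <- time_window_summary(ep, conditions = "self")
  w25 <- out[out$win_start == 250, ]
  w1000 <- out[out$win_start == 1000, ]
  expect_true(w25$sig); expect_gt(w25$t, 0)
  expect_false(w1000$sig)
  # null epochs: significant fraction < 5%
  epn <- synthetic_epochs(function(n, onsets) rnorm(n, 0, 0.4),
                          n_trials = 15, n_sites = 6, rt_ms = 2500,
                          smooth_ms = 50, seed = 46)
  outn <- time_window_summary(epn, conditions = "self")
  expect_lt(mean(outn$sig), 0.05)
  # windows fully masked -> no test, flagged as NA
  epm <- synthetic_epochs(function(n, onsets) rnorm(n, 0, 0.4),
                          n_trials = 15, rt_ms = 600, smooth_ms = 1,
                          seed = 47)
  outm <- time_window_summary(epm, conditions = "self")
  expect_true(is.na(outm$t[outm$win_start == 1000]))
  expect_error(time_window_summary(ep, windows = list(c(4000, 6000))),
               "beyond epoch")
})

test_that("grand averages pool sites sensibly", {
  mk <- function(seed) synthetic_epochs(function(n, onsets) {
    x <- rnorm(n, 0, 0.4)
    for (s in onsets) x[(s + 300):(s + 899)] <- x[(s + 300):(s + 899)] + 1.5
    x
  }, n_trials = 15, rt_ms = 2500, smooth_ms = 50, seed = seed)
  ep1 <- mk(48)
  lab1 <- data.frame(site_id = "S01", roi = "TPJ", participant_id = "P01",
                     condition = "self", label = "active",
                     stringsAsFactors = FALSE)
  g1 <- grand_average_roi(list(list(epochs = ep1, labels = lab1)),
                          "TPJ", "self", step_ms = 100, t_max = 2000)
  tc1 <- fit_site_timecourse(ep1, 1, "self", step_ms = 100)
  inwin <- g1$time_ms >= 400 & g1$time_ms <= 800
  ref <- tc1$beta[match(g1$time_ms, tc1$time_ms)]
  expect_true(all(abs(g1$beta[inwin] - ref[inwin]) <=
                    2 * tc1$se[match(g1$time_ms, tc1$time_ms)][inwin] + 1e-9))
  # duplicated site: same beta, smaller or equal SE
  ep2 <- ep1
  d2 <- c(2, dim(ep1$hfb)[2], dim(ep1$hfb)[3])
  ep2$hfb <- array(NA_real_, d2)
  ep2$valid <- array(TRUE, d2)
  for (s in 1:2) {
    ep2$hfb[s, , ] <- ep1$hfb[1, , ]
    ep2$valid[s, , ] <- ep1$valid[1, , ]
  }
  ep2$channels <- rbind(ep1$channels, ep1$channels)
  ep2$channels$site_id <- c("S01", "S02")
  lab2 <- rbind(lab1, transform(lab1, site_id = "S02"))
  g2 <- grand_average_roi(list(list(epochs = ep2, labels = lab2)),
                          "TPJ", "self", step_ms = 100, t_max = 2000)
  expect_equal(g2$beta[inwin], g1$beta[inwin], tolerance = 1e-6)
  expect_true(all(g2$se[inwin] <= g1$se[inwin] + 1e-9))
})
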