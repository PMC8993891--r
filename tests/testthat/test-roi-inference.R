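# ROI-level mixed models: outlier filtering, type/RT/choice effects,
# pairwise comparisons, logistic classification, second-level models.

make_profiles <- function(sites, roi = "dmPFC") {
  data.frame(site_id = sites, roi = roi, participant_id = "P01",
             mentalizing = "active", stringsAsFactors = FALSE)
}

sim_table <- function(...) {
  d <- simulate_roi_metrics(...)
  d$participant_id <- d$participant
  d$condition <- ifelse(d$type > 0, "self", "other")
  d$type_os <- -d$type
  d$choice_tf <- d$choice
  d$onset_ms <- d$value
  d
}

test_that("outlier filter keeps clean data and drops a junk site", {
  set.seed(61)
  d <- sim_table(n_participants = 2, sites_per_participant = 3,
                 trials_per_site = 60, b_rt = 0.2, sigma = 80, seed = 61)
  d$peak_ms <- d$offset_ms <- d$duration_ms <- d$peak_power_z <- NA
  prof <- make_profiles(unique(d$site_id))
  out <- multisite_outlier_filter(d, prof)
  expect_length(out$excluded_sites, 0)
  dropped <- mean(is.na(out$data$onset_ms))
  expect_lt(dropped, 0.02)
  # a site whose metric is junk relative to the ROI trend gets excluded
  d2 <- d
  bad <- d2$site_id == d2$site_id[1]
  d2$onset_ms[bad] <- sample(c(-1, 1), sum(bad), TRUE) *
    runif(sum(bad), 5000, 9000)
  out2 <- multisite_outlier_filter(d2, prof)
  expect_true(d2$site_id[1] %in% out2$excluded_sites)
  # rt > 5000 removed up front; empty input passes through
  d3 <- d; d3$rt_ms <- 6000
  out3 <- multisite_outlier_filter(d3, prof)
  expect_equal(nrow(out3$data), 0)
})

test_that("fit_roi_type_rt_choice recovers generator fixed effects", {
  d <- sim_table(n_participants = 3, sites_per_participant = 4,
                 trials_per_site = 60, b_type = 100, b_rt = 0.3,
                 b_choice = -40, sigma = 120, seed = 62)
  fit <- fit_roi_type_rt_choice(d, "dmPFC", "onset")
  eff <- fit$effects
  b_type <- eff[eff$name == "Type_Other-Self", ]
  # generator type coded +1/2 self: value = ... + 100*type, so
  # Other-Self = -100
  expect_lt(abs(b_type$b - (-100)), 2 * b_type$se)
  b_rt <- eff[eff$name == "RT_Behav", ]
  expect_lt(abs(b_rt$b - 0.3), 2 * b_rt$se)
  b_ch <- eff[eff$name == "Choice_True-False", ]
  expect_lt(abs(b_ch$b - (-40)), 2 * b_ch$se)
  expect_equal(nrow(fit$site_effects), 12)
  expect_true(all(is.finite(fit$site_effects$b_rt)))
})

test_that("VD covariates are inert when the generator has none", {
  d <- sim_table(n_participants = 2, sites_per_participant = 4,
                 trials_per_site = 60, b_type = 80, b_vd1 = 0, sigma = 100,
                 seed = 63)
  d$vd1 <- rnorm(nrow(d)); d$vd2 <- rnorm(nrow(d))
  f1 <- fit_roi_type_rt_choice(d, "dmPFC", "onset", include_vd = TRUE)
  f0 <- fit_roi_type_rt_choice(d, "dmPFC", "onset", include_vd = FALSE)
  b1 <- f1$effects[f1$effects$name == "Type_Other-Self", ]
  b0 <- f0$effects[f0$effects$name == "Type_Other-Self", ]
  expect_lt(abs(b1$b - b0$b), 0.1 * b1$se)
})

test_that("pairwise ROI comparisons are antisymmetric and self-zero", {
  d <- sim_table(n_participants = 2, sites_per_participant = 2,
                 trials_per_site = 40, seed = 64)
  d$roi <- ifelse(d$site_id %in% unique(d$site_id)[c(1, 3)], "TPJ", "PMC")
  d$onset_ms <- d$value + ifelse(d$roi == "PMC", 150, 0)
  self <- pairwise_roi_latency(d, "TPJ", "TPJ", "onset")
  expect_equal(self$b, 0)
  xy <- pairwise_roi_latency(d, "PMC", "TPJ", "onset")
  yx <- pairwise_roi_latency(d, "TPJ", "PMC", "onset")
  expect_equal(xy$b, -yx$b, tolerance = 1e-6)
  expect_equal(xy$se, yx$se, tolerance = 1e-6)
  expect_lt(abs(xy$b - 150), 3 * xy$se)
  # no shared participants -> NULL
  d2 <- d
  d2$participant_id[d2$roi == "TPJ"] <- "P01"
  d2$participant_id[d2$roi == "PMC"] <- "P02"
  expect_null(pairwise_roi_latency(d2, "TPJ", "PMC", "onset"))
})

test_that("onset-specificity logistic model recovers the generator slope", {
  set.seed(65)
  n <- 240
  st <- data.frame(
    participant_id = sample(sprintf("P%02d", 1:4), n, TRUE),
    onset_mean = runif(n, 100, 700))
  p <- plogis(0.014 * (st$onset_mean - 400))
  st$specific <- runif(n) < p
  fit <- onset_predicts_specificity(st)
  expect_lt(abs(fit$effect$b - 0.014), 2 * fit$effect$se)
  expect_equal(fit$effect$or_value, exp(fit$effect$b), tolerance = 1e-12)
  expect_false(fit$separation)
  # shuffled labels: OR ~ 1
  st2 <- st; st2$specific <- sample(st$specific)
  fit2 <- onset_predicts_specificity(st2)
  expect_lt(abs(fit2$effect$b), 2.5 * fit2$effect$se)
  expect_lt(abs(fit2$effect$or_value - 1), 0.05)
  # one class only -> error
  st3 <- st; st3$specific <- TRUE
  expect_error(onset_predicts_specificity(st3), ">= 2 sites per class")
  # complete separation -> flagged, penalized fallback still finite
  st4 <- st
  st4$specific <- st4$onset_mean > 400
  fit4 <- onset_predicts_specificity(st4)
  expect_true(fit4$separation)
  expect_true(is.finite(fit4$effect$b) && fit4$effect$b > 0)
})

test_that("second-level onset-vs-effect-size model recovers a linear trend", {
  set.seed(66)
  n <- 60
  st <- data.frame(participant_id = sample(sprintf("P%02d", 1:3), n, TRUE),
                   onset_mean = runif(n, 100, 600))
  st$effect <- 0.002 * st$onset_mean + rnorm(n, 0, 0.1)
  e <- onset_vs_effect_size(st)
  expect_lt(abs(e$b - 0.002), 2 * e$se)
  # onset-invariant coupling: slope ~ 0
  st0 <- st; st0$effect <- rnorm(n, 0.5, 0.1)
  e0 <- onset_vs_effect_size(st0)
  expect_lt(abs(e0$b), 3 * e0$se)
  # single participant handled
  st1 <- st; st1$participant_id <- "P01"
  expect_s3_class(onset_vs_effect_size(st1), "data.frame")
  expect_error(onset_vs_effect_size(st[1:5, ]), ">= 10 sites")
})

test_that("mPFC offset-vs-RT contrast recovers a constructed proximity", {
  set.seed(67)
  rows <- list()
  for (p in 1:2) for (s in 1:4) {
    roi <- if (s <= 2) "dmPFC" else "TPJ"
    n <- 40
    rt <- runif(n, 2000, 3000)
    # mPFC offsets 150 ms closer to the response than TPJ offsets
    gap <- if (roi == "dmPFC") 250 else 400
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = sprintf("P%02d", p),
      site_id = sprintf("P%02d_s%d", p, s), roi = roi, trial_id = 1:n,
      rt_ms = rt, offset_ms = rt - gap - rnorm(n, 0, 40),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  e <- mpfc_offset_vs_rt(d)
  expect_true(e$b > 110 && e$b < 190)
  expect_lt(e$p, 0.001)
  # identical ROIs -> near zero
  d0 <- d
  d0$offset_ms <- d0$rt_ms - 300 - rnorm(nrow(d0), 0, 40)
  e0 <- mpfc_offset_vs_rt(d0)
  expect_lt(abs(e0$b), 3 * e0$se)
  expect_error(mpfc_offset_vs_rt(d[d$roi == "TPJ", ]), "no mPFC sites")
})
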