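# Shared fixtures, memoized across test files (test_check runs every file
# in one session, helpers first). Expensive simulated sessions are built
# once and reused.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# 10-site burst/null study used for detector recovery and null calibration
detector_config <- function(active, seed) {
  bs <- default_burst_spec()
  bs$active_probability <- 0
  sel <- bs$roi == "TPJ" & bs$condition == "self"
  bs$active_probability[sel] <- as.numeric(active)
  bs$onset_mean[sel] <- 300; bs$onset_sd[sel] <- 20
  bs$duration_mean[sel] <- 400; bs$duration_sd[sel] <- 0
  bs$amplitude[sel] <- 3
  sim_config(n_participants = 1, sites_per_roi = c(TPJ = 10),
             trials_per_condition = c(self = 50), burst_spec = bs,
             artifacts = list(p_hfo = 0, p_no_response = 0,
                              p_irrelevant = 0),
             inter_trial_gap_ms = 6700, seed = seed)
}

detector_run <- function(active, seed = 101) {
  key <- paste0("detector_", active, "_", seed)
  cached(key, {
    ses <- simulate_session(detector_config(active, seed), "P01")
    ep <- preprocess_session(ses)
    list(session = ses, epochs = ep,
         metrics = run_single_trial(ep),
         labels = site_response_labels(ep, conditions = c("self",
                                                          "mentalizing")))
  })
}

single_burst_run <- function(seed = 2) {
  cached(paste0("single_burst_", seed), {
    ses <- make_fixture("single_burst", seed = seed)
    ep <- preprocess_session(ses)
    list(session = ses, epochs = ep, metrics = run_single_trial(ep))
  })
}

# Small epochs object built directly from a synthetic continuous HFB
# matrix (no wavelets) -- for fast unit tests of epoching/labeling.
synthetic_epochs <- function(hfb_fun, n_trials = 20, n_sites = 1,
                             rt_ms = 2000, fs = 1000, spacing_ms = 4000,
                             smooth_ms = 50, conditions = "self",
                             seed = 1) {
  set.seed(seed)
  n <- n_trials * spacing_ms + 4000
  onsets <- 2000 + (0:(n_trials - 1)) * spacing_ms
  H <- matrix(0, n_sites, n)
  for (i in seq_len(n_sites)) H[i, ] <- hfb_fun(n, onsets)
  attr(H, "fs") <- fs
  channels <- data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
                         participant_id = "P01",
                         roi = "TPJ", hemisphere = "L",
                         clinically_excluded = FALSE,
                         stringsAsFactors = FALSE)
  events <- data.frame(trial_id = seq_len(n_trials),
                       condition = rep(conditions,
                                       length.out = n_trials),
                       stim_onset = onsets,
                       rt_ms = rt_ms, vd1 = 0, vd2 = 0,
                       choice = "true", trait = NA,
                       trait_valence = "none",
                       hfo_flag = FALSE, irrelevant_press = FALSE,
                       stringsAsFactors = FALSE)
  events$response_sample <- events$stim_onset + rt_ms
  cfg <- preprocess_config()
  cfg$smooth_ms <- smooth_ms
  epoch_baseline_smooth(H, channels, events, cfg)
}

# Constructed metrics table for classification/inference unit tests.
constructed_metrics <- function(site_id, cond_means, n_per_cond = 20,
                                sd = 0.4, seed = 1, rt_ms = 2000) {
  set.seed(seed)
  rows <- lapply(names(cond_means), function(cond) {
    pp <- rnorm(n_per_cond, cond_means[[cond]], sd)
    data.frame(site_id = site_id, roi = "dmPFC", participant_id = "P01",
               trial_id = seq_len(n_per_cond), condition = cond,
               rt_ms = rt_ms, has_activation = TRUE,
               onset_ms = 300, peak_ms = 400, offset_ms = 700,
               duration_ms = 400, peak_power_z = pp, deactive_ms = 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$trial_id <- seq_len(nrow(out))
  out
}
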