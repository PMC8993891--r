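# Ground-truthed synthetic iEEG session generator. Voltage = pink-noise
# background + power-line sinusoid (with harmonics) + band-limited
# (70-180 Hz) noise bursts under trapezoidal envelopes. Burst carrier
# power is calibrated so the post-pipeline HFB z inside the burst equals
# the configured amplitude: because per-band power is z-scored over the
# whole recording, injecting bursts inflates the normalising variance, so
# the carrier-to-background power ratio r solves a fixed point in the
# pooled variance (see the methods vignette). Response times are coupled
# to the latest burst offset; choices follow a logistic valence-bias
# model.

#' Default burst specification
#'
#' One row per (ROI, condition): mean/SD of burst onset and duration (ms
#' relative to stimulus onset), target amplitude (post-pipeline HFB z) and
#' per-trial activation probability. Onset means follow the canonical
#' visual-to-medial-prefrontal ordering (101/303/316/322/465/466/537 ms);
#' other-mentalizing bursts last ~100 ms longer than self bursts in
#' default-mode ROIs; cognitive (arithmetic) activation probability falls
#' off from visual cortex to mPFC, giving the specificity gradient.
#'
#' @return Data frame with columns `roi`, `condition`, `onset_mean`,
#'   `onset_sd`, `duration_mean`, `duration_sd`, `amplitude`,
#'   `active_probability`.
#' @export
default_burst_spec <- function() {
  rois <- c("Visual", "TPJ", "ATL", "PMC", "amPFC", "dmPFC", "vmPFC", "none")
  onset <- c(Visual = 101, TPJ = 303, ATL = 316, PMC = 322,
             amPFC = 465, dmPFC = 466, vmPFC = 537, none = 300)
  osd <- c(Visual = 15, TPJ = 50, ATL = 50, PMC = 45,
           amPFC = 60, dmPFC = 55, vmPFC = 70, none = 80)
  dur_self <- c(Visual = 350, TPJ = 500, ATL = 500, PMC = 500,
                amPFC = 550, dmPFC = 550, vmPFC = 550, none = 400)
  extra_other <- c(Visual = 0, TPJ = 100, ATL = 100, PMC = 100,
                   amPFC = 100, dmPFC = 100, vmPFC = 100, none = 0)
  p_cog <- c(Visual = 0.95, TPJ = 0.6, ATL = 0.5, PMC = 0.4,
             amPFC = 0.1, dmPFC = 0.05, vmPFC = 0, none = 0.3)
  onset_cog <- c(Visual = 101, TPJ = 320, ATL = 330, PMC = 340,
                 amPFC = 480, dmPFC = 480, vmPFC = 500, none = 300)
  p_ment <- c(Visual = 0.95, TPJ = 0.85, ATL = 0.85, PMC = 0.85,
              amPFC = 0.85, dmPFC = 0.85, vmPFC = 0.85, none = 0.3)
  rows <- list()
  for (r in rois) {
    rows[[length(rows) + 1]] <- data.frame(
      roi = r, condition = c("self", "other", "cognitive"),
      onset_mean = unname(c(onset[r], onset[r], onset_cog[r])),
      onset_sd = unname(osd[r]),
      duration_mean = unname(c(dur_self[r], dur_self[r] + extra_other[r],
                               if (r == "Visual") 350 else 450)),
      duration_sd = c(120, 120, 110),
      amplitude = 3,
      active_probability = unname(c(p_ment[r], p_ment[r], p_cog[r])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_session()] /
#' [simulate_study()]. Defaults reflect the study design the pipeline is
#' meant for: 16 participants, 50 self- + 50 other-mentalizing + 80
#' arithmetic trials interleaved with 72 cued-rest trials per session,
#' 1000 Hz sampling, 1/f background with 60 Hz line noise, burst latencies
#' per [default_burst_spec()], response times coupled 1:1 to the latest
#' burst offset, and a self-positivity choice bias (valence log-odds
#' 0.931, valence-by-type interaction 0.326).
#'
#' @param n_participants Number of participants.
#' @param sites_per_roi Named integer vector: electrode sites per ROI
#'   (`none` = non-ROI sites).
#' @param trials_per_condition Named integer vector over task conditions
#'   (any of self/other/cognitive/episodic/semantic); `rest` entries give
#'   cued-rest trials.
#' @param fs Sampling rate (Hz, >= 1000).
#' @param background List: `exponent` (1/f power exponent) and
#'   `amplitude_uv` (voltage SD in microvolts).
#' @param line List: `freq`, `amplitude_uv`, `harmonics`, `harmonic_scale`.
#' @param burst_spec Data frame as from [default_burst_spec()].
#' @param rt_model List: `intercept_ms`, `coupling` (ms of RT per ms of the
#'   latest burst offset), `noise_sd_ms`, `b_vd1_ms`, `floor_ms`.
#' @param choice_model List: `b_valence`, `b_valence_x_type` (valence and
#'   type coded +/- 0.5).
#' @param vd_model List: `vd1_mean` (named by condition), `vd1_sd`, `vd2_sd`.
#' @param artifacts List of flag probabilities: `p_hfo`, `p_no_response`,
#'   `p_irrelevant`.
#' @param iti_ms Inter-trial interval (contains the next trial's baseline).
#' @param inter_trial_gap_ms Extra silent gap appended to every task trial.
#' @param rest_duration_ms Length-2 range of cued-rest durations.
#' @param tail_ms Recording padding after the final trial.
#' @param synthesize_signal If `FALSE`, only events and ground truth are
#'   generated (no voltage), for behavior-level studies.
#' @param seed Base seed; all sub-streams derive from it deterministically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 16,
                       sites_per_roi = c(Visual = 2, ATL = 1, TPJ = 2,
                                         PMC = 2, amPFC = 1, dmPFC = 2,
                                         vmPFC = 1, none = 4),
                       trials_per_condition = c(self = 50, other = 50,
                                                cognitive = 80, rest = 72),
                       fs = 1000,
                       background = list(exponent = 1, amplitude_uv = 20),
                       line = list(freq = 60, amplitude_uv = 5,
                                   harmonics = c(120, 180),
                                   harmonic_scale = 0.4),
                       burst_spec = default_burst_spec(),
                       rt_model = list(intercept_ms = 1270, coupling = 1,
                                       noise_sd_ms = 150, b_vd1_ms = 150,
                                       floor_ms = 400),
                       choice_model = list(b_valence = 0.931,
                                           b_valence_x_type = 0.326),
                       vd_model = list(vd1_mean = c(self = -0.4, other = 0.4,
                                                    cognitive = 0.2,
                                                    episodic = 0,
                                                    semantic = 0, rest = 0),
                                       vd1_sd = 0.3, vd2_sd = 1),
                       artifacts = list(p_hfo = 0.02, p_no_response = 0.02,
                                        p_irrelevant = 0.01),
                       iti_ms = 200, inter_trial_gap_ms = 0,
                       rest_duration_ms = c(5000, 10000), tail_ms = 5500,
                       synthesize_signal = TRUE, seed = 1) {
  cfg <- list(n_participants = n_participants, sites_per_roi = sites_per_roi,
              trials_per_condition = trials_per_condition, fs = fs,
              background = background, line = line, burst_spec = burst_spec,
              rt_model = rt_model, choice_model = choice_model,
              vd_model = vd_model, artifacts = artifacts, iti_ms = iti_ms,
              inter_trial_gap_ms = inter_trial_gap_ms,
              rest_duration_ms = rest_duration_ms, tail_ms = tail_ms,
              synthesize_signal = synthesize_signal, seed = seed)
  if (fs < 1000) stopf("sim_config: fs must be >= 1000 Hz")
  bs <- burst_spec
  if (any(bs$onset_sd < 0) || any(bs$duration_sd < 0))
    stopf("sim_config: burst SDs must be >= 0")
  if (any(bs$active_probability < 0 | bs$active_probability > 1))
    stopf("sim_config: active_probability must lie in [0, 1]")
  if (any(bs$amplitude < 0))
    stopf("sim_config: burst amplitude must be >= 0")
  if (rt_model$noise_sd_ms < 0) stopf("sim_config: rt noise_sd_ms < 0")
  bad <- setdiff(unique(bs$roi), roi_levels())
  if (length(bad)) stopf("sim_config: unknown ROI in burst_spec: %s",
                         paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

# Real noise with a deterministic f^(-beta/2) amplitude spectrum and
# random phases, optionally band-limited. Returned unnormalised.
#' @noRd
spectral_noise <- function(n0, fs, beta, fmin = 0, fmax = Inf) {
  n <- stats::nextn(n0, c(2, 3, 5))      # fast FFT length; truncate after
  nf <- floor(n / 2)
  f <- seq_len(nf) / n * fs
  amp <- f^(-beta / 2)
  amp[f < fmin | f > fmax] <- 0
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  if (n %% 2 == 0) {
    full <- c(0, spec[-nf], complex(real = Mod(spec[nf])),
              Conj(rev(spec[-nf])))
  } else {
    full <- c(0, spec, Conj(rev(spec)))
  }
  Re(fft(full, inverse = TRUE))[seq_len(n0)]
}

# Fraction of 1/f background variance lying inside [fmin, fmax].
#' @noRd
band_fraction <- function(n, fs, beta, fmin, fmax) {
  nf <- floor(n / 2)
  f <- seq_len(nf) / n * fs
  a2 <- f^(-beta)
  sum(a2[f >= fmin & f <= fmax]) / sum(a2)
}

# Solve the burst-power calibration. Per band, background power is ~
# exponential with sd = mean; z-scoring over the whole recording uses the
# pooled (burst-inflated) variance. With per-burst duty rho_j and target
# amplitudes a_j, the carrier/background power ratios are r_j = a_j*sigma
# where sigma (the pooled sd in units of the background mean) solves
#   sigma^2 = 2(1 - P) + 2*sum(rho_j (1 + a_j sigma)^2)
#             - (1 + sum(rho_j a_j sigma))^2,  P = sum(rho_j).
# Infeasible when the duty cycle is too high for the target amplitude
# (global z ceiling 1/sqrt(rho(2-rho))).
#' @noRd
solve_burst_scale <- function(duty, amp) {
  stopifnot(length(duty) == length(amp))
  keep <- duty > 0 & amp > 0
  if (!any(keep)) return(numeric(0))
  duty <- duty[keep]; amp <- amp[keep]
  P <- sum(duty)
  g <- function(s) {
    m1 <- 1 + sum(duty * amp * s)
    m2 <- 2 * (1 - P) + 2 * sum(duty * (1 + amp * s)^2)
    s^2 - (m2 - m1^2)
  }
  lead <- 1 - 2 * sum(duty * amp^2) + sum(duty * amp)^2
  if (lead <= 0 || g(1e7) <= 0)
    stopf(paste("burst calibration infeasible: target amplitude(s) %s at",
                "total duty %.3f exceed the z ceiling imposed by whole-",
                "recording z-scoring; lengthen inter-trial gaps or lower",
                "the amplitude"),
          paste(unique(amp), collapse = "/"), P)
  s <- uniroot(g, c(1e-6, 1e7), tol = 1e-10)$root
  out <- numeric(length(keep))
  out[keep] <- amp * s
  out
}

#' @noRd
draw_trial_frame <- function(cfg, pid) {
  tpc <- cfg$trials_per_condition
  conds <- rep(names(tpc), tpc)
  with_seed(substream_seed(cfg$seed, paste0("events:", pid)), {
    conds <- sample(conds)
    n <- length(conds)
    ev <- data.frame(trial_id = seq_len(n), condition = conds,
                     stringsAsFactors = FALSE)
    # trait pool: valence is a property of the trait word
    n_tr <- 30
    traits <- sprintf("trait%02d", seq_len(n_tr))
    tr_val <- rep(c("positive", "negative"), length.out = n_tr)
    ev$trait <- NA_character_
    ev$trait_valence <- "none"
    for (cond in c("self", "other")) {
      idx <- which(ev$condition == cond)
      pick <- sample(rep(seq_len(n_tr), length.out = length(idx)))
      ev$trait[idx] <- traits[pick]
      ev$trait_valence[idx] <- tr_val[pick]
    }
    vm <- cfg$vd_model
    mu1 <- vm$vd1_mean[ev$condition]
    mu1[is.na(mu1)] <- 0
    ev$vd1 <- rnorm(n, mu1, vm$vd1_sd)
    ev$vd2 <- rnorm(n, 0, vm$vd2_sd)
    task <- ev$condition != "rest"
    ev$hfo_flag <- task & runif(n) < cfg$artifacts$p_hfo
    ev$no_response <- task & runif(n) < cfg$artifacts$p_no_response
    ev$irrelevant_press <- task & runif(n) < cfg$artifacts$p_irrelevant
    ev
  })
}

#' @noRd
make_channel_table <- function(cfg, pid) {
  spr <- cfg$sites_per_roi
  roi <- rep(names(spr), spr)
  n <- length(roi)
  data.frame(site_id = sprintf("%s_s%02d", pid, seq_len(n)),
             participant_id = pid, roi = roi,
             hemisphere = "L", clinically_excluded = FALSE,
             stringsAsFactors = FALSE)
}

#' @noRd
draw_ground_truth <- function(cfg, pid, ev, channels) {
  bs <- cfg$burst_spec
  out <- list()
  for (i in seq_len(nrow(channels))) {
    site <- channels$site_id[i]
    roi <- channels$roi[i]
    with_seed(substream_seed(cfg$seed, paste0("truth:", pid, ":", site)), {
      n <- nrow(ev)
      onset <- rep(NA_real_, n); dur <- rep(NA_real_, n)
      amp <- rep(0, n); act <- rep(FALSE, n)
      for (cond in unique(ev$condition)) {
        row <- bs[bs$roi == roi & bs$condition == cond, ]
        idx <- which(ev$condition == cond)
        if (!length(idx)) next
        if (nrow(row) == 0) next
        a <- runif(length(idx)) < row$active_probability[1]
        o <- rnorm(length(idx), row$onset_mean[1], row$onset_sd[1])
        d <- pmax(50, rnorm(length(idx), row$duration_mean[1],
                            row$duration_sd[1]))
        a <- a & row$amplitude[1] > 0
        act[idx] <- a
        onset[idx[a]] <- pmax(0, o[a])
        dur[idx[a]] <- d[a]
        amp[idx[a]] <- row$amplitude[1]
      }
      out[[site]] <- data.frame(
        site_id = site, trial_id = ev$trial_id, is_active = act,
        true_onset = onset, true_offset = onset + dur,
        true_amplitude = amp, stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate one participant session
#'
#' Generates the event table, per-site ground-truth bursts, behavioral
#' responses (RT coupled to the latest burst offset, choices from the
#' logistic valence-bias model) and, unless disabled, the multichannel
#' voltage recording. Deterministic given `(config, participant)`.
#'
#' @param config A [sim_config()].
#' @param participant Participant id (default `"P01"`).
#' @return List of class `hfb_session`: `recording` (or `NULL`), `events`,
#'   `truth`, `participant_id`.
#' @export
simulate_session <- function(config, participant = "P01") {
  cfg <- config
  if (!inherits(cfg, "sim_config")) stopf("config must come from sim_config()")
  pid <- participant
  fs <- cfg$fs
  ev <- draw_trial_frame(cfg, pid)
  channels <- make_channel_table(cfg, pid)
  truth <- draw_ground_truth(cfg, pid, ev, channels)

  # behavioral coupling
  with_seed(substream_seed(cfg$seed, paste0("behav:", pid)), {
    n <- nrow(ev)
    latest <- vapply(ev$trial_id, function(tid) {
      off <- truth$true_offset[truth$trial_id == tid & truth$is_active]
      if (length(off)) max(off) else 0
    }, 0)
    rm_ <- cfg$rt_model
    rt <- rm_$intercept_ms + rm_$coupling * latest +
      rm_$b_vd1_ms * ev$vd1 + rnorm(n, 0, rm_$noise_sd_ms)
    rt <- pmax(rm_$floor_ms, rt)
    rt[ev$condition == "rest" | ev$no_response] <- NA
    ev$rt_ms <- round(rt)
    cm <- cfg$choice_model
    val <- ifelse(ev$trait_valence == "positive", 0.5,
                  ifelse(ev$trait_valence == "negative", -0.5, 0))
    typ <- ifelse(ev$condition == "self", 0.5,
                  ifelse(ev$condition == "other", -0.5, 0))
    eta <- cm$b_valence * val + cm$b_valence_x_type * val * typ
    pr <- plogis(eta)
    ch <- ifelse(runif(n) < pr, "true", "false")
    ch[ev$condition %in% c("cognitive", "episodic", "semantic")] <-
      ifelse(runif(sum(ev$condition %in%
                         c("cognitive", "episodic", "semantic"))) < 0.5,
             "true", "false")
    ch[ev$condition == "rest" | is.na(ev$rt_ms)] <- "none"
    ev$choice <- ch
  })

  # layout: self-paced; the ITI carries the next trial's baseline
  with_seed(substream_seed(cfg$seed, paste0("layout:", pid)), {
    n <- nrow(ev)
    durs <- numeric(n)
    for (i in seq_len(n)) {
      durs[i] <- if (ev$condition[i] == "rest") {
        runif(1, cfg$rest_duration_ms[1], cfg$rest_duration_ms[2])
      } else {
        (if (is.na(ev$rt_ms[i])) 5000 else ev$rt_ms[i]) + cfg$iti_ms +
          cfg$inter_trial_gap_ms
      }
    }
    starts <- 2000 + c(0, cumsum(durs[-n]))
    ev$stim_onset <- round(starts / 1000 * fs)
    ev$response_sample <- ifelse(is.na(ev$rt_ms), NA,
                                 ev$stim_onset + round(ev$rt_ms / 1000 * fs))
    n_samples <- ev$stim_onset[n] + round((durs[n] + cfg$tail_ms) / 1000 * fs)
  })
  ev <- ev[, c("trial_id", "condition", "stim_onset", "response_sample",
               "rt_ms", "choice", "trait", "trait_valence", "vd1", "vd2",
               "hfo_flag", "irrelevant_press", "no_response")]

  rec <- NULL
  if (cfg$synthesize_signal) {
    rec <- synthesize_voltage(cfg, pid, ev, channels, truth, n_samples)
  }
  structure(list(recording = rec, events = ev, truth = truth,
                 participant_id = pid),
            class = "hfb_session")
}

#' @noRd
synthesize_voltage <- function(cfg, pid, ev, channels, truth, n_samples) {
  fs <- cfg$fs
  n_ch <- nrow(channels)
  V <- matrix(0, n_ch, n_samples)
  bfrac <- band_fraction(n_samples, fs, cfg$background$exponent, 70, 180)
  tvec <- seq_len(n_samples) / fs
  onset_samp <- ev$stim_onset[match(truth$trial_id, ev$trial_id)]
  for (i in seq_len(n_ch)) {
    site <- channels$site_id[i]
    with_seed(substream_seed(cfg$seed, paste0("noise:", pid, ":", site)), {
      bg <- spectral_noise(n_samples, fs, cfg$background$exponent)
      bg <- bg / sd(bg) * cfg$background$amplitude_uv
      tr <- truth[truth$site_id == site & truth$is_active, ]
      tr_on <- onset_samp[truth$site_id == site & truth$is_active]
      x <- bg
      if (nrow(tr) > 0) {
        durs <- (tr$true_offset - tr$true_onset) / 1000 * fs
        duty <- durs / n_samples
        r <- solve_burst_scale(duty, tr$true_amplitude)
        # common-average referencing downstream attenuates each channel's
        # burst-to-background power ratio by (n-1)/n; pre-compensate
        if (n_ch > 1) r <- r * n_ch / (n_ch - 1)
        carrier <- spectral_noise(n_samples, fs, cfg$background$exponent,
                                  70, 180)
        v_band <- bfrac * cfg$background$amplitude_uv^2
        carrier <- carrier / sd(carrier) * sqrt(v_band)
        env <- numeric(n_samples)
        ramp <- round(20 / 1000 * fs)
        for (j in seq_len(nrow(tr))) {
          a <- tr_on[j] + round(tr$true_onset[j] / 1000 * fs)
          b <- tr_on[j] + round(tr$true_offset[j] / 1000 * fs) - 1L
          if (a < 1 || a >= n_samples) next
          b <- min(b, n_samples)
          len <- b - a + 1L
          rl <- min(ramp, floor(len / 2))
          e <- rep(1, len)
          if (rl > 0) {
            e[seq_len(rl)] <- seq(1 / rl, 1, length.out = rl)
            e[(len - rl + 1):len] <- seq(1, 1 / rl, length.out = rl)
          }
          env[a:b] <- pmax(env[a:b], sqrt(e * r[j]))
        }
        x <- x + carrier * env
      }
      ph <- runif(1, 0, 2 * pi)
      x <- x + cfg$line$amplitude_uv * sin(2 * pi * cfg$line$freq * tvec + ph)
      for (h in cfg$line$harmonics) {
        x <- x + cfg$line$amplitude_uv * cfg$line$harmonic_scale *
          sin(2 * pi * h * tvec + runif(1, 0, 2 * pi))
      }
      V[i, ] <- x
    })
  }
  hfb_recording(pid, fs, channels, V, cfg$line$freq)
}

#' Simulate a multi-participant study
#'
#' @param config A [sim_config()].
#' @return List of class `hfb_study`: `sessions` (one [simulate_session()]
#'   result per participant) and `config`.
#' @export
simulate_study <- function(config) {
  pids <- sprintf("P%02d", seq_len(config$n_participants))
  sessions <- lapply(pids, function(p) simulate_session(config, p))
  names(sessions) <- pids
  structure(list(sessions = sessions, config = config), class = "hfb_study")
}

#' Miniature deterministic fixture sessions
#'
#' Small single-participant sessions exercising one downstream rule each:
#' `null_no_signal` (no bursts anywhere), `single_burst` (one active site,
#' onset 300 ms, duration 400 ms, amplitude 3 z), `two_roi_lag` (ROI B
#' onsets exactly 150 ms after ROI A), `specificity_grid` (sites covering
#' the mentalizing-active x cognitive-active cells), `selectivity_grid`
#' (2 self-greater vs 10 other-greater sites).
#'
#' @param name Fixture name.
#' @param seed Base seed.
#' @return An `hfb_session` (see [simulate_session()]).
#' @export
make_fixture <- function(name = c("null_no_signal", "single_burst",
                                  "two_roi_lag", "specificity_grid",
                                  "selectivity_grid"),
                         seed = 1) {
  name <- match.arg(name)
  no_art <- list(p_hfo = 0, p_no_response = 0, p_irrelevant = 0)
  base_spec <- default_burst_spec()
  off_spec <- transform(base_spec, active_probability = 0)

  if (name == "null_no_signal") {
    cfg <- sim_config(n_participants = 1,
                      sites_per_roi = c(Visual = 1, TPJ = 1, PMC = 1,
                                        dmPFC = 1, vmPFC = 1, none = 1),
                      trials_per_condition = c(self = 20, other = 20),
                      burst_spec = off_spec, artifacts = no_art,
                      inter_trial_gap_ms = 500, seed = seed)
    return(simulate_session(cfg, "P01"))
  }

  if (name == "single_burst") {
    bs <- off_spec
    sel <- bs$roi == "TPJ" & bs$condition == "self"
    bs$active_probability[sel] <- 1
    bs$onset_mean[sel] <- 300; bs$onset_sd[sel] <- 0
    bs$duration_mean[sel] <- 400; bs$duration_sd[sel] <- 0
    bs$amplitude[sel] <- 3
    cfg <- sim_config(n_participants = 1,
                      sites_per_roi = c(TPJ = 1, none = 7),
                      trials_per_condition = c(self = 40),
                      burst_spec = bs, artifacts = no_art,
                      inter_trial_gap_ms = 6500, seed = seed)
    return(simulate_session(cfg, "P01"))
  }

  if (name == "two_roi_lag") {
    bs <- off_spec
    for (cond in c("self")) {
      for (r in c("TPJ", "PMC")) {
        sel <- bs$roi == r & bs$condition == cond
        bs$active_probability[sel] <- 1
        bs$onset_mean[sel] <- if (r == "TPJ") 300 else 450
        bs$onset_sd[sel] <- 20
        bs$duration_mean[sel] <- 400; bs$duration_sd[sel] <- 0
        bs$amplitude[sel] <- 3
      }
    }
    cfg <- sim_config(n_participants = 1,
                      sites_per_roi = c(TPJ = 1, PMC = 1, none = 6),
                      trials_per_condition = c(self = 30),
                      burst_spec = bs, artifacts = no_art,
                      inter_trial_gap_ms = 9000, seed = seed)
    ses <- simulate_session(cfg, "P01")
    # enforce the exact 150-ms lag: PMC onsets = TPJ onsets + 150
    tpj <- ses$truth$site_id == "P01_s01"
    pmc <- ses$truth$site_id == "P01_s02"
    ses$truth$true_onset[pmc] <- ses$truth$true_onset[tpj] + 150
    ses$truth$true_offset[pmc] <- ses$truth$true_onset[pmc] + 400
    ses$truth$is_active[pmc] <- ses$truth$is_active[tpj]
    n_samples <- ncol(ses$recording$voltage)
    ses$recording <- synthesize_voltage(cfg, "P01", ses$events,
                                        ses$recording$channels, ses$truth,
                                        n_samples)
    return(ses)
  }

  if (name == "specificity_grid") {
    # four dmPFC sites: (mz x cog) activity cells
    grid <- data.frame(site = 1:4,
                       mz = c(TRUE, TRUE, FALSE, FALSE),
                       cog = c(FALSE, TRUE, TRUE, FALSE))
    bs_rows <- list()
    for (i in grid$site) {
      roi <- "dmPFC"
      for (cond in c("self", "other", "cognitive")) {
        on_cond <- if (cond == "cognitive") grid$cog[i] else grid$mz[i]
        bs_rows[[length(bs_rows) + 1]] <- data.frame(
          roi = roi, condition = cond, onset_mean = 300, onset_sd = 30,
          duration_mean = 400, duration_sd = 60, amplitude = 2,
          active_probability = as.numeric(on_cond), site_slot = i,
          stringsAsFactors = FALSE)
      }
    }
    spec <- do.call(rbind, bs_rows)
    cfg <- sim_config(n_participants = 1,
                      sites_per_roi = c(dmPFC = 4, none = 4),
                      trials_per_condition = c(self = 15, other = 15,
                                               cognitive = 15),
                      burst_spec = off_spec, artifacts = no_art,
                      inter_trial_gap_ms = 6000, seed = seed)
    ses <- simulate_session(cfg, "P01")
    ses <- regenerate_truth_per_site(cfg, ses, spec)
    attr(ses, "grid") <- grid
    return(ses)
  }

  # selectivity_grid: 12 TPJ sites, all active for both mentalizing types;
  # 2 with greater self peak power, 10 with greater other peak power
  grid <- data.frame(site = 1:12,
                     self_amp = c(2.5, 2.5, rep(1.2, 10)),
                     other_amp = c(1.2, 1.2, rep(2.5, 10)))
  bs_rows <- list()
  for (i in grid$site) {
    for (cond in c("self", "other")) {
      bs_rows[[length(bs_rows) + 1]] <- data.frame(
        roi = "TPJ", condition = cond, onset_mean = 300, onset_sd = 30,
        duration_mean = 400, duration_sd = 60,
        amplitude = if (cond == "self") grid$self_amp[i] else
          grid$other_amp[i],
        active_probability = 1, site_slot = i, stringsAsFactors = FALSE)
    }
  }
  spec <- do.call(rbind, bs_rows)
  cfg <- sim_config(n_participants = 1, sites_per_roi = c(TPJ = 12),
                    trials_per_condition = c(self = 18, other = 18),
                    burst_spec = off_spec, artifacts = no_art,
                    inter_trial_gap_ms = 4500, seed = seed)
  ses <- simulate_session(cfg, "P01")
  ses <- regenerate_truth_per_site(cfg, ses, spec)
  attr(ses, "grid") <- grid
  ses
}

# Redraw ground truth with a per-site burst spec (column `site_slot`
# indexes the channel), then re-synthesize the voltage.
#' @noRd
regenerate_truth_per_site <- function(cfg, ses, spec) {
  channels <- if (!is.null(ses$recording)) ses$recording$channels else
    make_channel_table(cfg, ses$participant_id)
  ev <- ses$events
  pid <- ses$participant_id
  out <- list()
  for (i in seq_len(nrow(channels))) {
    site <- channels$site_id[i]
    sspec <- spec[spec$site_slot == i, ]
    with_seed(substream_seed(cfg$seed, paste0("truth:", pid, ":", site)), {
      n <- nrow(ev)
      onset <- rep(NA_real_, n); dur <- rep(NA_real_, n)
      amp <- rep(0, n); act <- rep(FALSE, n)
      for (cond in unique(ev$condition)) {
        row <- sspec[sspec$condition == cond, ]
        idx <- which(ev$condition == cond)
        if (!length(idx) || nrow(row) == 0) next
        a <- runif(length(idx)) < row$active_probability[1]
        o <- rnorm(length(idx), row$onset_mean[1], row$onset_sd[1])
        d <- pmax(50, rnorm(length(idx), row$duration_mean[1],
                            row$duration_sd[1]))
        a <- a & row$amplitude[1] > 0
        act[idx] <- a
        onset[idx[a]] <- pmax(0, o[a])
        dur[idx[a]] <- d[a]
        amp[idx[a]] <- row$amplitude[1]
      }
      out[[site]] <- data.frame(site_id = site, trial_id = ev$trial_id,
                                is_active = act, true_onset = onset,
                                true_offset = onset + dur,
                                true_amplitude = amp,
                                stringsAsFactors = FALSE)
    })
  }
  ses$truth <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (cfg$synthesize_signal) {
    n_samples <- ncol(ses$recording$voltage)
    ses$recording <- synthesize_voltage(cfg, pid, ev, channels, ses$truth,
                                        n_samples)
  }
  ses
}

#' Metrics-level generator for inference parameter recovery
#'
#' Draws single-trial activation-metric observations directly under the
#' mixed-model structure fitted by [fit_roi_type_rt_choice()]:
#' `value = mu + u_participant + u_site + b_type*type + b_rt*rt +
#' b_choice*choice + b_vd1*vd1 + noise`, with type/choice coded +/- 0.5.
#' Used by the parameter-recovery suite, where "recovering the generator
#' slope" must refer to an actual generator parameter.
#'
#' @param n_participants,sites_per_participant,trials_per_site Design size.
#' @param mu Baseline metric mean.
#' @param b_type,b_rt,b_choice,b_vd1 Generator fixed effects.
#' @param sd_participant,sd_site Random-intercept SDs.
#' @param sigma Residual SD.
#' @param rt_mean,rt_sd RT distribution (ms), truncated to [400, 5000].
#' @param seed Seed.
#' @return Data frame with columns `participant`, `site_id`, `roi`,
#'   `trial_id`, `type`, `rt_ms`, `choice`, `vd1`, `vd2`, `value`.
#' @export
simulate_roi_metrics <- function(n_participants = 4,
                                 sites_per_participant = 4,
                                 trials_per_site = 60, mu = 700,
                                 b_type = 100, b_rt = 0.2, b_choice = -20,
                                 b_vd1 = 30, sd_participant = 60,
                                 sd_site = 40, sigma = 120,
                                 rt_mean = 2500, rt_sd = 500, seed = 1) {
  with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      up <- rnorm(1, 0, sd_participant)
      for (s in seq_len(sites_per_participant)) {
        us <- rnorm(1, 0, sd_site)
        n <- trials_per_site
        type <- sample(rep(c(0.5, -0.5), length.out = n))    # self/other
        choice <- sample(rep(c(0.5, -0.5), length.out = n))  # true/false
        rt <- pmin(5000, pmax(400, rnorm(n, rt_mean, rt_sd)))
        vd1 <- rnorm(n, 0, 1); vd2 <- rnorm(n, 0, 1)
        val <- mu + up + us + b_type * type + b_rt * rt +
          b_choice * choice + b_vd1 * vd1 + rnorm(n, 0, sigma)
        rows[[length(rows) + 1]] <- data.frame(
          participant = sprintf("P%02d", p),
          site_id = sprintf("P%02d_s%02d", p, s), roi = "dmPFC",
          trial_id = seq_len(n), type = type, rt_ms = rt, choice = choice,
          vd1 = vd1, vd2 = vd2, value = val, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Ground-truth activation metrics
#'
#' Converts a session's ground truth into the metric table an ideal
#' detector would produce (onset/offset/duration from the envelope
#' support, peak power = target amplitude, peak at the envelope midpoint).
#'
#' @param session An `hfb_session`.
#' @return Data frame shaped like [run_single_trial()] output.
#' @export
ground_truth_metrics <- function(session) {
  tr <- session$truth
  ev <- session$events
  m <- merge(tr, ev[, c("trial_id", "condition", "rt_ms")], by = "trial_id")
  data.frame(site_id = m$site_id, trial_id = m$trial_id,
             condition = m$condition, rt_ms = m$rt_ms,
             has_activation = m$is_active,
             onset_ms = ifelse(m$is_active, m$true_onset, NA),
             peak_ms = ifelse(m$is_active,
                              (m$true_onset + m$true_offset) / 2, NA),
             offset_ms = ifelse(m$is_active, m$true_offset, NA),
             duration_ms = ifelse(m$is_active,
                                  m$true_offset - m$true_onset, NA),
             peak_power_z = ifelse(m$is_active, m$true_amplitude, 0),
             stringsAsFactors = FALSE)
}
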