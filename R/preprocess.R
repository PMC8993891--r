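# Preprocessing: notch filter -> common-average re-reference -> Morlet
# time-frequency decomposition -> per-band z-transform -> epoching with
# per-trial baseline correction -> band averaging -> gaussian smoothing,
# plus trial exclusions and timepoint-outlier masking. The fixed order
# matters: the z-transform precedes epoching/baseline correction and the
# per-band baseline subtraction precedes band averaging (both are linear,
# so band-averaging and baseline subtraction commute and the averaged
# trace is corrected once).

#' Default preprocessing configuration
#'
#' @return Named list of preprocessing parameters: `notch_bands`,
#'   `hfb_range`, `hfb_step`, `n_cycles`, `smooth_ms`, `baseline_ms`,
#'   `epoch_ms`, `rt_min_ms`, `mad_threshold`, `mask_post_rt_ms`.
#' @export
preprocess_config <- function() {
  list(notch_bands = list(c(57, 63), c(117, 123), c(177, 183)),
       hfb_range = c(70, 180), hfb_step = 10, n_cycles = 5,
       smooth_ms = 50, baseline_ms = c(-200, 0), epoch_ms = c(-200, 5000),
       rt_min_ms = 400, mad_threshold = 3, mask_post_rt_ms = 200)
}

#' Zero-phase notch filter
#'
#' Band-stop Butterworth filters (order 4, forward-backward so zero phase)
#' applied per channel, with 2 s of reflected signal at each edge to damp
#' filter transients. Default bands remove power-line noise and its
#' harmonics.
#'
#' @param rec An `hfb_recording`.
#' @param bands List of `c(low, high)` Hz pairs.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, bands = preprocess_config()$notch_bands) {
  fs <- rec$fs
  for (b in bands) {
    if (max(b) >= fs / 2)
      stopf("notch_filter: band edge %g Hz >= Nyquist (%g Hz)", max(b), fs / 2)
  }
  pad <- min(round(2 * fs), ncol(rec$voltage) - 1)
  filts <- lapply(bands, function(b)
    signal::butter(4, b / (fs / 2), type = "stop"))
  V <- rec$voltage
  for (i in seq_len(nrow(V))) {
    x <- V[i, ]
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[(length(x) - pad + 1):length(x)]))
    for (f in filts) xp <- signal::filtfilt(f, xp)
    V[i, ] <- xp[(pad + 1):(pad + length(x))]
  }
  rec$voltage <- V
  rec
}

#' Common-average re-reference
#'
#' Subtracts the mean signal of the retained (not clinically excluded)
#' channels from each retained channel; excluded channels are dropped from
#' the recording and all downstream analysis.
#'
#' @param rec An `hfb_recording`.
#' @return The re-referenced recording (excluded channels removed).
#' @export
rereference_common_average <- function(rec) {
  keep <- !rec$channels$clinically_excluded
  if (sum(keep) < 2)
    stopf("rereference_common_average: need >= 2 retained channels, got %d",
          sum(keep))
  V <- rec$voltage[keep, , drop = FALSE]
  V <- sweep(V, 2, colMeans(V))
  rec$voltage <- V
  rec$channels <- rec$channels[keep, , drop = FALSE]
  rec
}

# Morlet wavelet power via FFT convolution with an analytic gaussian
# kernel in the frequency domain (spectral sd = f0 / n_cycles).
#' @noRd
morlet_power <- function(x, fs, f0, n_cycles = 5) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))      # pad to a fast FFT length
  x <- c(x, numeric(n - n0))
  X <- fft(x)
  freqs <- c(seq(0, floor(n / 2)), -rev(seq_len(ceiling(n / 2) - 1))) * fs / n
  sigma_f <- f0 / n_cycles
  H <- exp(-(freqs - f0)^2 / (2 * sigma_f^2))
  H[freqs < 0] <- 0
  Mod(fft(X * H, inverse = TRUE) / n)[seq_len(n0)]^2
}

#' Continuous HFB z-power
#'
#' For each analysis band (default centers 70, 80, ..., 180 Hz), computes
#' 5-cycle Morlet wavelet power, z-transforms it across the whole
#' recording, and averages the per-band z-scores into a single HFB
#' timecourse per channel.
#'
#' @param rec A re-referenced `hfb_recording`.
#' @param config Preprocessing configuration ([preprocess_config()]).
#' @return Channels x samples matrix of HFB z-power, with attributes
#'   `bands` (band centers) and `fs`.
#' @export
hfb_power <- function(rec, config = preprocess_config()) {
  fs <- rec$fs
  bands <- seq(config$hfb_range[1], config$hfb_range[2], by = config$hfb_step)
  longest_period <- 1 / bands[1]
  if (ncol(rec$voltage) < 10 * longest_period * fs)
    stopf("hfb_power: recording shorter than 10 periods of the longest wavelet")
  n0 <- ncol(rec$voltage)
  n <- stats::nextn(n0, c(2, 3, 5))
  freqs <- c(seq(0, floor(n / 2)), -rev(seq_len(ceiling(n / 2) - 1))) * fs / n
  pos <- freqs >= 0
  out <- matrix(0, nrow(rec$voltage), n0)
  for (i in seq_len(nrow(rec$voltage))) {
    X <- fft(c(rec$voltage[i, ], numeric(n - n0)))  # one forward FFT/channel
    acc <- numeric(n0)
    for (f0 in bands) {
      sigma_f <- f0 / config$n_cycles
      H <- numeric(n)
      H[pos] <- exp(-(freqs[pos] - f0)^2 / (2 * sigma_f^2))
      p <- Mod(fft(X * H, inverse = TRUE) / n)[seq_len(n0)]^2
      acc <- acc + (p - mean(p)) / sd(p)
    }
    out[i, ] <- acc / length(bands)
  }
  attr(out, "bands") <- bands
  attr(out, "fs") <- fs
  out
}

#' @noRd
gaussian_kernel <- function(width_ms, fs) {
  # "width" = total kernel support; sd = width/6, truncated at +/- width/2
  half <- round(width_ms / 2 / 1000 * fs)
  sigma <- width_ms / 6 / 1000 * fs
  k <- dnorm(-half:half, sd = sigma)
  k / sum(k)
}

#' Epoch, baseline-correct and smooth the HFB signal
#'
#' Cuts the continuous HFB z-power into stimulus-locked epochs, subtracts
#' each trial's pre-stimulus baseline mean, smooths with a gaussian window
#' (total width `smooth_ms`), and builds the validity mask (timepoints at
#' or after `rt + 200` ms are invalid, i.e. belong to the next trial).
#' Trials whose epoch would extend past the recording end are dropped with
#' a warning.
#'
#' @param hfb Continuous HFB matrix from [hfb_power()].
#' @param channels Channel table of the (re-referenced) recording.
#' @param events Event table (after or before exclusions; see
#'   [apply_trial_exclusions()]).
#' @param config Preprocessing configuration.
#' @return Object of class `hfb_epochs`: list with `hfb` (site x trial x
#'   time array, smoothed), `valid` (logical array), `time_ms`,
#'   `baseline_idx`, `channels`, `events`, `fs`, `config`.
#' @export
epoch_baseline_smooth <- function(hfb, channels, events,
                                  config = preprocess_config()) {
  fs <- attr(hfb, "fs")
  step_ms <- 1000 / fs
  t0 <- config$epoch_ms[1]; t1 <- config$epoch_ms[2]
  time_ms <- seq(t0, t1, by = step_ms)
  n_t <- length(time_ms)
  base_idx <- which(time_ms >= config$baseline_ms[1] &
                      time_ms < config$baseline_ms[2])
  offs <- round(time_ms / 1000 * fs)

  keep <- events$stim_onset + max(offs) <= ncol(hfb) &
    events$stim_onset + min(offs) >= 1
  if (any(!keep))
    warnf("epoch_baseline_smooth: dropped %d trial(s) extending past the recording",
          sum(!keep))
  ev <- events[keep, , drop = FALSE]
  n_tr <- nrow(ev)
  n_s <- nrow(hfb)
  kern <- gaussian_kernel(config$smooth_ms, fs)
  half <- (length(kern) - 1) / 2

  arr <- array(NA_real_, c(n_s, n_tr, n_t))
  valid <- array(TRUE, c(n_s, n_tr, n_t))
  for (j in seq_len(n_tr)) {
    idx <- ev$stim_onset[j] + offs
    seg <- hfb[, idx, drop = FALSE]
    seg <- seg - rowMeans(seg[, base_idx, drop = FALSE])
    # reflect-pad and smooth each site's trace
    for (i in seq_len(n_s)) {
      x <- seg[i, ]
      xp <- c(rev(x[seq_len(half)]), x, rev(x[(n_t - half + 1):n_t]))
      sm <- stats::filter(xp, kern, sides = 2)
      arr[i, j, ] <- sm[(half + 1):(half + n_t)]
    }
    if (!is.na(ev$rt_ms[j]))
      valid[, j, time_ms >= ev$rt_ms[j] + config$mask_post_rt_ms] <- FALSE
  }
  structure(list(hfb = arr, valid = valid, time_ms = time_ms,
                 baseline_idx = base_idx, channels = channels, events = ev,
                 fs = fs, config = config),
            class = "hfb_epochs")
}

#' @export
print.hfb_epochs <- function(x, ...) {
  cat(sprintf("<hfb_epochs> %d sites x %d trials x %d timepoints (%g..%g ms)\n",
              dim(x$hfb)[1], dim(x$hfb)[2], dim(x$hfb)[3],
              min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Apply trial exclusion rules
#'
#' Removes trials with epileptic high-frequency oscillations, no
#' behavioral response, irrelevant button presses, or response time under
#' `rt_min_ms` (400 ms; an RT of exactly 400 ms is retained), plus
#' cued-rest trials. Exclusion reasons are recorded per trial in the
#' `"exclusions"` attribute.
#'
#' @param events Event table.
#' @param config Preprocessing configuration.
#' @return Filtered event table with an `exclusions` attribute.
#' @export
apply_trial_exclusions <- function(events, config = preprocess_config()) {
  reasons <- list(
    rest = events$condition == "rest",
    hfo = events$hfo_flag,
    no_response = is.na(events$rt_ms) & events$condition != "rest",
    irrelevant_press = events$irrelevant_press,
    rt_under_min = !is.na(events$rt_ms) & events$rt_ms < config$rt_min_ms)
  drop <- Reduce(`|`, reasons)
  log <- do.call(rbind, lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    if (!length(idx)) return(NULL)
    data.frame(trial_id = events$trial_id[idx], reason = r,
               stringsAsFactors = FALSE)
  }))
  out <- events[!drop, , drop = FALSE]
  if (nrow(out) == 0) warnf("apply_trial_exclusions: no trials retained")
  attr(out, "exclusions") <- log %||%
    data.frame(trial_id = integer(), reason = character())
  out
}

#' Mask per-timepoint outliers
#'
#' For each (site, condition, timepoint), observations more than
#' `mad_threshold` scaled MADs from the cross-trial median are marked
#' invalid. Conditions with fewer than 5 trials are skipped with a
#' warning; timepoints with zero MAD are skipped (nothing is masked).
#'
#' @param epochs An `hfb_epochs`.
#' @param config Preprocessing configuration.
#' @return The epochs with an updated `valid` mask and an
#'   `n_masked` element.
#' @export
mask_timepoint_outliers <- function(epochs, config = epochs$config) {
  thr <- config$mad_threshold
  ev <- epochs$events
  n_masked <- 0L
  for (cond in unique(ev$condition)) {
    tr_idx <- which(ev$condition == cond)
    if (length(tr_idx) < 5) {
      warnf("mask_timepoint_outliers: condition '%s' has < 5 trials; skipped",
            cond)
      next
    }
    for (i in seq_len(dim(epochs$hfb)[1])) {
      m <- epochs$hfb[i, tr_idx, , drop = TRUE]        # trials x time
      v <- epochs$valid[i, tr_idx, , drop = TRUE]
      m[!v] <- NA
      med <- apply(m, 2, median, na.rm = TRUE)
      madv <- 1.4826 * apply(abs(sweep(m, 2, med)), 2, median, na.rm = TRUE)
      lim <- thr * madv
      bad <- sweep(abs(sweep(m, 2, med)), 2, lim, `>`)
      bad[is.na(bad)] <- FALSE
      bad[, is.na(madv) | madv == 0] <- FALSE
      bad[, epochs$baseline_idx] <- FALSE   # baseline samples stay valid
      n_masked <- n_masked + sum(bad)
      vi <- epochs$valid[i, tr_idx, , drop = TRUE]
      vi[bad] <- FALSE
      epochs$valid[i, tr_idx, ] <- vi
    }
  }
  epochs$n_masked <- n_masked
  epochs
}

#' Full preprocessing of one session
#'
#' Runs the fixed pipeline: notch filter, common-average re-reference, HFB
#' z-power, trial exclusions, epoching with baseline correction and
#' smoothing, and timepoint-outlier masking.
#'
#' @param session An `hfb_session` (or list with `recording` and `events`).
#' @param config Preprocessing configuration.
#' @param mask_outliers Apply [mask_timepoint_outliers()]?
#' @return An `hfb_epochs`.
#' @export
preprocess_session <- function(session, config = preprocess_config(),
                               mask_outliers = TRUE) {
  rec <- session$recording
  if (is.null(rec)) stopf("preprocess_session: session has no recording")
  rec <- notch_filter(rec, config$notch_bands)
  rec <- rereference_common_average(rec)
  hfb <- hfb_power(rec, config)
  ev <- apply_trial_exclusions(session$events, config)
  ep <- epoch_baseline_smooth(hfb, rec$channels, ev, config)
  if (mask_outliers) ep <- suppressWarnings(mask_timepoint_outliers(ep))
  attr(ep, "exclusions") <- attr(ev, "exclusions")
  ep
}
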