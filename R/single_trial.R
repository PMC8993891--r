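# Single-trial activation detection: a sliding +/-10 ms window test of
# evoked HFB power against the trial's pre-stimulus baseline, corrected
# jointly across timepoints, trials and sites by Benjamini-Yekutieli FDR,
# with a 50-ms persistence rule and extraction of five metrics (onset,
# peak, offset latency, duration, peak power).
#
# Smoothed HFB samples are strongly serially correlated, so a textbook
# two-sample test that counts window samples as independent is grossly
# anticonservative. The detector therefore standardises the window mean
# by the site's pooled across-trial baseline variance with
# effective-sample-size factors computed from the baseline
# autocorrelation function (see the methods vignette): the test statistic
# is (window mean - trial baseline mean) / sqrt(sigma2 * (kappa_w +
# kappa_b)), with degrees of freedom from the pooled baseline.

# Pooled baseline statistics for one site: variance, autocorrelation,
# effective-sample-size factors, pooled df.
#' @noRd
site_baseline_stats <- function(epochs, site, max_lag = 60) {
  bi <- epochs$baseline_idx
  n_tr <- dim(epochs$hfb)[2]
  segs <- lapply(seq_len(n_tr), function(j) {
    b <- epochs$hfb[site, j, bi]
    b[epochs$valid[site, j, bi]]
  })
  segs <- segs[vapply(segs, length, 0L) >= 10]
  if (!length(segs)) stopf("site %d: no valid baseline samples", site)
  pooled <- unlist(lapply(segs, function(b) b - mean(b)))
  sig2 <- var(pooled)
  ml <- min(max_lag, min(vapply(segs, length, 0L)) - 2)
  acs <- vapply(segs, function(b)
    as.numeric(acf(b, lag.max = ml, plot = FALSE)$acf), numeric(ml + 1))
  rho <- rowMeans(acs)
  # the centered acf on short segments is biased low by ~1/n per lag;
  # the per-segment variance likewise loses ~tau/n of the marginal
  # variance -- correct both so the null t is properly scaled
  n_b <- min(vapply(segs, length, 0L))
  rho[-1] <- pmin(1, rho[-1] + 1 / n_b)
  tau <- max(1, 1 + 2 * sum(pmax(rho[-1], 0)))
  sig2 <- sig2 / max(0.5, 1 - tau / n_b)
  df_pool <- max(3, length(pooled) / tau - length(segs))
  kappa <- function(n) {
    if (n <= 0) return(NA_real_)
    l <- seq_len(n - 1)
    r <- ifelse(l <= ml, rho[l + 1], 0)
    max((n + 2 * sum((n - l) * r)) / n^2, 1e-8)
  }
  list(sig2 = sig2, rho = rho, df = df_pool, kappa = kappa,
       kappa_base = kappa(length(segs[[1]])))
}

#' Sliding-window activation p-values for one trial
#'
#' Tests each timepoint in `[0, rt + 200]` ms (intersected with the valid
#' mask) by comparing the mean of the valid samples in a +/-`half_width_ms`
#' window against the trial's baseline mean, standardised by the site's
#' pooled baseline variance with serial-correlation effective-sample-size
#' factors. Windows shrink at range edges; windows with fewer than 3 valid
#' samples get p = 1. Two-tailed p; the sign of the statistic is retained.
#'
#' @param epochs An `hfb_epochs`.
#' @param site Site index.
#' @param trial Trial index.
#' @param half_width_ms Window half-width (ms).
#' @param stats Optional precomputed [site] baseline statistics.
#' @return Data frame with `time_idx` (index into `epochs$time_ms`), `t`,
#'   `p`; empty when no timepoint is testable.
#' @export
sliding_window_pvals <- function(epochs, site, trial, half_width_ms = 10,
                                 stats = NULL) {
  if (is.null(stats)) stats <- site_baseline_stats(epochs, site)
  tm <- epochs$time_ms
  rt <- epochs$events$rt_ms[trial]
  upper <- if (is.na(rt)) max(tm) else rt + epochs$config$mask_post_rt_ms
  valid <- epochs$valid[site, trial, ]
  test_idx <- which(tm >= 0 & tm <= upper & valid)
  if (!length(test_idx))
    return(data.frame(time_idx = integer(), t = numeric(), p = numeric()))
  x <- epochs$hfb[site, trial, ]
  bi <- epochs$baseline_idx
  bvalid <- epochs$valid[site, trial, bi]
  xb <- mean(x[bi][bvalid])
  lo_rng <- min(test_idx); hi_rng <- max(test_idx)
  hw <- round(half_width_ms / 1000 * epochs$fs)
  # restrict window samples to the tested range and the valid mask
  in_rng <- valid & seq_along(x) >= lo_rng & seq_along(x) <= hi_rng
  cs <- cumsum(ifelse(in_rng, x, 0))
  cn <- cumsum(as.numeric(in_rng))
  lo <- pmax(lo_rng, test_idx - hw); hi <- pmin(hi_rng, test_idx + hw)
  nw <- cn[hi] - ifelse(lo > 1, cn[lo - 1], 0)
  sw <- cs[hi] - ifelse(lo > 1, cs[lo - 1], 0)
  kw <- vapply(seq_len(2 * hw + 1), stats$kappa, 0)
  ok <- nw >= 3
  tt <- numeric(length(test_idx)); pp <- rep(1, length(test_idx))
  se <- sqrt(stats$sig2 * (kw[pmax(nw, 1)] + stats$kappa_base))
  tt[ok] <- (sw[ok] / nw[ok] - xb) / se[ok]
  pp[ok] <- 2 * pt(-abs(tt[ok]), stats$df)
  data.frame(time_idx = test_idx, t = tt, p = pp)
}

#' Joint FDR correction over one family
#'
#' Benjamini-Yekutieli adjustment pooled over all tested timepoints,
#' trials and sites of one correction family (by default one
#' participant's epochs).
#'
#' @param p Vector of raw p-values (pooled family).
#' @param alpha FDR level.
#' @return Logical significance vector (`adjusted p < alpha`), with the
#'   adjusted p-values in attribute `"p_adj"`.
#' @export
joint_fdr <- function(p, alpha = 0.05) {
  if (!length(p)) stopf("joint_fdr: empty p-value family")
  adj <- fdr_by(p)
  structure(!is.na(adj) & adj < alpha, p_adj = adj)
}

#' Enforce the 50-ms persistence rule
#'
#' Clears every maximal run of `TRUE` values shorter than `min_ms`
#' (runs are broken by `FALSE`/`NA`, so invalid timepoints break runs).
#' A run of exactly `min_ms` is kept.
#'
#' @param sig_mask Logical vector on the epoch time grid.
#' @param min_ms Minimum run duration (ms).
#' @param step_ms Grid step (ms per sample).
#' @return The cleaned logical vector.
#' @export
enforce_min_run <- function(sig_mask, min_ms = 50, step_ms = 1) {
  out <- sig_mask
  out[is.na(out)] <- FALSE
  runs <- true_runs(out)
  short <- runs[runs$length * step_ms < min_ms, , drop = FALSE]
  for (r in seq_len(nrow(short)))
    out[short$start[r]:short$end[r]] <- FALSE
  out
}

#' Extract single-trial activation metrics
#'
#' Onset = first significant timepoint, offset = last, duration = number
#' of significant timepoints times the sample period (multiple runs
#' accumulate), peak = timepoint of the maximum smoothed HFB z among
#' significant timepoints (ties broken to the earliest), peak power = the
#' trace at the peak. When the mask is empty, `has_activation` is `FALSE`
#' and `peak_power_z` falls back to the maximum of the trace over the
#' valid `[0, rt]` window (needed by peak-power comparisons that include
#' non-activated trials).
#'
#' @param sig_mask Logical vector (after [enforce_min_run()]), activation
#'   polarity only.
#' @param trace Smoothed HFB z trace on the same grid.
#' @param time_ms Time axis (ms).
#' @param valid Logical validity vector (for the fallback peak power).
#' @param rt_ms Trial response time (ms).
#' @return One-row data frame of metrics.
#' @export
extract_metrics <- function(sig_mask, trace, time_ms,
                            valid = rep(TRUE, length(trace)), rt_ms = NA) {
  step_ms <- if (length(time_ms) > 1) diff(time_ms[1:2]) else 1
  sig <- which(sig_mask)
  if (length(sig)) {
    pk <- sig[which.max(trace[sig])]
    data.frame(has_activation = TRUE,
               onset_ms = time_ms[sig[1]],
               peak_ms = time_ms[pk],
               offset_ms = time_ms[sig[length(sig)]],
               duration_ms = length(sig) * step_ms,
               peak_power_z = trace[pk])
  } else {
    win <- !is.na(time_ms) & time_ms >= 0 &
      (if (is.na(rt_ms)) TRUE else time_ms <= rt_ms) & valid
    pk <- if (any(win)) max(trace[win]) else NA_real_
    data.frame(has_activation = FALSE, onset_ms = NA_real_,
               peak_ms = NA_real_, offset_ms = NA_real_,
               duration_ms = NA_real_, peak_power_z = pk)
  }
}

#' Run the single-trial analysis
#'
#' Composes the sliding-window tests, the joint BY-FDR correction (family:
#' all tested timepoints x trials x sites in `epochs`, both tails pooled),
#' the 50-ms persistence rule, and metric extraction for every site and
#' trial. Metrics are defined for activations (positive deflections);
#' significant deactivation time is reported per trial as
#' `deactive_ms`.
#'
#' @param epochs An `hfb_epochs` (one participant).
#' @param alpha FDR level.
#' @param half_width_ms Sliding-window half-width (ms).
#' @param min_run_ms Persistence threshold (ms).
#' @param keep_masks Keep the per-trial significance masks (attribute
#'   `"sig_mask"`, site x trial x time array)?
#' @return Data frame of `ActivationMetrics` rows: `site_id`, `roi`,
#'   `trial_id`, `condition`, `rt_ms`, the five metrics, `has_activation`,
#'   `deactive_ms`.
#' @export
run_single_trial <- function(epochs, alpha = 0.05, half_width_ms = 10,
                             min_run_ms = 50, keep_masks = FALSE) {
  n_s <- dim(epochs$hfb)[1]; n_tr <- dim(epochs$hfb)[2]
  step_ms <- 1000 / epochs$fs
  res <- vector("list", n_s)
  for (i in seq_len(n_s)) {
    stats <- site_baseline_stats(epochs, i)
    res[[i]] <- lapply(seq_len(n_tr), function(j)
      sliding_window_pvals(epochs, i, j, half_width_ms, stats))
  }
  allp <- unlist(lapply(res, lapply, `[[`, "p"))
  sig <- if (length(allp)) joint_fdr(allp, alpha) else logical(0)

  masks <- if (keep_masks) array(FALSE, dim(epochs$hfb)) else NULL
  rows <- vector("list", n_s * n_tr)
  pos <- 0L; k0 <- 0L
  for (i in seq_len(n_s)) {
    for (j in seq_len(n_tr)) {
      pw <- res[[i]][[j]]
      n_k <- nrow(pw)
      s_ij <- if (n_k) sig[(k0 + 1):(k0 + n_k)] else logical(0)
      k0 <- k0 + n_k
      full_pos <- full_neg <- logical(dim(epochs$hfb)[3])
      full_pos[pw$time_idx] <- s_ij & pw$t > 0
      full_neg[pw$time_idx] <- s_ij & pw$t < 0
      full_pos <- enforce_min_run(full_pos, min_run_ms, step_ms)
      full_neg <- enforce_min_run(full_neg, min_run_ms, step_ms)
      if (keep_masks) masks[i, j, ] <- full_pos
      met <- extract_metrics(full_pos, epochs$hfb[i, j, ], epochs$time_ms,
                             epochs$valid[i, j, ], epochs$events$rt_ms[j])
      pos <- pos + 1L
      rows[[pos]] <- cbind(
        data.frame(site_id = epochs$channels$site_id[i],
                   roi = epochs$channels$roi[i],
                   participant_id = epochs$channels$participant_id[i],
                   trial_id = epochs$events$trial_id[j],
                   condition = epochs$events$condition[j],
                   rt_ms = epochs$events$rt_ms[j],
                   stringsAsFactors = FALSE),
        met,
        data.frame(deactive_ms = sum(full_neg) * step_ms))
    }
  }
  out <- do.call(rbind, rows[seq_len(pos)])
  rownames(out) <- NULL
  if (keep_masks) attr(out, "sig_mask") <- masks
  out
}
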