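# Trial-averaged analysis: per-timepoint evoked-power estimation against
# the pre-stimulus baseline, response labeling (active / deactive /
# nonresponsive), whole-brain time-window summaries, and grand-average
# ROI timecourses.
#
# The per-timepoint model is a mixed model with one dummy per timepoint
# and a per-trial random intercept over the baseline pool. Because every
# trial contributes the same balanced design (its baseline plus the
# timepoint sample), the GLS estimate of each dummy reduces exactly to
# the mean over trials of (timepoint value - trial baseline mean), i.e.
# a paired comparison; the epochs are already per-trial baseline
# corrected, so beta(t) is the cross-trial mean of the corrected trace
# and its p-value a paired t-test. The equivalence is verified against
# lme4 in the test suite.

#' @noRd
condition_trials <- function(epochs, condition) {
  if (condition == "mentalizing")
    which(epochs$events$condition %in% c("self", "other"))
  else which(epochs$events$condition == condition)
}

#' Evoked timecourse of one site and condition
#'
#' Estimates the mean evoked HFB power beta(t) relative to the trial
#' baseline for peri-stimulus timepoints (0 to the epoch end, subsampled
#' every `step_ms`), with cross-trial SE and a paired two-tailed p-value
#' per timepoint. Timepoints with fewer than `min_trials` valid trials are
#' not estimated.
#'
#' @param epochs An `hfb_epochs`.
#' @param site Site index.
#' @param condition Condition name; `"mentalizing"` pools self + other.
#' @param step_ms Evaluation grid step (ms).
#' @param min_trials Minimum valid trials per timepoint.
#' @return Data frame `time_ms`, `beta`, `se`, `p`, `n`; `NULL` (with a
#'   warning) when the condition has fewer than `min_trials` trials.
#' @export
fit_site_timecourse <- function(epochs, site, condition, step_ms = 2,
                                min_trials = 8) {
  tr <- condition_trials(epochs, condition)
  if (length(tr) < min_trials) {
    warnf("fit_site_timecourse: site %d '%s' has %d trials (< %d); skipped",
          site, condition, length(tr), min_trials)
    return(NULL)
  }
  tm <- epochs$time_ms
  grid <- which(tm >= 0)
  grid <- grid[seq(1, length(grid), by = max(1, round(step_ms * epochs$fs / 1000)))]
  m <- epochs$hfb[site, tr, grid, drop = TRUE]
  v <- epochs$valid[site, tr, grid, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = length(tr))
  if (is.null(dim(v))) v <- matrix(v, nrow = length(tr))
  m[!v] <- NA
  n <- colSums(!is.na(m))
  beta <- colMeans(m, na.rm = TRUE)
  s2 <- (colSums(m^2, na.rm = TRUE) - n * beta^2) / pmax(n - 1, 1)
  se <- sqrt(s2 / n)
  tt <- beta / se
  p <- 2 * pt(-abs(tt), n - 1)
  bad <- n < min_trials | !is.finite(se) | se == 0
  beta[n == 0] <- NA
  p[bad] <- NA
  data.frame(time_ms = tm[grid], beta = beta, se = se, p = p, n = n)
}

#' Label a site's response from its timecourse estimate
#'
#' `active` when only significantly positive timepoints exist, `deactive`
#' when only negative; when both polarities are significant, the polarity
#' of the greatest absolute deflection decides; `nonresponsive` otherwise.
#'
#' @param estimate Data frame from [fit_site_timecourse()] with a logical
#'   `sig` column (after FDR and persistence).
#' @return One of `"active"`, `"deactive"`, `"nonresponsive"`.
#' @export
label_response <- function(estimate) {
  if (is.null(estimate) || !any(estimate$sig %in% TRUE))
    return("nonresponsive")
  b <- estimate$beta[which(estimate$sig)]
  pos <- any(b > 0); neg <- any(b < 0)
  if (pos && !neg) return("active")
  if (neg && !pos) return("deactive")
  if (b[which.max(abs(b))] > 0) "active" else "deactive"
}

#' Trial-averaged response labels for all sites
#'
#' Fits every site's evoked timecourse per condition, applies BY-FDR per
#' condition across timepoints and sites, the 50-ms persistence rule, and
#' the response-labeling rule.
#'
#' @param epochs An `hfb_epochs`.
#' @param conditions Conditions to label; `"mentalizing"` pools self +
#'   other trials.
#' @param alpha FDR level.
#' @param step_ms Estimation grid step.
#' @param min_run_ms Persistence threshold (ms).
#' @return List: `labels` (data frame `site_id`, `roi`, `participant_id`,
#'   `condition`, `label`) and `timecourses` (nested list of estimate
#'   data frames with `p_adj` and `sig` columns).
#' @export
site_response_labels <- function(epochs,
                                 conditions = c("self", "other",
                                                "cognitive", "mentalizing"),
                                 alpha = 0.05, step_ms = 2,
                                 min_run_ms = 50) {
  n_s <- dim(epochs$hfb)[1]
  conditions <- intersect(conditions, c(unique(epochs$events$condition),
                                        "mentalizing"))
  tcs <- list(); labels <- list()
  for (cond in conditions) {
    ests <- lapply(seq_len(n_s), function(i)
      suppressWarnings(fit_site_timecourse(epochs, i, cond, step_ms)))
    pool <- unlist(lapply(ests, function(e) if (is.null(e)) NULL else e$p))
    adj <- fdr_by(pool)
    k0 <- 0
    for (i in seq_len(n_s)) {
      e <- ests[[i]]
      if (!is.null(e)) {
        nk <- nrow(e)
        e$p_adj <- adj[(k0 + 1):(k0 + nk)]
        k0 <- k0 + nk
        sig <- !is.na(e$p_adj) & e$p_adj < alpha
        e$sig <- enforce_min_run(sig, min_run_ms, step_ms)
        ests[[i]] <- e
      }
      labels[[length(labels) + 1]] <- data.frame(
        site_id = epochs$channels$site_id[i],
        roi = epochs$channels$roi[i],
        participant_id = epochs$channels$participant_id[i],
        condition = cond, label = label_response(e),
        stringsAsFactors = FALSE)
    }
    tcs[[cond]] <- ests
  }
  list(labels = do.call(rbind, labels), timecourses = tcs)
}

#' Time-window summary of evoked responses
#'
#' For each site, condition and half-open time window `[a, b)` ms,
#' compares the per-trial mean HFB power in the window (valid timepoints
#' only) against the baseline via a one-sample test of the
#' baseline-corrected means; signed t-values with BY-FDR across sites and
#' windows (per condition).
#'
#' @param epochs An `hfb_epochs`.
#' @param windows List of `c(start, end)` ms pairs.
#' @param conditions Conditions to summarise.
#' @param alpha FDR level.
#' @param min_trials Minimum contributing trials.
#' @return Data frame with `site_id`, `roi`, `condition`, `win_start`,
#'   `win_end`, `t`, `df`, `p`, `p_adj`, `sig`, `n`.
#' @export
time_window_summary <- function(epochs,
                                windows = list(c(0, 250), c(250, 500),
                                               c(500, 750), c(750, 1000),
                                               c(1000, 2000)),
                                conditions = c("self", "other", "cognitive"),
                                alpha = 0.05, min_trials = 8) {
  tm <- epochs$time_ms
  for (w in windows)
    if (w[2] > max(tm) + 1e-9) stopf("time_window_summary: window beyond epoch")
  conditions <- intersect(conditions, unique(epochs$events$condition))
  rows <- list()
  for (cond in conditions) {
    tr <- condition_trials(epochs, cond)
    for (i in seq_len(dim(epochs$hfb)[1])) {
      for (w in windows) {
        sel <- tm >= w[1] & tm < w[2]
        m <- epochs$hfb[i, tr, sel, drop = TRUE]
        v <- epochs$valid[i, tr, sel, drop = TRUE]
        if (is.null(dim(m))) { m <- matrix(m, nrow = length(tr)); v <- matrix(v, nrow = length(tr)) }
        m[!v] <- NA
        means <- rowMeans(m, na.rm = TRUE)
        means <- means[is.finite(means)]
        n <- length(means)
        if (n < min_trials || sd(means) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            site_id = epochs$channels$site_id[i],
            roi = epochs$channels$roi[i], condition = cond,
            win_start = w[1], win_end = w[2], t = NA_real_, df = NA_real_,
            p = NA_real_, n = n, stringsAsFactors = FALSE)
          next
        }
        tt <- mean(means) / (sd(means) / sqrt(n))
        rows[[length(rows) + 1]] <- data.frame(
          site_id = epochs$channels$site_id[i],
          roi = epochs$channels$roi[i], condition = cond,
          win_start = w[1], win_end = w[2], t = tt, df = n - 1,
          p = 2 * pt(-abs(tt), n - 1), n = n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (cond in unique(out$condition)) {
    sel <- out$condition == cond
    out$p_adj[sel] <- fdr_by(out$p[sel])
  }
  out$sig <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Grand-average ROI timecourse
#'
#' Pools baseline-corrected single-trial HFB timecourses over the
#' responsive (active or deactive) sites of one ROI, estimating beta(t)
#' over `[0, t_max]` ms with site- (and participant-) level random
#' intercepts via lme4; with a single contributing site the estimate
#' reduces to that site's paired timecourse.
#'
#' @param sessions List of lists with elements `epochs` (an `hfb_epochs`)
#'   and `labels` (from [site_response_labels()]).
#' @param roi ROI name.
#' @param condition Condition (`"mentalizing"` pools self + other).
#' @param step_ms Evaluation grid step (ms).
#' @param t_max Upper limit of the estimated timecourse (ms).
#' @param min_trials Minimum pooled observations per timepoint.
#' @return Data frame `time_ms`, `beta`, `se`, `p`, `n_obs`, `n_sites`,
#'   or `NULL` when the ROI has no responsive site.
#' @export
grand_average_roi <- function(sessions, roi, condition, step_ms = 20,
                              t_max = 3000, min_trials = 8) {
  dat <- list()
  for (ses in sessions) {
    ep <- ses$epochs
    lab <- ses$labels$labels %||% ses$labels
    ok <- lab$condition == condition & lab$roi == roi &
      lab$label %in% c("active", "deactive")
    sites <- match(lab$site_id[ok], ep$channels$site_id)
    if (!length(sites)) next
    tr <- condition_trials(ep, condition)
    tm <- ep$time_ms
    grid <- which(tm >= 0 & tm <= t_max)
    grid <- grid[seq(1, length(grid),
                     by = max(1, round(step_ms * ep$fs / 1000)))]
    for (i in sites) {
      m <- ep$hfb[i, tr, grid, drop = TRUE]
      v <- ep$valid[i, tr, grid, drop = TRUE]
      if (is.null(dim(m))) { m <- matrix(m, nrow = length(tr)); v <- matrix(v, nrow = length(tr)) }
      m[!v] <- NA
      dat[[length(dat) + 1]] <- list(
        participant = ep$channels$participant_id[i],
        site = ep$channels$site_id[i], time_ms = tm[grid], m = m)
    }
  }
  if (!length(dat)) return(NULL)
  tm_grid <- dat[[1]]$time_ms
  n_sites <- length(unique(vapply(dat, `[[`, "", "site")))
  multi_p <- length(unique(vapply(dat, `[[`, "", "participant"))) > 1
  out <- data.frame(time_ms = tm_grid, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n_obs = 0L, n_sites = n_sites)
  for (k in seq_along(tm_grid)) {
    y <- unlist(lapply(dat, function(d) d$m[, k]))
    site <- rep(vapply(dat, `[[`, "", "site"),
                vapply(dat, function(d) nrow(d$m), 0L))
    part <- rep(vapply(dat, `[[`, "", "participant"),
                vapply(dat, function(d) nrow(d$m), 0L))
    ok <- is.finite(y)
    y <- y[ok]; site <- site[ok]; part <- part[ok]
    if (length(y) < min_trials) next
    out$n_obs[k] <- length(y)
    if (n_sites == 1) {
      out$beta[k] <- mean(y)
      out$se[k] <- sd(y) / sqrt(length(y))
      tt <- out$beta[k] / out$se[k]
      out$p[k] <- 2 * pt(-abs(tt), length(y) - 1)
    } else {
      df_ <- data.frame(y = y, site = site, part = part)
      fml <- if (multi_p) y ~ 1 + (1 | part) + (1 | site) else
        y ~ 1 + (1 | site)
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lmerTest::lmer(fml, data = df_,
                         control = lme4::lmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
      if (is.null(fit)) {
        out$beta[k] <- mean(y); out$se[k] <- sd(y) / sqrt(length(y))
        tt <- out$beta[k] / out$se[k]
        out$p[k] <- 2 * pt(-abs(tt), length(y) - 1)
      } else {
        cf <- summary(fit)$coefficients
        out$beta[k] <- cf[1, "Estimate"]; out$se[k] <- cf[1, "Std. Error"]
        out$p[k] <- cf[1, "Pr(>|t|)"]
      }
    }
  }
  out
}
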