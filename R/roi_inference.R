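# Aggregate ROI analyses of the single-trial metrics: robust outlier
# filtering, per-ROI mixed models of mentalizing type / RT / choice
# effects, pairwise ROI latency comparisons, the onset -> specificity
# logistic classification, second-level onset-vs-effect-size models, and
# the mPFC offset-vs-RT contrast. Mixed models are fitted with
# lme4/lmerTest (Satterthwaite df); on failure the random structure is
# simplified down a fixed ladder and the structure actually used is
# recorded in the result.

#' Merge single-trial metrics with behavioral covariates
#'
#' Joins the metrics table with each session's event covariates (vd1,
#' vd2, choice, trait valence) and adds the model codings: `type_os`
#' (+1/2 other, -1/2 self), `choice_tf` (+1/2 true, -1/2 false).
#'
#' @param metrics Row-bound [run_single_trial()] tables.
#' @param sessions List of `hfb_session`s (or any lists with `events` and
#'   `participant_id`).
#' @return The metrics table with covariate columns.
#' @export
build_inference_table <- function(metrics, sessions) {
  evs <- do.call(rbind, lapply(sessions, function(s)
    cbind(participant_id = s$participant_id,
          s$events[, c("trial_id", "vd1", "vd2", "choice",
                       "trait_valence")])))
  out <- merge(metrics, evs, by = c("participant_id", "trial_id"),
               sort = FALSE)
  out$type_os <- ifelse(out$condition == "other", 0.5,
                        ifelse(out$condition == "self", -0.5, NA))
  out$choice_tf <- ifelse(out$choice == "true", 0.5,
                          ifelse(out$choice == "false", -0.5, NA))
  out
}

#' @noRd
metric_columns <- function() {
  c(onset = "onset_ms", peak = "peak_ms", offset = "offset_ms",
    duration = "duration_ms", peak_power = "peak_power_z")
}

#' Robust multi-site outlier filtering
#'
#' Two-stage rule on mentalizing trials of mentalizing-active ROI sites
#' (trials with RT over 5000 ms are removed first). Stage 1, per site and
#' metric: bisquare robust regression of the metric on RT; observations
#' with residuals beyond `mad_thr` scaled MADs are discarded (set `NA`).
#' Stage 2, per ROI and metric: the same rule pooled over all
#' mentalizing-active sites of the ROI; sites with more than
#' `site_excl_frac` of their observations flagged in stage 2 are removed
#' entirely.
#'
#' @param data Table from [build_inference_table()].
#' @param profiles Site profiles from [classify_sites()].
#' @param mad_thr MAD threshold.
#' @param site_excl_frac Site-exclusion fraction.
#' @param min_obs Minimum observations for a site-level fit (smaller sites
#'   pass through unfiltered with a warning).
#' @return List: `data` (filtered; flagged cells `NA`, excluded sites
#'   dropped), `excluded_sites`, `n_flagged`.
#' @export
multisite_outlier_filter <- function(data, profiles, mad_thr = 3,
                                     site_excl_frac = 0.5, min_obs = 8) {
  act <- profiles$site_id[profiles$mentalizing == "active" &
                            profiles$roi != "none"]
  d <- data[data$site_id %in% act & !is.na(data$type_os) &
              !is.na(data$rt_ms) & data$rt_ms <= 5000, , drop = FALSE]
  if (!nrow(d)) return(list(data = d, excluded_sites = character(),
                            n_flagged = 0L))
  mc <- metric_columns()
  n_flagged <- 0L
  flag_fit <- function(value, rt) {
    ok <- is.finite(value) & is.finite(rt)
    flags <- rep(FALSE, length(value))
    if (sum(ok) < min_obs) return(list(flags = flags, enough = FALSE))
    fit <- tryCatch(bisquare_regress(cbind(1, rt[ok]), value[ok]),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(flags = flags, enough = FALSE))
    s <- mad_scaled(fit$residuals)
    if (s > 0) flags[ok] <- abs(fit$residuals) > mad_thr * s
    list(flags = flags, enough = TRUE)
  }
  # stage 1: per site
  for (m in mc) {
    for (s in unique(d$site_id)) {
      i <- which(d$site_id == s)
      r <- flag_fit(d[[m]][i], d$rt_ms[i])
      if (!r$enough) {
        if (m == mc[1])
          warnf("multisite_outlier_filter: site %s has < %d observations; unfiltered",
                s, min_obs)
        next
      }
      n_flagged <- n_flagged + sum(r$flags)
      d[[m]][i[r$flags]] <- NA
    }
  }
  # stage 2: per ROI pool; count site flag fractions
  site_flags <- setNames(numeric(length(unique(d$site_id))),
                         unique(d$site_id))
  site_tot <- site_flags
  for (m in mc) {
    for (roi in unique(d$roi)) {
      i <- which(d$roi == roi)
      r <- flag_fit(d[[m]][i], d$rt_ms[i])
      if (!r$enough) next
      n_flagged <- n_flagged + sum(r$flags)
      ok_i <- i[is.finite(d[[m]][i])]
      for (s in unique(d$site_id[i])) {
        in_site <- d$site_id[ok_i] == s
        site_tot[s] <- site_tot[s] + sum(in_site)
        site_flags[s] <- site_flags[s] + sum(r$flags[is.finite(d[[m]][i])][in_site])
      }
      d[[m]][i[r$flags]] <- NA
    }
  }
  frac <- ifelse(site_tot > 0, site_flags / site_tot, 0)
  excl <- names(frac)[frac > site_excl_frac]
  list(data = d[!d$site_id %in% excl, , drop = FALSE],
       excluded_sites = excl, n_flagged = n_flagged)
}

# Mixed-model ladder: try formulas in order, return the first fit that
# converges without error; singular fits are accepted but flagged.
#' @noRd
fit_lmm <- function(formulas, data, reml = TRUE) {
  for (k in seq_along(formulas)) {
    fml <- formulas[[k]]
    if (!any(grepl("\\|", deparse(fml)))) {
      fit <- tryCatch(lm(fml, data = data), error = function(e) NULL)
      if (!is.null(fit))
        return(list(fit = fit, formula = fml, mixed = FALSE,
                    singular = FALSE, rank = k))
      next
    }
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(fml, data = data, REML = reml))),
      error = function(e) NULL)
    if (!is.null(fit))
      return(list(fit = fit, formula = fml, mixed = TRUE,
                  singular = lme4::isSingular(fit), rank = k))
  }
  NULL
}

#' @noRd
lmm_effects <- function(lf, terms, rename = terms) {
  if (is.null(lf)) return(NULL)
  cf <- if (lf$mixed) summary(lf$fit)$coefficients else {
    s <- summary(lf$fit)$coefficients
    cbind(s[, 1:2, drop = FALSE], df = lf$fit$df.residual,
          `t value` = s[, 3], `Pr(>|t|)` = s[, 4])
  }
  rows <- lapply(seq_along(terms), function(i) {
    tn <- terms[i]
    if (!tn %in% rownames(cf)) return(NULL)
    effect_estimate(rename[i], cf[tn, 1], cf[tn, 2],
                    cf[tn, ncol(cf)], cf[tn, "df"])
  })
  do.call(rbind, rows)
}

#' Per-ROI mixed models of type, RT and choice effects
#'
#' Two companion models per ROI and metric, on mentalizing trials of the
#' filtered inference table: (i) the type model, `metric ~ type_os +
#' rt + vd1 + vd2` with a per-site random type slope, giving the
#' Type(Other-Self) effect controlled for RT and visual dissimilarity;
#' (ii) the behavior model, `metric ~ rt + choice_tf + vd1 + vd2` with a
#' per-site random RT slope, giving RT and Choice(True-False) effects.
#' Random intercepts are nested within site and participant; the ladder
#' simplifies the structure on convergence failure.
#'
#' @param data Filtered table (see [multisite_outlier_filter()]).
#' @param roi ROI name.
#' @param metric One of `"onset"`, `"peak"`, `"offset"`, `"duration"`,
#'   `"peak_power"`.
#' @param include_vd Include the visual-dissimilarity covariates?
#' @return List of class `roi_model`: `roi`, `metric`, `effects` (rows
#'   Type_Other-Self, RT_Behav, Choice_True-False, with `b`, `se`, `p`,
#'   `df`), `site_effects` (per-site BLUP slopes for type and RT),
#'   `n_obs`, `random_structure`.
#' @export
fit_roi_type_rt_choice <- function(data, roi, metric, include_vd = TRUE) {
  col <- metric_columns()[[metric]]
  d <- data[data$roi == roi & is.finite(data[[col]]) &
              !is.na(data$type_os) & is.finite(data$rt_ms), , drop = FALSE]
  if (nrow(d) < 20) stopf("fit_roi_type_rt_choice: too few observations (%d)",
                          nrow(d))
  d$value <- d[[col]]
  d$rt_c <- d$rt_ms - mean(d$rt_ms)
  d$usite <- d$site_id
  multi_p <- length(unique(d$participant_id)) > 1
  lad <- function(fixed, slope) {
    f <- function(re) stats::as.formula(paste("value ~", fixed, re))
    if (multi_p) list(
      f(sprintf("+ (1 + %s | usite) + (1 | participant_id)", slope)),
      f(sprintf("+ (1 + %s || usite) + (1 | participant_id)", slope)),
      f("+ (1 | usite) + (1 | participant_id)"),
      f("+ (1 | usite)"), f(""))
    else list(
      f(sprintf("+ (1 + %s | usite)", slope)),
      f(sprintf("+ (1 + %s || usite)", slope)),
      f("+ (1 | usite)"), f(""))
  }
  vd <- if (include_vd) " + vd1 + vd2" else ""
  f_type <- fit_lmm(lad(paste0("type_os + rt_c", vd), "type_os"), d)
  f_beh <- fit_lmm(lad(paste0("rt_c + choice_tf", vd), "rt_c"), d)
  eff <- rbind(
    lmm_effects(f_type, "type_os", "Type_Other-Self"),
    lmm_effects(f_beh, c("rt_c", "choice_tf"),
                c("RT_Behav", "Choice_True-False")),
    lmm_effects(f_beh, c("vd1", "vd2"), c("VD1", "VD2")))
  blup <- function(lf, term) {
    if (is.null(lf) || !lf$mixed) return(NULL)
    re <- lme4::ranef(lf$fit)$usite
    fe <- lme4::fixef(lf$fit)
    if (is.null(re) || !term %in% colnames(re)) return(NULL)
    setNames(fe[[term]] + re[[term]], rownames(re))
  }
  b_type <- blup(f_type, "type_os")
  b_rt <- blup(f_beh, "rt_c")
  sites <- unique(d$usite)
  site_effects <- data.frame(
    site_id = sites,
    participant_id = d$participant_id[match(sites, d$usite)],
    b_type = if (is.null(b_type)) NA_real_ else b_type[sites],
    b_rt = if (is.null(b_rt)) NA_real_ else b_rt[sites],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(roi = roi, metric = metric, effects = eff,
                 site_effects = site_effects, n_obs = nrow(d),
                 random_structure = c(
                   type = if (is.null(f_type)) NA else deparse1(f_type$formula),
                   behavior = if (is.null(f_beh)) NA else deparse1(f_beh$formula))),
            class = "roi_model")
}

#' @export
print.roi_model <- function(x, ...) {
  cat(sprintf("<roi_model> %s / %s (n = %d)\n", x$roi, x$metric, x$n_obs))
  print(x$effects, digits = 4)
  invisible(x)
}

#' Pairwise ROI latency comparison
#'
#' Within-trial ROI difference (`roiX - roiY`) of one activation metric,
#' controlled for RT, with random intercepts for participant and trial
#' within participant; restricted to participants contributing
#' mentalizing-active observations in both ROIs.
#'
#' @param data Filtered inference table (mentalizing-active ROI sites).
#' @param roiX,roiY ROI names.
#' @param metric Metric name.
#' @return One-row effect data frame, or `NULL` when no participant has
#'   observations in both ROIs.
#' @export
pairwise_roi_latency <- function(data, roiX, roiY, metric) {
  if (roiX == roiY)
    return(effect_estimate(paste0(roiX, "-", roiY), 0, 0, 1, Inf))
  col <- metric_columns()[[metric]]
  d <- data[data$roi %in% c(roiX, roiY) & is.finite(data[[col]]) &
              is.finite(data$rt_ms), , drop = FALSE]
  shared <- intersect(unique(d$participant_id[d$roi == roiX]),
                      unique(d$participant_id[d$roi == roiY]))
  if (!length(shared)) return(NULL)
  d <- d[d$participant_id %in% shared, , drop = FALSE]
  d$value <- d[[col]]
  d$roi_ind <- ifelse(d$roi == roiX, 0.5, -0.5)
  d$rt_c <- d$rt_ms - mean(d$rt_ms)
  d$ptrial <- paste(d$participant_id, d$trial_id)
  multi_p <- length(shared) > 1
  lad <- if (multi_p) list(
    value ~ roi_ind + rt_c + (1 | participant_id) + (1 | ptrial),
    value ~ roi_ind + rt_c + (1 | ptrial),
    value ~ roi_ind + rt_c)
  else list(value ~ roi_ind + rt_c + (1 | ptrial),
            value ~ roi_ind + rt_c)
  lf <- fit_lmm(lad, d)
  out <- lmm_effects(lf, "roi_ind", paste0(roiX, "-", roiY))
  out
}

#' All pairwise ROI comparisons for one metric
#'
#' @param data Filtered inference table.
#' @param metric Metric name.
#' @param rois ROIs to compare (default the six DMN ROIs + Visual present
#'   in the data).
#' @param alpha FDR level; BY correction across the unique pairs.
#' @return Data frame with one row per estimable pair: `roi_x`, `roi_y`,
#'   `b`, `se`, `p`, `df`, `p_adj`, `sig`.
#' @export
pairwise_roi_matrix <- function(data, metric, rois = NULL, alpha = 0.05) {
  rois <- rois %||% intersect(roi_levels(),
                              setdiff(unique(data$roi), "none"))
  rows <- list()
  for (i in seq_along(rois)) for (j in seq_along(rois)) {
    if (j <= i) next
    e <- pairwise_roi_latency(data, rois[i], rois[j], metric)
    if (is.null(e)) next
    rows[[length(rows) + 1]] <- data.frame(
      roi_x = rois[i], roi_y = rois[j], b = e$b, se = e$se, p = e$p,
      df = e$df, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adj <- fdr_by(out$p)
  out$sig <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

# Firth-penalized logistic regression (Jeffreys prior), used as the
# fallback under complete separation.
#' @noRd
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    I <- crossprod(X, XW)
    H <- XW %*% solve(I, t(X))
    h <- diag(H)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(I)))
  list(coefficients = as.numeric(beta), se = se, n_iter = it)
}

#' Logistic classification of specificity from onset latency
#'
#' Logistic mixed-effects model predicting mentalizing-specificity (vs
#' non-specificity) from each site's mean activation onset, with a
#' participant random intercept; the odds ratio gives the change in odds
#' per millisecond of onset. Complete separation (or glmer failure) falls
#' back to Firth-penalized logistic regression, flagged in the result.
#'
#' @param site_table Data frame with `onset_mean` (ms), `specific`
#'   (logical), `participant_id`.
#' @param center_ms Onset centering (ms) for numerical stability; the
#'   slope is unaffected.
#' @return List: `effect` (effect row with `or_value`), `method`,
#'   `separation`.
#' @export
onset_predicts_specificity <- function(site_table, center_ms = 400) {
  st <- site_table[is.finite(site_table$onset_mean) &
                     !is.na(site_table$specific), , drop = FALSE]
  if (sum(st$specific) < 2 || sum(!st$specific) < 2)
    stopf("onset_predicts_specificity: need >= 2 sites per class")
  st$x <- st$onset_mean - center_ms
  st$y <- as.numeric(st$specific)
  multi_p <- length(unique(st$participant_id)) > 1
  fit <- NULL
  if (multi_p) {
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::glmer(y ~ x + (1 | participant_id), data = st,
                  family = stats::binomial))),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    sep <- abs(cf["x", 1]) > 10 || cf["x", 2] > 100
    if (!sep) {
      eff <- effect_estimate("onset_ms", cf["x", 1], cf["x", 2],
                             cf["x", 4], nrow(st) - 2, or = TRUE)
      return(list(effect = eff, method = "glmer", separation = FALSE))
    }
  }
  g <- tryCatch(suppressWarnings(
    stats::glm(y ~ x, data = st, family = stats::binomial)),
    error = function(e) NULL)
  sep <- is.null(g) || !g$converged || any(abs(coef(g)) > 10)
  if (!sep) {
    cf <- summary(g)$coefficients
    eff <- effect_estimate("onset_ms", cf["x", 1], cf["x", 2], cf["x", 4],
                           g$df.residual, or = TRUE)
    return(list(effect = eff, method = "glm", separation = FALSE))
  }
  ff <- firth_logistic(cbind(1, st$x), st$y)
  z <- ff$coefficients[2] / ff$se[2]
  eff <- effect_estimate("onset_ms", ff$coefficients[2], ff$se[2],
                         2 * pnorm(-abs(z)), nrow(st) - 2, or = TRUE)
  list(effect = eff, method = "firth", separation = TRUE)
}

#' Second-level model: onset latency vs per-site effect size
#'
#' Regresses per-site random-effect sizes (BLUP slopes from
#' [fit_roi_type_rt_choice()]) on per-site mean onset latencies with a
#' participant random intercept.
#'
#' @param site_table Data frame with `onset_mean`, `effect`,
#'   `participant_id`.
#' @return One-row effect data frame.
#' @export
onset_vs_effect_size <- function(site_table) {
  st <- site_table[is.finite(site_table$onset_mean) &
                     is.finite(site_table$effect), , drop = FALSE]
  if (nrow(st) < 10) stopf("onset_vs_effect_size: need >= 10 sites, got %d",
                           nrow(st))
  st$x <- st$onset_mean - mean(st$onset_mean)
  multi_p <- length(unique(st$participant_id)) > 1
  lad <- if (multi_p) list(effect ~ x + (1 | participant_id), effect ~ x)
  else list(effect ~ x)
  lf <- fit_lmm(lad, st)
  lmm_effects(lf, "x", "onset_ms")
}

#' mPFC offset-to-response proximity contrast
#'
#' Models the per-trial gap between the behavioral response and the
#' activation offset (`rt - offset`, ms) with an ROI-group indicator
#' (+1/2 non-mPFC, -1/2 mPFC: a positive slope means non-mPFC offsets
#' precede the response by more, i.e. mPFC offsets more closely precede
#' it), with participant and trial-within-participant intercepts.
#'
#' @param data Filtered inference table with `offset_ms` and `rt_ms`.
#' @return One-row effect data frame.
#' @export
mpfc_offset_vs_rt <- function(data) {
  mpfc <- c("amPFC", "dmPFC", "vmPFC")
  d <- data[is.finite(data$offset_ms) & is.finite(data$rt_ms) &
              data$roi != "none", , drop = FALSE]
  if (!any(d$roi %in% mpfc)) stopf("mpfc_offset_vs_rt: no mPFC sites")
  d$gap <- d$rt_ms - d$offset_ms
  d$grp <- ifelse(d$roi %in% mpfc, -0.5, 0.5)
  d$ptrial <- paste(d$participant_id, d$trial_id)
  multi_p <- length(unique(d$participant_id)) > 1
  lad <- if (multi_p) list(
    gap ~ grp + (1 | participant_id) + (1 | ptrial),
    gap ~ grp + (1 | ptrial), gap ~ grp)
  else list(gap ~ grp + (1 | ptrial), gap ~ grp)
  lf <- fit_lmm(lad, d)
  lmm_effects(lf, "grp", "nonmPFC-mPFC_gap")
}
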