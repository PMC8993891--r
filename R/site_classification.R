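# Functional specificity and self/other selectivity of mentalizing-active
# sites. Decision rules combine trial-averaged response labels with
# direct bisquare robust-regression comparisons of single-trial peak
# power (all trials, including those with nonsignificant activations),
# BY-corrected across sites per comparison family.

#' Robust peak-power comparison between two conditions at one site
#'
#' Bisquare robust regression of single-trial peak power on a condition
#' indicator (+1/2 for `condA`, -1/2 for `condB`), so the slope is the
#' `condA - condB` peak-power difference.
#'
#' @param metrics Metrics table from [run_single_trial()].
#' @param site Site id.
#' @param condA,condB Condition names; `"mentalizing"` pools self + other.
#' @param min_trials Minimum trials per condition.
#' @return One-row effect data frame (`b`, `se`, `p`, `df`), or `NULL`
#'   when either condition has too few trials.
#' @export
compare_peak_power <- function(metrics, site, condA, condB,
                               min_trials = 8) {
  pick <- function(cond) {
    if (cond == "mentalizing") metrics$condition %in% c("self", "other")
    else metrics$condition == cond
  }
  sel <- metrics$site_id == site & !is.na(metrics$peak_power_z)
  a <- metrics$peak_power_z[sel & pick(condA)]
  b <- metrics$peak_power_z[sel & pick(condB)]
  if (length(a) < min_trials || length(b) < min_trials) return(NULL)
  y <- c(a, b)
  X <- cbind(intercept = 1,
             cond = c(rep(0.5, length(a)), rep(-0.5, length(b))))
  fit <- bisquare_regress(X, y)
  effect_estimate(paste0(condA, "-", condB), fit$coefficients["cond"],
                  fit$se[2], fit$p[2], fit$df)
}

#' Classify functional specificity of one site
#'
#' `mentalizing_specific` iff the site is mentalizing-active (collapsed
#' across self/other), NOT cognitive-active, and its mentalizing peak
#' power significantly exceeds the arithmetic peak power. Sites coactive
#' for mentalizing and arithmetic are `non_specific` regardless of peak
#' power differences, as are mentalizing-active sites with nonsignificant
#' power differences. Sites that are not mentalizing-active get
#' `not_applicable`.
#'
#' @param mentalizing_active,cognitive_active Logical.
#' @param power_sig Peak-power comparison significant (after FDR)?
#' @param power_b Peak-power slope (mentalizing - cognitive).
#' @return Specificity label.
#' @export
classify_specificity <- function(mentalizing_active, cognitive_active,
                                 power_sig, power_b) {
  if (!isTRUE(mentalizing_active)) return("not_applicable")
  if (isTRUE(cognitive_active)) return("non_specific")
  if (isTRUE(power_sig) && isTRUE(power_b > 0)) return("mentalizing_specific")
  "non_specific"
}

#' Classify self/other selectivity of one site
#'
#' Sites active for both mentalizing types are labeled by the self-other
#' peak-power comparison: `self_greater`, `other_greater`, or
#' `non_selective`. Sites active for exactly one type are `self_only` /
#' `other_only` when that type's peak power is significantly greater, and
#' `non_selective` otherwise. Sites active for neither type get
#' `not_applicable`.
#'
#' @param self_active,other_active Logical.
#' @param power_sig Self-other comparison significant (after FDR)?
#' @param power_b Peak-power slope (self - other).
#' @return Selectivity label.
#' @export
classify_selectivity <- function(self_active, other_active, power_sig,
                                 power_b) {
  self_active <- isTRUE(self_active); other_active <- isTRUE(other_active)
  if (!self_active && !other_active) return("not_applicable")
  if (self_active && other_active) {
    if (isTRUE(power_sig) && power_b > 0) return("self_greater")
    if (isTRUE(power_sig) && power_b < 0) return("other_greater")
    return("non_selective")
  }
  if (self_active && isTRUE(power_sig) && power_b > 0) return("self_only")
  if (other_active && isTRUE(power_sig) && power_b < 0) return("other_only")
  "non_selective"
}

#' Build per-site profiles (specificity + selectivity)
#'
#' Combines trial-averaged labels with the two peak-power comparison
#' families (mentalizing vs cognitive; self vs other), each BY-corrected
#' across sites, and applies the classification rules.
#'
#' @param metrics Metrics table from [run_single_trial()] (one or more
#'   participants row-bound).
#' @param labels Label table from [site_response_labels()] (`$labels`).
#' @param alpha FDR level for the peak-power comparisons.
#' @return Data frame: one row per site with labels per condition, the
#'   comparison estimates, `specificity` and `selectivity`.
#' @export
classify_sites <- function(metrics, labels, alpha = 0.05) {
  if (!is.null(labels$labels)) labels <- labels$labels
  sites <- unique(labels$site_id)
  lab_of <- function(site, cond) {
    l <- labels$label[labels$site_id == site & labels$condition == cond]
    if (length(l)) l[1] else "nonresponsive"
  }
  prof <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s,
               roi = labels$roi[labels$site_id == s][1],
               participant_id = labels$participant_id[labels$site_id == s][1],
               mentalizing = lab_of(s, "mentalizing"),
               self = lab_of(s, "self"), other = lab_of(s, "other"),
               cognitive = lab_of(s, "cognitive"),
               stringsAsFactors = FALSE)
  }))
  cmp_mc <- lapply(sites, function(s)
    compare_peak_power(metrics, s, "mentalizing", "cognitive"))
  cmp_so <- lapply(sites, function(s)
    compare_peak_power(metrics, s, "self", "other"))
  adj <- function(cmps) {
    p <- vapply(cmps, function(x) if (is.null(x)) NA_real_ else x$p, 0)
    fdr_by(p)
  }
  p_mc <- adj(cmp_mc); p_so <- adj(cmp_so)
  get_b <- function(cmps) vapply(cmps, function(x)
    if (is.null(x)) NA_real_ else x$b, 0)
  prof$pp_mz_cog_b <- get_b(cmp_mc)
  prof$pp_mz_cog_p_adj <- p_mc
  prof$pp_self_other_b <- get_b(cmp_so)
  prof$pp_self_other_p_adj <- p_so
  prof$specificity <- vapply(seq_len(nrow(prof)), function(i)
    classify_specificity(prof$mentalizing[i] == "active",
                         prof$cognitive[i] == "active",
                         !is.na(p_mc[i]) && p_mc[i] < alpha,
                         prof$pp_mz_cog_b[i]), "")
  prof$selectivity <- vapply(seq_len(nrow(prof)), function(i) {
    if (prof$mentalizing[i] != "active") return("not_applicable")
    classify_selectivity(prof$self[i] == "active",
                         prof$other[i] == "active",
                         !is.na(p_so[i]) && p_so[i] < alpha,
                         prof$pp_self_other_b[i])
  }, "")
  rownames(prof) <- NULL
  prof
}

#' Self- versus other-selective site counts in one ROI
#'
#' Self-selective = self_only + self_greater; other-selective =
#' other_only + other_greater. The two counts enter McNemar's chi-square
#' (Yates-corrected, df = 1) as the discordant cells.
#'
#' @param profiles Profile table from [classify_sites()].
#' @param roi ROI name (or `"whole_brain"` for all sites).
#' @return List: `n_self_selective`, `n_other_selective`, `test`
#'   (an `hfb_test`).
#' @export
selectivity_counts <- function(profiles, roi) {
  sel <- if (identical(roi, "whole_brain")) rep(TRUE, nrow(profiles))
  else profiles$roi == roi
  pr <- profiles[sel & profiles$mentalizing == "active", ]
  if (!nrow(pr)) stopf("selectivity_counts: no mentalizing-active sites in %s",
                       roi)
  n_self <- sum(pr$selectivity %in% c("self_only", "self_greater"))
  n_other <- sum(pr$selectivity %in% c("other_only", "other_greater"))
  list(n_self_selective = n_self, n_other_selective = n_other,
       test = mcnemar_yates(n_self, n_other))
}
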