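# Behavioral models: the self-positivity choice bias (logistic
# mixed-effects classification of true/false choices on trait valence and
# its interaction with mentalizing type) and the RT model (type, choice,
# their interaction, and visual-dissimilarity covariates). Valence is
# coded +1/2 (positive) / -1/2 (negative) and type +1/2 (self) / -1/2
# (other), so the interaction is positive when the valence bias is
# stronger during self-mentalizing.

#' @noRd
behavior_frame <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) {
    ev <- s$events
    ev$participant_id <- s$participant_id
    ev
  }))
}

#' Self-positivity choice bias model
#'
#' Logistic mixed-effects classification of choosing 'true' on trait
#' valence and valence x type, with random intercepts for trait within
#' participant. Odds ratios accompany each effect. Complete separation is
#' flagged (`separation = TRUE`, Firth fallback).
#'
#' @param sessions List of `hfb_session`s (or a single events data frame
#'   with a `participant_id` column).
#' @return List of class `behavior_model`: `effects` (valence,
#'   valence x type rows with `or_value`), `n`, `method`, `separation`.
#' @export
choice_bias_model <- function(sessions) {
  ev <- if (is.data.frame(sessions)) sessions else behavior_frame(sessions)
  d <- ev[ev$condition %in% c("self", "other") &
            ev$choice %in% c("true", "false") &
            ev$trait_valence %in% c("positive", "negative"), , drop = FALSE]
  if (!nrow(d)) stopf("choice_bias_model: no usable mentalizing trials")
  if (length(unique(d$trait_valence)) < 2)
    stopf("choice_bias_model: single-valence input")
  d$y <- as.numeric(d$choice == "true")
  d$val <- ifelse(d$trait_valence == "positive", 0.5, -0.5)
  d$type <- ifelse(d$condition == "self", 0.5, -0.5)
  d$vt <- d$val * d$type
  multi_p <- length(unique(d$participant_id)) > 1
  fml <- if (multi_p) y ~ val + vt + (1 | participant_id / trait) else
    y ~ val + vt + (1 | trait)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = d, family = stats::binomial))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    if (all(abs(cf[, 1]) < 10) && all(cf[, 2] < 100)) {
      eff <- rbind(
        effect_estimate("valence", cf["val", 1], cf["val", 2],
                        cf["val", 4], nrow(d) - 3, or = TRUE),
        effect_estimate("valence_x_type", cf["vt", 1], cf["vt", 2],
                        cf["vt", 4], nrow(d) - 3, or = TRUE))
      return(structure(list(effects = eff, n = nrow(d), method = "glmer",
                            separation = FALSE), class = "behavior_model"))
    }
  }
  ff <- firth_logistic(cbind(1, d$val, d$vt), d$y)
  z <- ff$coefficients[2:3] / ff$se[2:3]
  eff <- rbind(
    effect_estimate("valence", ff$coefficients[2], ff$se[2],
                    2 * pnorm(-abs(z[1])), nrow(d) - 3, or = TRUE),
    effect_estimate("valence_x_type", ff$coefficients[3], ff$se[3],
                    2 * pnorm(-abs(z[2])), nrow(d) - 3, or = TRUE))
  structure(list(effects = eff, n = nrow(d), method = "firth",
                 separation = TRUE), class = "behavior_model")
}

#' Response-time model
#'
#' Linear mixed model of RT on mentalizing type, choice, their
#' interaction, and the visual-dissimilarity covariates, with a
#' participant random intercept; also returns the RT cell means per type
#' and choice.
#'
#' @param sessions List of `hfb_session`s (or an events data frame with
#'   `participant_id`).
#' @return List of class `behavior_model`: `effects` (type, choice,
#'   type x choice, VD1, VD2), `cell_means`, `n`.
#' @export
rt_model <- function(sessions) {
  ev <- if (is.data.frame(sessions)) sessions else behavior_frame(sessions)
  d <- ev[ev$condition %in% c("self", "other") & is.finite(ev$rt_ms) &
            ev$choice %in% c("true", "false"), , drop = FALSE]
  if (!nrow(d)) stopf("rt_model: no usable mentalizing trials")
  d$type <- ifelse(d$condition == "self", 0.5, -0.5)
  d$ch <- ifelse(d$choice == "true", 0.5, -0.5)
  multi_p <- length(unique(d$participant_id)) > 1
  lad <- if (multi_p) list(
    rt_ms ~ type * ch + vd1 + vd2 + (1 | participant_id),
    rt_ms ~ type * ch + vd1 + vd2)
  else list(rt_ms ~ type * ch + vd1 + vd2)
  lf <- fit_lmm(lad, d)
  eff <- lmm_effects(lf, c("type", "ch", "type:ch", "vd1", "vd2"),
                     c("type_self-other", "choice_true-false",
                       "type_x_choice", "VD1", "VD2"))
  cm <- do.call(rbind, lapply(split(d, list(d$condition, d$choice)),
                              function(g) if (!nrow(g)) NULL else
                                data.frame(condition = g$condition[1],
                                           choice = g$choice[1],
                                           mean_rt = mean(g$rt_ms),
                                           se_rt = sd(g$rt_ms) / sqrt(nrow(g)),
                                           n = nrow(g))))
  rownames(cm) <- NULL
  structure(list(effects = eff, cell_means = cm, n = nrow(d)),
            class = "behavior_model")
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf("<behavior_model> n = %d trials\n", x$n))
  print(x$effects, digits = 4)
  if (!is.null(x$cell_means)) print(x$cell_means, digits = 4)
  invisible(x)
}
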