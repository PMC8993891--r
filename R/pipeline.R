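# End-to-end orchestration: simulate (or read) -> preprocess -> detect ->
# label -> classify -> ROI inference -> behavior, with per-stage logging
# of exclusion counts and a reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Runs every stage on a simulated study (or on sessions loaded with
#' [read_session()]): preprocessing, single-trial detection,
#' trial-averaged labeling, site classification, multi-site outlier
#' filtering, per-ROI mixed models, pairwise ROI comparisons, the
#' onset-to-specificity classification, behavioral models. Identical
#' seeds and configuration give identical outputs.
#'
#' @param sim A [sim_config()] (a study is simulated), or an `hfb_study`,
#'   or a list of `hfb_session`s.
#' @param out_dir Optional directory: result tables + manifest are
#'   written there with [write_results()].
#' @param alpha FDR level used throughout.
#' @param metrics_for_models Metrics analysed by the ROI models.
#' @param preprocess_cfg Preprocessing configuration.
#' @param verbose Log per-stage counts?
#' @return List of class `hfb_pipeline`: `metrics`, `labels`, `profiles`,
#'   `filtered`, `roi_models`, `pairwise`, `onset_specificity`,
#'   `behavior_choice`, `behavior_rt`, `log`.
#' @export
run_pipeline <- function(sim, out_dir = NULL, alpha = 0.05,
                         metrics_for_models = c("onset", "duration"),
                         preprocess_cfg = preprocess_config(),
                         verbose = TRUE) {
  log <- list()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log[[length(log) + 1]] <<- msg
    if (verbose) message(msg)
  }
  if (inherits(sim, "sim_config")) {
    say("simulate: %d participant(s), seed %s", sim$n_participants, sim$seed)
    study <- simulate_study(sim)
    sessions <- study$sessions
    cfg_for_manifest <- unclass(sim)
    seed <- sim$seed
  } else if (inherits(sim, "hfb_study")) {
    sessions <- sim$sessions
    cfg_for_manifest <- unclass(sim$config)
    seed <- sim$config$seed
  } else {
    sessions <- sim
    cfg_for_manifest <- list()
    seed <- NA
  }

  metrics <- list(); labels <- list(); processed <- list()
  for (ses in sessions) {
    ep <- preprocess_session(ses, preprocess_cfg)
    excl <- attr(ep, "exclusions")
    say("preprocess %s: %d sites, %d trials retained (%d excluded: %s)",
        ses$participant_id, dim(ep$hfb)[1], dim(ep$hfb)[2],
        length(unique(excl$trial_id)),
        paste(names(table(excl$reason)), table(excl$reason),
              sep = "=", collapse = ", "))
    mt <- run_single_trial(ep, alpha = alpha)
    say("detect %s: %d/%d site-trials with activations",
        ses$participant_id, sum(mt$has_activation), nrow(mt))
    lb <- site_response_labels(ep, alpha = alpha)
    processed[[ses$participant_id]] <- list(epochs = ep, labels = lb)
    metrics[[ses$participant_id]] <- mt
    labels[[ses$participant_id]] <- lb$labels
  }
  metrics <- do.call(rbind, metrics)
  labels <- do.call(rbind, labels)
  rownames(metrics) <- rownames(labels) <- NULL

  profiles <- classify_sites(metrics, labels, alpha = alpha)
  say("classify: %d mentalizing-active sites, %d mentalizing-specific",
      sum(profiles$mentalizing == "active"),
      sum(profiles$specificity == "mentalizing_specific"))

  infer <- build_inference_table(metrics, sessions)
  filt <- suppressWarnings(multisite_outlier_filter(infer, profiles))
  say("outlier filter: %d observations flagged, %d site(s) excluded",
      filt$n_flagged, length(filt$excluded_sites))

  roi_models <- list()
  for (m in metrics_for_models) {
    for (r in setdiff(unique(filt$data$roi), "none")) {
      key <- paste(r, m, sep = ".")
      roi_models[[key]] <- tryCatch(
        fit_roi_type_rt_choice(filt$data, r, m), error = function(e) NULL)
    }
  }
  pairwise <- lapply(setNames(nm = metrics_for_models), function(m)
    pairwise_roi_matrix(filt$data, m, alpha = alpha))

  onset_spec <- tryCatch({
    act <- profiles[profiles$mentalizing == "active" &
                      profiles$roi != "none", ]
    onset_by_site <- tapply(filt$data$onset_ms, filt$data$site_id,
                            mean, na.rm = TRUE)
    st <- data.frame(site_id = act$site_id,
                     participant_id = act$participant_id,
                     onset_mean = as.numeric(onset_by_site[act$site_id]),
                     specific = act$specificity == "mentalizing_specific")
    onset_predicts_specificity(st)
  }, error = function(e) NULL)

  beh_choice <- tryCatch(choice_bias_model(sessions), error = function(e) NULL)
  beh_rt <- tryCatch(rt_model(sessions), error = function(e) NULL)

  out <- structure(list(metrics = metrics, labels = labels,
                        profiles = profiles, filtered = filt,
                        roi_models = roi_models, pairwise = pairwise,
                        onset_specificity = onset_spec,
                        behavior_choice = beh_choice, behavior_rt = beh_rt,
                        processed = processed, log = unlist(log)),
                   class = "hfb_pipeline")
  if (!is.null(out_dir)) {
    tabs <- list(metrics = metrics, labels = labels, profiles = profiles)
    for (m in names(pairwise))
      if (!is.null(pairwise[[m]]))
        tabs[[paste0("pairwise_", m)]] <- pairwise[[m]]
    eff <- do.call(rbind, lapply(names(roi_models), function(k) {
      rm_ <- roi_models[[k]]
      if (is.null(rm_)) return(NULL)
      cbind(roi = rm_$roi, metric = rm_$metric, rm_$effects)
    }))
    if (!is.null(eff)) tabs$roi_effects <- eff
    write_results(tabs, out_dir, config = cfg_for_manifest, seed = seed)
  }
  out
}

#' @export
print.hfb_pipeline <- function(x, ...) {
  cat("<hfb_pipeline>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
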