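# End-to-end pipeline driver: simulate -> EEG features -> fNIRS features ->
# connectivity -> LOSO prediction -> coupling statistics.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. All randomness (cohort
#' generation, ICA initialisation, permutation draws) flows from the named
#' seeds here; there is no unseeded RNG use inside the pipeline.
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort to
#'   simulate, or an existing `synthetic_cohort` object.
#' @param pairs amplitude-modulation pairs to compute (default beta-m-alpha
#'   and gamma-m-alpha, the two wired into the connectivity stage).
#' @param apply_wica logical: run wICA artifact correction on the EEG.
#' @param wica a [wica_params()].
#' @param mbll a [mbll_params()].
#' @param alpha edge-selection significance level (default 0.05).
#' @param svr an [svr_spec()].
#' @param clip_predictions clip SVR output into \[0, 100\].
#' @param n_perm permutations per coupling comparison (default 10000).
#' @param seed master seed for the permutation stage.
#' @param out_dir optional directory; when given, every stage output plus the
#'   resolved configuration is written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, pairs = c("beta_m_alpha", "gamma_m_alpha"),
                            apply_wica = TRUE, wica = wica_params(),
                            mbll = mbll_params(), alpha = 0.05,
                            svr = svr_spec(), clip_predictions = FALSE,
                            n_perm = 10000, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec") ||
              inherits(cohort, "synthetic_cohort"))
  vp <- valid_modulation_pairs()$name
  if (!all(pairs %in% vp)) {
    stop("`pairs` must be valid carrier-m-modulator names", call. = FALSE)
  }
  structure(list(cohort = cohort, pairs = pairs,
                 apply_wica = isTRUE(apply_wica), wica = wica, mbll = mbll,
                 alpha = alpha, svr = svr,
                 clip_predictions = isTRUE(clip_predictions),
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' EEG feature chain for one subject
#'
#' Broadband 0.1-100 Hz Butterworth filtering, optional wICA cleaning, then
#' one amplitude-modulation series per requested pair.
#'
#' @param rec raw EEG [recording()].
#' @param pairs pair names (see [valid_modulation_pairs()]).
#' @param apply_wica logical.
#' @param wica a [wica_params()].
#' @return named list of `am_series`.
#' @export
process_eeg <- function(rec, pairs = c("beta_m_alpha", "gamma_m_alpha"),
                        apply_wica = TRUE, wica = wica_params()) {
  rec <- bandpass_broadband(rec)
  if (apply_wica) rec <- wica_clean(rec, wica)
  out <- lapply(pairs, function(p) amplitude_modulation(rec, p))
  stats::setNames(out, pairs)
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort if needed, extracts per-subject features, computes
#' the four connectivity matrices per subject, runs LOSO connectome-based
#' prediction and the CSS coupling analysis. Stage outputs are written to
#' `config$out_dir` when set (delimited matrices, JSON reports, the resolved
#' configuration, the ground truth).
#'
#' @param config a [pipeline_config()].
#' @return list with `prediction` ([loso_predict()] report), `coupling`
#'   ([coupling_analysis()] report), `cohort_table` and the simulated
#'   `cohort`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  spec <- cohort$spec

  mats <- lapply(cohort$subjects, function(subj) {
    sid <- subj$id
    stage_try <- function(stage, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed for subject %s: %s",
                     stage, sid, conditionMessage(e)), call. = FALSE)
      })
    }
    ams <- stage_try("eeg_features",
                     process_eeg(subj$eeg, config$pairs,
                                 config$apply_wica, config$wica))
    hb <- stage_try("fnirs_features", {
      if (inherits(subj$fnirs, "hb_series")) {
        subj$fnirs
      } else {
        process_fnirs(subj$fnirs$od_760, subj$fnirs$od_850, config$mbll)
      }
    })
    stage_try("connectivity", {
      out <- c(
        list(hbo = pearson_connectivity(hb, "hbo", subject_id = sid),
             hbr = pearson_connectivity(hb, "hbr", subject_id = sid)),
        lapply(ams, pearson_connectivity, subject_id = sid)
      )
      out
    })
  })
  perf <- vapply(cohort$subjects, `[[`, numeric(1), "performance")
  tab <- cohort_table(mats, perf)

  prediction <- loso_predict(tab, alpha = config$alpha, svr = config$svr,
                             clip = config$clip_predictions)
  coupling <- coupling_analysis(tab, prediction$fold_masks,
                                n_perm = config$n_perm, seed = config$seed)

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(config, cohort, tab, prediction, coupling)
  }
  list(prediction = prediction, coupling = coupling, cohort_table = tab,
       cohort = cohort)
}

resolved_config_list <- function(config) {
  spec <- if (inherits(config$cohort, "synthetic_cohort")) {
    config$cohort$spec
  } else config$cohort
  list(
    cohort_spec = unclass(spec),
    pairs = config$pairs,
    apply_wica = config$apply_wica,
    wica = unclass(config$wica),
    mbll = list(dpf_760 = config$mbll$dpf_760, dpf_850 = config$mbll$dpf_850,
                source_detector_distance = config$mbll$source_detector_distance,
                extinction = as.data.frame(config$mbll$extinction)),
    alpha = config$alpha, svr = unclass(config$svr),
    clip_predictions = config$clip_predictions,
    n_perm = config$n_perm, seed = config$seed
  )
}

write_pipeline_outputs <- function(config, cohort, tab, prediction, coupling) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  jsonlite::write_json(resolved_config_list(config), out("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(prediction$predictions, out("predictions.csv"))
  jsonlite::write_json(
    list(mae = prediction$mae, alpha = prediction$alpha,
         predictions = prediction$predictions),
    out("prediction_report.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(coupling$comparisons, out("coupling.csv"))
  jsonlite::write_json(
    list(comparisons = coupling$comparisons, css = coupling$css),
    out("coupling_report.json"), auto_unbox = TRUE, digits = NA)
  mat_dir <- out("matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  for (sid in tab$subjects) {
    for (m in tab$modalities) {
      v <- tab$matrices[[sid]][[m]]$values
      data.table::fwrite(as.data.frame(v),
                         file.path(mat_dir, sprintf("%s_%s.csv", sid, m)))
    }
  }
  jsonlite::write_json(
    list(performance = cohort$truth$performance,
         planted_edges = cohort$truth$planted_edges,
         planted_edge_targets = cohort$truth$planted_edge_targets),
    out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
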