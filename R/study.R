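#' Replicate study of LOOCV lateralization AUCs on simulated cohorts
#'
#' Repeatedly simulates an MR-negative cohort (by default 14 left-sided and
#' 10 right-sided patients whose asymmetry-index features are drawn from the
#' default group moments), runs the three LOOCV logistic models (T2, PET,
#' T2+PET) on each replicate, and records the AUC of the pooled held-out
#' probabilities per replicate. The replicate mean approximates the expected
#' small-cohort performance of each model under the generative group
#' distributions.
#'
#' @param n_replicates number of simulated cohorts.
#' @param groups generative parameter rows; default: the two MR-negative
#'   rows of [default_group_params()].
#' @param seed integer; replicate `r` uses seed `seed + r`.
#' @param penalty_c inverse ridge strength passed to the classifier.
#' @param ai_correlation within-subject correlation of the two AI features
#'   (0 = independent, the default).
#'
#' @return Tibble with columns `replicate`, `model`, `auc`, `mse`.
#' @export
replicate_auc_study <- function(n_replicates = 200,
                                groups = NULL,
                                seed = 1,
                                penalty_c = 1,
                                ai_correlation = 0) {
  if (is.null(groups)) {
    groups <- dplyr::filter(default_group_params(),
                            grepl("^MRneg", .data$group))
  }
  feature_sets <- list(
    T2 = "ai_t2", PET = "ai_suvr", `T2+PET` = c("ai_t2", "ai_suvr")
  )
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cohort <- generate_cohort_features(groups, seed = seed + r,
                                       ai_correlation = ai_correlation)
    purrr::imap_dfr(feature_sets, function(feats, nm) {
      res <- lateralize(cohort, feats, model_name = nm,
                        penalty_c = penalty_c)
      tibble::tibble(replicate = r, model = nm, auc = res$auc, mse = res$mse)
    })
  })
}

#' Summarise a replicate AUC study
#'
#' @param study output of [replicate_auc_study()].
#' @return Tibble with one row per model: mean/SD of AUC and MSE over
#'   replicates, plus the fraction of replicates where the combined model's
#'   AUC is at least each single modality's (reported on the `T2+PET` row as
#'   `combined_ge_both`).
#' @export
summarise_auc_study <- function(study) {
  out <- study |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
      mean_mse = mean(.data$mse), n_replicates = dplyr::n(),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(study[c("replicate", "model", "auc")],
                             names_from = "model", values_from = "auc")
  frac <- mean(wide$`T2+PET` >= wide$T2 & wide$`T2+PET` >= wide$PET)
  dplyr::mutate(out, combined_ge_both = ifelse(.data$model == "T2+PET",
                                               frac, NA_real_))
}
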