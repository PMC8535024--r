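#' Default subgroup definitions for the evaluation report
#'
#' Subgroups follow the clinical reporting scheme: all lesions, prostate
#' zone (PZ / TZ), focality (solitary / multifocal), PI-RADS score (3 / 4 /
#' 5), and index lesions stratified by PSA (< 4, 4-10, >= 10 ng/mL).
#'
#' @param records Lesion record tibble.
#' @return Named list of logical vectors over the rows of `records`.
#' @export
default_subgroups <- function(records) {
  list(all = rep(TRUE, nrow(records)),
       zone_PZ = records$zone == "PZ",
       zone_TZ = records$zone == "TZ",
       solitary = records$focality == "solitary",
       multifocal = records$focality == "multifocal",
       pirads_3 = records$pirads == 3,
       pirads_4 = records$pirads == 4,
       pirads_5 = records$pirads == 5,
       index_all = records$is_index,
       index_psa_lt4 = records$is_index & records$psa < 4,
       index_psa_4_10 = records$is_index & records$psa >= 4 & records$psa < 10,
       index_psa_ge10 = records$is_index & records$psa >= 10)
}

eval_one <- function(scores, labels, bootstrap_b, conf, seed) {
  ci <- bootstrap_auc_ci(scores, labels, B = bootstrap_b, conf = conf,
                         seed = seed)
  yp <- youden_point(scores, labels)
  pred <- as.integer(scores >= yp$threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens_ci <- wald_ci(yp$sensitivity, tp + fn, conf)
  spec_ci <- wald_ci(yp$specificity, tn + fp, conf)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  ppv_ci <- if (!is.na(ppv)) wald_ci(ppv, tp + fp, conf) else
    tibble(lower = NA_real_, upper = NA_real_)
  npv_ci <- if (!is.na(npv)) wald_ci(npv, tn + fn, conf) else
    tibble(lower = NA_real_, upper = NA_real_)
  tibble(auc = auc_mw(scores, labels), auc_lo = ci[["lower"]],
         auc_hi = ci[["upper"]], threshold = yp$threshold,
         sensitivity = yp$sensitivity, sens_lo = sens_ci$lower,
         sens_hi = sens_ci$upper, specificity = yp$specificity,
         spec_lo = spec_ci$lower, spec_hi = spec_ci$upper, ppv = ppv,
         ppv_lo = ppv_ci$lower, ppv_hi = ppv_ci$upper, npv = npv,
         npv_lo = npv_ci$lower, npv_hi = npv_ci$upper)
}

#' Evaluate and compare classifiers on a lesion cohort
#'
#' For each subgroup and model: AUC with percentile-bootstrap CI, the Youden
#' operating point with Wald CIs on sensitivity/specificity and PPV/NPV,
#' and, against the designated baseline model, the DeLong test on the paired
#' AUC difference plus McNemar tests on sensitivity (positives) and
#' specificity (negatives) at each model's own operating point. Subgroups
#' containing a single class are reported as not evaluable rather than
#' raising errors.
#'
#' @param predictions Tibble with columns `lesion_id`, `model`, `score`
#'   (long format, one row per lesion per model).
#' @param records Lesion record tibble (labels and subgroup metadata); only
#'   lesions present in `predictions` are evaluated.
#' @param baseline Model name the others are compared against (default
#'   "pirads_cla"; use NULL to skip paired comparisons).
#' @param bootstrap_b Bootstrap resamples for the AUC CI (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @param groups Named list of logical vectors over `records` rows; default
#'   [default_subgroups()].
#' @return Tibble of class `vt_eval`, one row per (group, model).
#' @export
evaluate_models <- function(predictions, records, baseline = "pirads_cla",
                            bootstrap_b = 1000L, conf = 0.95, seed = 1L,
                            groups = NULL) {
  records <- records[records$lesion_id %in% unique(predictions$lesion_id), ]
  if (nrow(records) == 0) abort("no overlapping lesions between predictions and records")
  if (is.null(groups)) groups <- default_subgroups(records)
  models <- unique(predictions$model)
  if (!is.null(baseline) && !baseline %in% models)
    abort(sprintf("baseline model '%s' has no predictions", baseline))
  # lesion x model score matrix aligned to records
  score_of <- function(model) {
    p <- predictions[predictions$model == model, ]
    s <- setNames(p$score, p$lesion_id)[records$lesion_id]
    if (anyNA(s)) abort(sprintf("model '%s' is missing predictions", model))
    unname(s)
  }
  scores <- lapply(setNames(models, models), score_of)
  labels <- records$label

  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]] & !is.na(groups[[g]])
    n_pos <- sum(labels[sel] == 1)
    n_neg <- sum(labels[sel] == 0)
    for (mod in models) {
      base_row <- tibble(group = g, model = mod, n = n_pos + n_neg,
                         n_pos = n_pos, n_neg = n_neg,
                         evaluable = n_pos > 0 && n_neg > 0)
      if (!base_row$evaluable) {
        rows[[length(rows) + 1]] <- base_row
        next
      }
      met <- eval_one(scores[[mod]][sel], labels[sel], bootstrap_b, conf,
                      seed + length(rows))
      cmp <- tibble(delta_auc = NA_real_, p_delong = NA_real_,
                    p_mcnemar_sens = NA_real_, p_mcnemar_spec = NA_real_,
                    discordant_sens = NA_integer_, discordant_spec = NA_integer_)
      if (!is.null(baseline) && mod != baseline) {
        sa <- scores[[mod]][sel]
        sb <- scores[[baseline]][sel]
        y <- labels[sel]
        dl <- delong_test(sa, sb, y)
        ta <- youden_point(sa, y)$threshold
        tb <- youden_point(sb, y)$threshold
        pa <- as.integer(sa >= ta)
        pb <- as.integer(sb >= tb)
        ms <- mcnemar_test(pa[y == 1] == 1, pb[y == 1] == 1)
        mp <- mcnemar_test(pa[y == 0] == 0, pb[y == 0] == 0)
        cmp <- tibble(delta_auc = dl$delta_auc, p_delong = dl$p_value,
                      p_mcnemar_sens = ms$p_value, p_mcnemar_spec = mp$p_value,
                      discordant_sens = ms$b + ms$c,
                      discordant_spec = mp$b + mp$c)
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(base_row, met, cmp)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- baseline
  attr(out, "roc") <- lapply(scores, function(s) roc_points(s, labels))
  class(out) <- c("vt_eval", class(out))
  out
}

#' @export
glance.vt_eval <- function(x, ...) {
  overall <- x[x$group == "all" & x$evaluable, ]
  none <- nrow(overall) == 0
  tibble(n_models = length(unique(x$model)), n_groups = length(unique(x$group)),
         n_lesions = max(x$n),
         best_model = if (none) NA_character_ else
           overall$model[which.max(overall$auc)],
         best_auc = if (none) NA_real_ else max(overall$auc))
}
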