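eval_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(61)
      n <- 120
      records <- tibble::tibble(
        lesion_id = sprintf("L%03d", 1:n),
        patient_id = sprintf("P%03d", 1:n),
        label = rbinom(n, 1, 0.55),
        pirads = sample(3:5, n, TRUE),
        zone = sample(c("PZ", "TZ"), n, TRUE, c(0.8, 0.2)),
        focality = sample(c("solitary", "multifocal"), n, TRUE),
        is_index = rep(TRUE, n),
        psa = round(rlnorm(n, log(7), 0.5), 1),
        split = "test")
      good <- rnorm(n) + 1.5 * records$label
      weak <- rnorm(n) + 0.5 * records$label
      preds <- dplyr::bind_rows(
        tibble::tibble(lesion_id = records$lesion_id, score = good,
                       model = "good"),
        tibble::tibble(lesion_id = records$lesion_id, score = weak,
                       model = "pirads_cla"))
      cache <<- list(records = records, preds = preds)
    }
    cache
  }
})

test_that("subgroups partition the cohort and carry paired comparisons", {
  fx <- eval_fixture()
  ev <- evaluate_models(fx$preds, fx$records, bootstrap_b = 50, seed = 2)
  expect_s3_class(ev, "vt_eval")
  pir <- ev[grepl("^pirads_", ev$group) & ev$model == "good", ]
  expect_equal(sum(pir$n), nrow(fx$records))
  all_row <- ev[ev$group == "all" & ev$model == "good", ]
  expect_true(all_row$evaluable)
  expect_true(all_row$auc > 0.5)
  expect_false(is.na(all_row$p_delong))
  base_row <- ev[ev$group == "all" & ev$model == "pirads_cla", ]
  expect_true(is.na(base_row$p_delong))
  expect_true(all(ev$auc_lo <= ev$auc & ev$auc <= ev$auc_hi, na.rm = TRUE))
})

test_that("single-class groups are reported as not evaluable", {
  fx <- eval_fixture()
  rec <- fx$records
  rec$label <- 1L
  ev <- evaluate_models(fx$preds, rec, bootstrap_b = 20, seed = 3)
  expect_true(all(!ev$evaluable))
  expect_false(isTRUE(any(ev$evaluable)))
  expect_equal(nrow(ev), length(default_subgroups(rec)) * 2)
})

test_that("PPV and NPV match a hand-built confusion table", {
  records <- tibble::tibble(
    lesion_id = sprintf("L%d", 1:8), patient_id = sprintf("P%d", 1:8),
    label = c(1, 1, 1, 1, 0, 0, 0, 0), pirads = rep(4L, 8),
    zone = "PZ", focality = "solitary", is_index = TRUE, psa = 5,
    split = "test")
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.3, 0.2, 0.1)
  preds <- tibble::tibble(lesion_id = records$lesion_id, score = scores,
                          model = "m")
  ev <- evaluate_models(preds, records, baseline = NULL, bootstrap_b = 20,
                        seed = 1, groups = list(all = rep(TRUE, 8)))
  thr <- ev$threshold[1]
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1 & records$label == 1)
  fp <- sum(pred == 1 & records$label == 0)
  tn <- sum(pred == 0 & records$label == 0)
  fn <- sum(pred == 0 & records$label == 1)
  expect_equal(ev$ppv[1], tp / (tp + fp))
  expect_equal(ev$npv[1], tn / (tn + fn))
})

test_that("evaluation JSON serialization is byte-stable", {
  fx <- eval_fixture()
  ev1 <- evaluate_models(fx$preds, fx$records, bootstrap_b = 30, seed = 5)
  ev2 <- evaluate_models(fx$preds, fx$records, bootstrap_b = 30, seed = 5)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_eval_json(ev1, f1)
  write_eval_json(ev2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
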