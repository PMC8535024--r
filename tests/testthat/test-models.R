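# shared small cohort for the model tests
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(phantom_config(n_patients = 36, seed = 77))
      r <- split_cohort(co$records, seed = 78)
      st <- extract_stacks(co)
      idx <- split(seq_len(nrow(r)), r$split)
      cache <<- list(co = co, r = r, st = st, idx = idx,
                     ft = feature_table(st, r))
    }
    cache
  }
})

test_that("the CNN has the documented layer plan and parameter count", {
  expect_equal(cnn_n_parameters(cnn_config()), 4221282L)
  # spatial arithmetic: 64 -> 32 -> 16 after the two pools drives the FC size
  expect_equal(cnn_n_parameters(cnn_config(fc_hidden = 1)),
               (32 * 26 * 9 + 32) + 64 + (64 * 32 * 9 + 64) + 128 +
                 (1 * 64 * 16 * 16 + 1) + (2 * 1 + 2))
})

test_that("CNN predictions are valid probabilities and deterministic", {
  fx <- model_fixture()
  fit <- train_cnn(fx$st[fx$r$lesion_id[fx$idx$train]],
                   fx$r$label[fx$idx$train],
                   fx$st[fx$r$lesion_id[fx$idx$validation]],
                   fx$r$label[fx$idx$validation],
                   cnn_config(epochs = 3, seed = 5))
  test_st <- fx$st[fx$r$lesion_id[fx$idx$test]]
  p1 <- predict(fit, test_st)
  p2 <- predict(fit, test_st)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_true(all(is.finite(fit$log$train_loss)))

  # the whole training run is a pure function of its seed
  fit2 <- train_cnn(fx$st[fx$r$lesion_id[fx$idx$train]],
                    fx$r$label[fx$idx$train],
                    fx$st[fx$r$lesion_id[fx$idx$validation]],
                    fx$r$label[fx$idx$validation],
                    cnn_config(epochs = 3, seed = 5))
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$log, fit2$log)
})

test_that("a zero learning rate leaves the initialization untouched", {
  fx <- model_fixture()
  cfg <- cnn_config(epochs = 1, lr = 0, seed = 9)
  fit <- train_cnn(fx$st[fx$r$lesion_id[fx$idx$train]],
                   fx$r$label[fx$idx$train],
                   fx$st[fx$r$lesion_id[fx$idx$validation]],
                   fx$r$label[fx$idx$validation], cfg)
  init <- withr::with_seed(cfg$seed, voltexture:::cnn_init_weights(cfg))
  for (nm in c("conv1_w", "conv2_w", "fc1_w", "fc2_w", "bn1_gamma",
               "bn2_beta")) {
    expect_equal(unname(fit$final_weights[[nm]]), unname(init[[nm]]),
                 tolerance = 1e-6)
  }
})

test_that("uniformly scaled class weights scale the loss by the same factor", {
  fx <- model_fixture()
  base <- cnn_config(epochs = 1, lr = 0, seed = 4, class_weights = c(1, 1))
  doubled <- cnn_config(epochs = 1, lr = 0, seed = 4, class_weights = c(2, 2))
  args <- list(fx$st[fx$r$lesion_id[fx$idx$train]], fx$r$label[fx$idx$train],
               fx$st[fx$r$lesion_id[fx$idx$validation]],
               fx$r$label[fx$idx$validation])
  l1 <- do.call(train_cnn, c(args, list(base)))$log$train_loss
  l2 <- do.call(train_cnn, c(args, list(doubled)))$log$train_loss
  expect_equal(l2, 2 * l1, tolerance = 1e-6)
})

test_that("training rejects a single-class training set", {
  fx <- model_fixture()
  pos <- fx$r$lesion_id[fx$r$label == 1][1:4]
  expect_error(train_cnn(fx$st[pos], rep(1, 4), fx$st[pos], rep(1, 4),
                         cnn_config(epochs = 1)), "both classes")
})

test_that("the loss stays finite across seeds", {
  fx <- model_fixture()
  for (seed in 1:3) {
    fit <- train_cnn(fx$st[fx$r$lesion_id[fx$idx$train]],
                     fx$r$label[fx$idx$train],
                     fx$st[fx$r$lesion_id[fx$idx$validation]],
                     fx$r$label[fx$idx$validation],
                     cnn_config(epochs = 2, seed = seed))
    expect_true(all(is.finite(fit$log$train_loss)))
  }
})

test_that("the unlimited-depth forest memorizes its training data and is seeded", {
  fx <- model_fixture()
  tr <- fx$ft[fx$idx$train, ]
  rf1 <- train_rf(tr, seed = 3)
  rf2 <- train_rf(tr, seed = 3)
  p_tr1 <- predict(rf1, tr)
  expect_gte(auc_mw(p_tr1$score, tr$label), 0.99)
  expect_identical(p_tr1, predict(rf2, tr))

  bad <- tr
  bad[[2]][1] <- NA_real_
  expect_error(train_rf(bad), "finite|missing")
  expect_error(predict(rf1, bad), "missing")
})

test_that("the PI-RADS rule thresholds at a score of 4", {
  recs <- tibble::tibble(lesion_id = c("a", "b", "c"), pirads = c(3L, 4L, 5L))
  expect_equal(pirads_cla(recs)$score, c(0, 1, 1))
  expect_error(pirads_cla(tibble::tibble(lesion_id = "a", pirads = NA)),
               "missing")
  expect_error(pirads_cla(tibble::tibble(lesion_id = "a", pirads = 2L)),
               "3, 4, or 5")
})

test_that("the rule's operating point approaches the PI-RADS confusion parameters", {
  # cheap minimal-size patches so a large cohort is fast to draw
  co <- generate_cohort(phantom_config(n_patients = 1800,
                                       lesions_per_patient = c(1, 1),
                                       patch_shape_range = c(4, 4), seed = 55))
  r <- co$records
  pred <- pirads_cla(r)
  sens <- mean(pred$score[r$label == 1] == 1)
  spec <- mean(pred$score[r$label == 0] == 0)
  conf <- default_pirads_confusion()
  expect_equal(sens, sum(conf[c("4", "5"), "pos"]), tolerance = 0.03)
  expect_equal(spec, conf["3", "neg"], tolerance = 0.03)
})

test_that("learned models beat the rule baseline on texture-separable phantoms", {
  fx <- model_fixture()
  te <- fx$idx$test
  y <- fx$r$label[te]
  rf <- train_rf(fx$ft[fx$idx$train, ], seed = 3)
  auc_rf <- auc_mw(predict(rf, fx$ft[te, ])$score, y)
  auc_rule <- auc_mw(pirads_cla(fx$r[te, ])$score, y)
  expect_gt(auc_rf, auc_rule)
})
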