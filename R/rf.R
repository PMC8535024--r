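#' Train the Haralick-feature random-forest baseline
#'
#' Random forest on the 104 directional Haralick features with the
#' conventional texture-baseline settings: 50 trees, Gini impurity, nodes
#' expanded until leaves are pure, bootstrap resampling. Scores are the
#' fraction of trees voting csPCa.
#'
#' @param features Feature tibble from [feature_table()] (columns
#'   `lesion_id`, features, `label`).
#' @param n_trees Number of trees (default 50).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `vt_rf` wrapping the fitted forest.
#' @export
train_rf <- function(features, n_trees = 50L, seed = 1L) {
  X <- as.data.frame(features[, setdiff(names(features), c("lesion_id", "label"))])
  if (any(!vapply(X, is.numeric, logical(1))) || anyNA(X) ||
      any(!is.finite(as.matrix(X))))
    abort("features must be finite numerics with no missing values")
  y <- factor(features$label, levels = 0:1)
  if (nlevels(droplevels(y)) < 2) abort("training set must contain both classes")
  fit <- withr::with_seed(seed, randomForest(
    x = X, y = y, ntree = n_trees, replace = TRUE, nodesize = 1L))
  structure(list(fit = fit, feature_names = names(X), n_trees = n_trees,
                 seed = seed), class = "vt_rf")
}

#' Predict csPCa probabilities with the random-forest baseline
#'
#' @param object A `vt_rf` from [train_rf()].
#' @param features Feature tibble with the same feature columns.
#' @param ... Unused.
#' @return Tibble with `lesion_id` and `score`.
#' @export
predict.vt_rf <- function(object, features, ...) {
  X <- as.data.frame(features[, object$feature_names])
  if (anyNA(X)) abort("features must not contain missing values")
  p <- predict(object$fit, X, type = "prob")[, "1"]
  tibble(lesion_id = features$lesion_id, score = unname(p))
}

#' @export
print.vt_rf <- function(x, ...) {
  cat(sprintf("<vt_rf> %d trees on %d features\n", x$n_trees,
              length(x$feature_names)))
  invisible(x)
}

#' @export
glance.vt_rf <- function(x, ...) {
  tibble(n_trees = x$n_trees, n_features = length(x$feature_names),
         oob_error = x$fit$err.rate[x$n_trees, "OOB"])
}

#' PI-RADS rule classifier (score >= 4 means csPCa)
#'
#' The radiologist-score baseline: a lesion is called csPCa iff its PI-RADS
#' score is 4 or 5. As a single-operating-point classifier its score is the
#' binary prediction itself (a two-level score), which is also how its AUC
#' is computed downstream.
#'
#' @param records Lesion record tibble with a `pirads` column in {3, 4, 5}.
#' @return Tibble with `lesion_id` and `score` in {0, 1}.
#' @export
pirads_cla <- function(records) {
  if (anyNA(records$pirads)) abort("missing PI-RADS score")
  if (!all(records$pirads %in% 3:5)) abort("PI-RADS scores must be 3, 4, or 5")
  tibble(lesion_id = records$lesion_id,
         score = as.numeric(records$pirads >= 4))
}
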