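#' Plot ROC curves of an evaluation
#'
#' @param object A `vt_eval` from [evaluate_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vt_eval <- function(object, ...) {
  roc <- attr(object, "roc")
  df <- dplyr::bind_rows(lapply(names(roc), function(m)
    mutate(roc[[m]], model = m)))
  overall <- object[object$group == "all" & object$evaluable, ]
  lab <- setNames(sprintf("%s (AUC %.2f)", overall$model, overall$auc),
                  overall$model)
  df$model <- lab[df$model]
  ggplot(df, aes(x = .data$fpr, y = .data$tpr, colour = .data$model)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity", colour = NULL) +
    theme_minimal()
}

#' Plot the CNN training log
#'
#' Per-epoch training loss and validation AUC; the selected checkpoint is
#' marked.
#'
#' @param object A `vt_cnn` from [train_cnn()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vt_cnn <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_auc"),
                            names_to = "metric")
  best <- tibble(epoch = object$best_epoch, metric = "val_auc",
                 value = object$best_val_auc)
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    geom_point(data = best, colour = "red") +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' Display the channels of a GLCM stack
#'
#' Heatmap of each direction-modality co-occurrence matrix (log scale).
#'
#' @param object A `vt_glcm_stack`.
#' @param channels Which channels to show (default first 13).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vt_glcm_stack <- function(object, channels = 1:13, ...) {
  nm <- attr(object, "channels")
  df <- dplyr::bind_rows(lapply(channels, function(i) {
    m <- object[, , i]
    tibble(x = as.vector(row(m)), y = as.vector(col(m)),
           p = as.vector(m), channel = nm[i])
  }))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = log10(.data$p + 1e-6))) +
    geom_raster() +
    facet_wrap(~channel) +
    scale_fill_viridis_c(name = "log10 P") +
    coord_equal() +
    labs(x = "level x", y = "level y") +
    theme_minimal()
}
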