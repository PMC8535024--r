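#' Configuration of the compact GLCM-stack CNN
#'
#' Architecture: conv 3x3 (26 -> 32, stride 1, padding 1) + batch norm +
#' ReLU, 2x2 max-pool, conv 3x3 (32 -> 64) + batch norm + ReLU, 2x2
#' max-pool, then two fully connected layers (flatten -> `fc_hidden` -> 2)
#' with a softmax head. Training minimizes class-weighted cross-entropy with
#' Adam.
#'
#' @param conv_channels Two (in, out) pairs for the convolutional layers.
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param lr Adam learning rate.
#' @param betas Adam (beta1, beta2).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param class_weights Per-class loss weights (NULL = inverse class
#'   frequency on the training split).
#' @param n_levels GLCM dimension (spatial size of the input channels).
#' @param seed Seed for weight initialization and epoch shuffling.
#' @return List of class `vt_cnn_config`.
#' @export
cnn_config <- function(conv_channels = list(c(26L, 32L), c(32L, 64L)),
                       fc_hidden = 256L, lr = 1e-5, betas = c(0.9, 0.999),
                       epochs = 200L, batch_size = 10L, class_weights = NULL,
                       n_levels = 64L, seed = 1L) {
  stopifnot(lr > 0 || lr == 0, epochs >= 1, batch_size >= 1,
            length(betas) == 2, n_levels %% 4 == 0)
  structure(list(conv_channels = conv_channels, fc_hidden = as.integer(fc_hidden),
                 lr = lr, betas = betas, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights, n_levels = as.integer(n_levels),
                 seed = as.integer(seed)),
            class = "vt_cnn_config")
}

# He-normal initialization; all randomness drawn from the current R RNG
cnn_init_weights <- function(config) {
  cc <- config$conv_channels
  L <- config$n_levels
  fc_in <- cc[[2]][2] * (L / 4)^2
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  list(conv1_w = he(cc[[1]][2], cc[[1]][1] * 9, cc[[1]][1] * 9),
       conv1_b = numeric(cc[[1]][2]),
       bn1_gamma = rep(1, cc[[1]][2]), bn1_beta = numeric(cc[[1]][2]),
       bn1_mean = numeric(cc[[1]][2]), bn1_var = rep(1, cc[[1]][2]),
       conv2_w = he(cc[[2]][2], cc[[2]][1] * 9, cc[[2]][1] * 9),
       conv2_b = numeric(cc[[2]][2]),
       bn2_gamma = rep(1, cc[[2]][2]), bn2_beta = numeric(cc[[2]][2]),
       bn2_mean = numeric(cc[[2]][2]), bn2_var = rep(1, cc[[2]][2]),
       fc1_w = he(config$fc_hidden, fc_in, fc_in),
       fc1_b = numeric(config$fc_hidden),
       fc2_w = he(2L, config$fc_hidden, config$fc_hidden),
       fc2_b = numeric(2L))
}

#' Number of learnable parameters of a CNN configuration
#'
#' Counts convolution and fully connected weights and biases plus batch-norm
#' scale/shift (running statistics excluded). At the defaults this is
#' 4,221,282.
#'
#' @param config A [cnn_config()].
#' @return Integer parameter count.
#' @export
cnn_n_parameters <- function(config = cnn_config()) {
  cc <- config$conv_channels
  L <- config$n_levels
  fc_in <- cc[[2]][2] * (L / 4)^2
  conv <- sum(vapply(cc, function(p) p[2] * p[1] * 9 + p[2], numeric(1)))
  bn <- sum(vapply(cc, function(p) 2 * p[2], numeric(1)))
  fc <- config$fc_hidden * fc_in + config$fc_hidden +
    2 * config$fc_hidden + 2
  as.integer(conv + bn + fc)
}

# stacks (list of (L, L, C) arrays) -> (C*L*L) x n matrix, channel planes
# contiguous, as the C++ kernels expect
stacks_to_matrix <- function(stacks) {
  stopifnot(length(stacks) > 0)
  vapply(stacks, function(s) as.vector(unclass(s)), numeric(length(stacks[[1]])))
}

#' Train the compact CNN on GLCM stacks
#'
#' Minimizes class-weighted cross-entropy with Adam and returns the epoch
#' checkpoint with the highest validation AUC (ties keep the earlier epoch).
#' The run is fully determined by the configuration seed: weight
#' initialization and per-epoch shuffling are drawn from it and the
#' numerical kernels are deterministic.
#'
#' @param train_stacks,val_stacks Named lists of [glcm_stack()] results.
#' @param train_labels,val_labels Binary labels (1 = csPCa), aligned with
#'   the stack lists.
#' @param config A [cnn_config()].
#' @return Object of class `vt_cnn`: best weights, final weights, per-epoch
#'   training log, and the configuration.
#' @export
train_cnn <- function(train_stacks, train_labels, val_stacks, val_labels,
                      config = cnn_config()) {
  train_labels <- as.integer(train_labels)
  val_labels <- as.integer(val_labels)
  if (length(unique(train_labels)) < 2)
    abort("training set must contain both classes")
  n <- length(train_stacks)
  stopifnot(length(train_labels) == n, length(val_stacks) == length(val_labels))
  cw <- config$class_weights
  if (is.null(cw)) {
    tab <- table(factor(train_labels, levels = 0:1))
    cw <- as.numeric(n / (2 * tab))
  }
  C <- config$conv_channels[[1]][1]
  L <- config$n_levels
  Xtr <- stacks_to_matrix(train_stacks)
  Xval <- stacks_to_matrix(val_stacks)
  if (nrow(Xtr) != C * L * L)
    abort("stack shape does not match conv_channels/n_levels")
  res <- withr::with_seed(config$seed, {
    w0 <- cnn_init_weights(config)
    order <- t(vapply(seq_len(config$epochs), function(e) sample.int(n),
                      integer(n)))
    cnn_train_cpp(Xtr, train_labels, Xval, val_labels, w0, cw, C, L,
                  config$epochs, config$batch_size, config$lr,
                  config$betas[1], config$betas[2], order)
  })
  structure(list(weights = res$weights, final_weights = res$final_weights,
                 log = tibble(epoch = seq_len(config$epochs),
                              train_loss = res$train_loss,
                              val_auc = res$val_auc),
                 best_epoch = res$best_epoch, best_val_auc = res$best_val_auc,
                 class_weights = cw, config = config),
            class = "vt_cnn")
}

#' Predict csPCa probabilities with a trained CNN
#'
#' Runs the network in evaluation mode (batch-norm statistics frozen at the
#' selected checkpoint).
#'
#' @param object A `vt_cnn` from [train_cnn()].
#' @param stacks Named list of GLCM stacks.
#' @param ... Unused.
#' @return Tibble with `lesion_id` and `score` = P(csPCa).
#' @export
predict.vt_cnn <- function(object, stacks, ...) {
  X <- stacks_to_matrix(stacks)
  s <- cnn_forward_cpp(X, object$weights, object$config$conv_channels[[1]][1],
                       object$config$n_levels, object$config$batch_size)
  tibble(lesion_id = names(stacks) %||% as.character(seq_along(stacks)),
         score = s)
}

#' @export
print.vt_cnn <- function(x, ...) {
  cat(sprintf("<vt_cnn> %d parameters, %d epochs, best val AUC %.3f (epoch %d)\n",
              cnn_n_parameters(x$config), x$config$epochs, x$best_val_auc,
              x$best_epoch))
  invisible(x)
}

#' @export
tidy.vt_cnn <- function(x, ...) x$log

#' @export
glance.vt_cnn <- function(x, ...) {
  tibble(n_parameters = cnn_n_parameters(x$config),
         epochs = x$config$epochs, best_epoch = x$best_epoch,
         best_val_auc = x$best_val_auc,
         final_train_loss = x$log$train_loss[nrow(x$log)])
}
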