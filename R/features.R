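#' Four Haralick descriptors of one normalized GLCM
#'
#' Standard definitions on a probability matrix P over level pairs (x, y):
#' contrast `sum P (x-y)^2`, homogeneity `sum P / (1 + (x-y)^2)`, energy
#' `sum P^2`, and correlation `sum P (x-mu_x)(y-mu_y) / (sd_x sd_y)` with
#' marginal moments. A point-mass GLCM (zero marginal variance) has
#' correlation 1 by convention, matching prevailing texture libraries.
#'
#' @param P Square nonnegative matrix; renormalized if its sum differs from 1
#'   by more than 1e-9 (an all-zero matrix is an error).
#' @return Named numeric vector (contrast, correlation, homogeneity, energy).
#' @export
haralick4 <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(P < 0)) abort("GLCM entries must be nonnegative")
  tot <- sum(P)
  if (tot == 0) abort("all-zero GLCM (no voxel pairs)")
  if (abs(tot - 1) > 1e-9) P <- P / tot
  n <- nrow(P)
  x <- matrix(seq_len(n), n, n)
  y <- t(x)
  d2 <- (x - y)^2
  contrast <- sum(P * d2)
  homogeneity <- sum(P / (1 + d2))
  energy <- sum(P^2)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(n) * px)
  muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))
  correlation <- if (sx * sy == 0) 1 else
    sum(P * (x - mux) * (y - muy)) / (sx * sy)
  c(contrast = contrast, correlation = correlation,
    homogeneity = homogeneity, energy = energy)
}

#' Haralick feature vector of a GLCM stack
#'
#' Concatenates the four descriptors over every stack channel in fixed
#' (modality, direction, descriptor) order; at the defaults (13 directions,
#' two modalities) this yields the 104-dimensional vector consumed by the
#' random-forest baseline. Names follow `<modality>_<direction>_<descriptor>`.
#'
#' @param stack A [glcm_stack()] result (normalized).
#' @return Named numeric vector of length `4 * n_channels`.
#' @export
feature_vector <- function(stack) {
  chans <- attr(stack, "channels")
  pcs <- attr(stack, "pair_counts")
  out <- numeric(0)
  for (i in seq_len(dim(stack)[3])) {
    if (pcs[i] == 0)
      abort(sprintf("channel %s has zero voxel pairs", chans[i]))
    h <- haralick4(stack[, , i])
    names(h) <- paste(chans[i], names(h), sep = "_")
    out <- c(out, h)
  }
  out
}

#' Haralick feature table for a cohort
#'
#' One row per lesion with the named feature columns plus the label, ready
#' for the random-forest baseline.
#'
#' @param stacks Named list of GLCM stacks keyed by lesion_id.
#' @param records Lesion record tibble (for labels), or NULL to omit labels.
#' @return Tibble with `lesion_id`, feature columns, and `label` if records
#'   are given.
#' @export
feature_table <- function(stacks, records = NULL) {
  feats <- map(stacks, feature_vector)
  tbl <- as_tibble(do.call(rbind, feats))
  tbl <- dplyr::bind_cols(tibble(lesion_id = names(stacks)), tbl)
  if (!is.null(records))
    tbl <- left_join(tbl, records[, c("lesion_id", "label")], by = "lesion_id")
  tbl
}
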