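#' Area under the ROC curve (Mann-Whitney form)
#'
#' `(#{pos > neg} + 0.5 #{pos = neg}) / (n_pos n_neg)`, computed via
#' midranks.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0 || n == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve points
#'
#' One row per distinct score threshold (rule: positive iff score >=
#' threshold), from the all-positive to the all-negative operating point.
#'
#' @inheritParams auc_mw
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tibble(threshold = thr,
         tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)),
         fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)))
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Lesion-level resampling with replacement; resamples containing a single
#' class are redrawn. The interval is the percentile interval of the `B`
#' resampled AUCs.
#'
#' @inheritParams auc_mw
#' @param B Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000L, conf = 0.95,
                             seed = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  run <- function() {
    n <- length(scores)
    stat <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      stat[b] <- auc_mw(scores[idx], labels[idx])
    }
    alpha <- (1 - conf) / 2
    q <- quantile(stat, c(alpha, 1 - alpha), names = FALSE)
    c(lower = q[1], upper = q[2])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Youden-index operating point
#'
#' Threshold (over observed scores, rule: positive iff score >= threshold)
#' maximizing sensitivity + specificity - 1. Ties are broken toward higher
#' sensitivity, then the lower threshold.
#'
#' @inheritParams auc_mw
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_point <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  J <- sens + spec - 1
  ord <- order(-J, -sens, thr)
  i <- ord[1]
  tibble(threshold = thr[i], sensitivity = sens[i], specificity = spec[i],
         youden = J[i])
}

#' Wald confidence interval for a proportion
#'
#' Normal approximation `p_hat +/- z sqrt(p_hat (1 - p_hat) / n)`, clipped
#' to [0, 1]. At the boundary (`p_hat` 0 or 1) the interval collapses to a
#' point, a documented limitation of the Wald form.
#'
#' @param p_hat Observed proportion(s).
#' @param n Denominator(s), >= 1.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `estimate`, `lower`, `upper` (one row per input).
#' @export
wald_ci <- function(p_hat, n, conf = 0.95) {
  if (any(n < 1)) abort("n must be >= 1")
  if (any(p_hat < 0 | p_hat > 1)) abort("p_hat must be in [0, 1]")
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n)
  tibble(estimate = p_hat, lower = pmax(0, p_hat - half),
         upper = pmin(1, p_hat + half))
}

# midrank structural components of the DeLong variance
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  rz <- rank(c(pos, neg), ties.method = "average")
  rx <- rank(pos, ties.method = "average")
  ry <- rank(neg, ties.method = "average")
  v10 <- (rz[seq_len(m)] - rx) / n
  v01 <- 1 - (rz[m + seq_len(n)] - ry) / m
  list(auc = (sum(rz[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' DeLong test for two paired AUCs
#'
#' Fast midrank implementation of the nonparametric comparison of two
#' correlated ROC areas; the p-value is two-sided normal on the paired AUC
#' difference. Identical score vectors give a zero difference and p = 1.
#'
#' @param scores_a,scores_b Paired scores of the two classifiers on the same
#'   lesions, in the same order.
#' @inheritParams auc_mw
#' @return Tibble with `auc_a`, `auc_b`, `delta_auc`, `statistic` (z),
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    abort("scores_a, scores_b and labels must be paired (equal length)")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10)
  n <- length(ca$v01)
  var1 <- function(x) if (length(x) < 2) 0 else var(x)
  s <- var1(ca$v10 - cb$v10) / m + var1(ca$v01 - cb$v01) / n
  delta <- ca$auc - cb$auc
  if (s <= 0) {
    # degenerate variance: identical structural components; only the
    # no-difference case carries a defined p-value
    z <- if (delta == 0) 0 else NA_real_
  } else {
    z <- delta / sqrt(s)
  }
  tibble(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta, statistic = z,
         p_value = 2 * pnorm(-abs(z)))
}

#' McNemar test on paired correctness indicators
#'
#' Compares two classifiers' per-lesion correctness (computed on positives
#' for sensitivity, on negatives for specificity). Uses the exact binomial
#' test on the discordant pairs when there are fewer than 25 of them,
#' otherwise the continuity-corrected chi-square; no discordant pairs gives
#' p = 1 by convention.
#'
#' @param correct_a,correct_b Equal-length logical/0-1 vectors.
#' @return Tibble with discordant counts `b` (A right, B wrong), `c` (A
#'   wrong, B right), `method`, `p_value`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b))
    abort("correctness vectors must be paired (equal length)")
  a <- as.logical(correct_a)
  bv <- as.logical(correct_b)
  b <- sum(a & !bv)
  cc <- sum(!a & bv)
  nd <- b + cc
  if (nd == 0) {
    return(tibble(b = b, c = cc, method = "none discordant", p_value = 1))
  }
  if (nd < 25) {
    p <- binom.test(b, nd, 0.5)$p.value
    method <- "exact binomial"
  } else {
    p <- mcnemar.test(matrix(c(0, cc, b, 0), 2, 2), correct = TRUE)$p.value
    method <- "chi-square (continuity corrected)"
  }
  tibble(b = b, c = cc, method = method, p_value = min(1, p))
}
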