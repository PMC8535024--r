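# Independent brute-force oracles used across tests. These deliberately use
# naive loops so they share no code with the implementation under test.

# co-occurrence counts by exhaustive enumeration of all voxel pairs
glcm_oracle <- function(vol, offset, n_levels) {
  d <- dim(vol)
  M <- matrix(0, n_levels, n_levels)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        ii <- i + offset[1]; jj <- j + offset[2]; kk <- k + offset[3]
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            kk >= 1 && kk <= d[3]) {
          x <- vol[i, j, k]; y <- vol[ii, jj, kk]
          M[x, y] <- M[x, y] + 1
        }
      }
    }
  }
  M
}

# four Haralick statistics by direct double-loop summation
haralick_oracle <- function(P) {
  P <- P / sum(P)
  n <- nrow(P)
  contrast <- homog <- energy <- 0
  mux <- muy <- 0
  for (x in 1:n) for (y in 1:n) {
    contrast <- contrast + P[x, y] * (x - y)^2
    homog <- homog + P[x, y] / (1 + (x - y)^2)
    energy <- energy + P[x, y]^2
    mux <- mux + x * P[x, y]
    muy <- muy + y * P[x, y]
  }
  sx2 <- sy2 <- covxy <- 0
  for (x in 1:n) for (y in 1:n) {
    sx2 <- sx2 + (x - mux)^2 * P[x, y]
    sy2 <- sy2 + (y - muy)^2 * P[x, y]
    covxy <- covxy + (x - mux) * (y - muy) * P[x, y]
  }
  corr <- if (sx2 * sy2 == 0) 1 else covxy / sqrt(sx2 * sy2)
  c(contrast = contrast, correlation = corr, homogeneity = homog,
    energy = energy)
}

# AUC by exhaustive pair counting
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden point by exhaustive sweep over candidate cutoffs
youden_oracle <- function(scores, labels) {
  thr <- c(sort(unique(scores)), Inf)
  best <- -Inf
  for (t in thr) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec - 1 > best + 1e-12) best <- sens + spec - 1
  }
  best
}

# small deterministic cohort shared by several test files
tiny_cohort <- function(n_patients = 16, seed = 42, ...) {
  generate_cohort(phantom_config(n_patients = n_patients, seed = seed, ...))
}

random_quantized <- function(dims, n_levels) {
  array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
}
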