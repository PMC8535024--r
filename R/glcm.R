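#' The 13 canonical 3D co-occurrence directions
#'
#' The 26 immediate neighbors of a voxel in 3D fall into 13 equivalence
#' classes under negation (a displacement and its opposite index the same
#' voxel pairs, transposed). The canonical representative of each class has
#' its first nonzero component equal to +1; the set is returned in fixed
#' lexicographic order of (di, dj, dk).
#'
#' @return 13 x 3 integer matrix of displacements, rows named `d01`..`d13`.
#' @export
canonical_directions <- function() {
  g <- as.matrix(expand.grid(dk = -1:1, dj = -1:1, di = -1:1))[, 3:1]
  keep <- apply(g, 1, function(d) {
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] == 1
  })
  d <- g[keep, , drop = FALSE]
  d <- d[order(d[, 1], d[, 2], d[, 3]), , drop = FALSE]
  dimnames(d) <- list(sprintf("d%02d", seq_len(nrow(d))), c("di", "dj", "dk"))
  storage.mode(d) <- "integer"
  d
}

#' Co-occurrence matrix of a quantized volume along one displacement
#'
#' Counts ordered voxel pairs: entry (x, y) is the number of voxels with
#' level x whose neighbor at displacement `offset` has level y. Pairs whose
#' neighbor falls outside the volume are skipped, so the total count is
#' `(I-|di|) (J-|dj|) (K-|dk|)`. A volume too small to hold any pair for the
#' displacement yields an all-zero matrix with `pair_count` 0.
#'
#' @param volume Integer 3D array with values in 1..n_levels (see
#'   [quantize()]).
#' @param offset Integer displacement `c(di, dj, dk)`, not all zero.
#' @param n_levels Number of gray levels; defaults to the `n_levels`
#'   attribute of `volume`, else `max(volume)`.
#' @return `n_levels` x `n_levels` count matrix with attribute `pair_count`.
#' @export
glcm_single <- function(volume, offset, n_levels = NULL) {
  stopifnot(length(dim(volume)) == 3, length(offset) == 3)
  offset <- as.integer(offset)
  if (all(offset == 0)) abort("offset must be nonzero")
  if (is.null(n_levels)) n_levels <- attr(volume, "n_levels") %||% max(volume)
  M <- glcm_single_cpp(as.integer(volume), dim(volume), offset,
                       as.integer(n_levels))
  attr(M, "pair_count") <- sum(M)
  M
}

#' 26-channel GLCM stack of a two-channel patch
#'
#' Computes one co-occurrence matrix per direction and per modality and
#' stacks them in fixed order: T2W directions 1..13 first, then ADC
#' directions 1..13. Accumulation follows the ordered-pair definition (along
#' +d only); `symmetric = TRUE` adds the transpose first (the common
#' Haralick convention). With `normalize = TRUE` each matrix is divided by
#' its own pair count, making the stack invariant to patch size.
#'
#' @param patch A `vt_patch` (list with `t2w` and `adc` 3D arrays) or any
#'   list of named channel arrays.
#' @param directions Displacement matrix, default [canonical_directions()].
#' @param n_levels Gray levels for quantization (default 64).
#' @param normalize Divide each matrix by its pair count (default TRUE).
#' @param symmetric Replace each matrix M by M + t(M) before normalization.
#' @return 3D array `(n_levels, n_levels, 2 * n_directions)` of class
#'   `vt_glcm_stack`, with attributes `pair_counts`, `channels`,
#'   `normalized`, `symmetric`, `directions`.
#' @export
glcm_stack <- function(patch, directions = canonical_directions(),
                       n_levels = 64L, normalize = TRUE, symmetric = FALSE) {
  chans <- patch[intersect(c("t2w", "adc"), names(patch))]
  if (length(chans) < 1) abort("patch must carry named channel arrays")
  q <- lapply(chans, function(ch) quantize(normalize_0_255(ch), n_levels))
  nd <- nrow(directions)
  n_channels <- length(q) * nd
  out <- array(0, c(n_levels, n_levels, n_channels))
  pair_counts <- numeric(n_channels)
  ch_names <- character(n_channels)
  idx <- 0L
  for (m in names(q)) {
    for (d in seq_len(nd)) {
      idx <- idx + 1L
      M <- glcm_single(q[[m]], directions[d, ], n_levels)
      pc <- attr(M, "pair_count")
      if (symmetric) {
        M <- M + t(M)
        pc <- 2 * pc
      }
      if (normalize && pc > 0) M <- M / pc
      out[, , idx] <- M
      pair_counts[idx] <- pc
      ch_names[idx] <- paste(m, rownames(directions)[d], sep = "_")
    }
  }
  structure(out, pair_counts = pair_counts, channels = ch_names,
            normalized = normalize, symmetric = symmetric,
            directions = directions, lesion_id = patch$lesion_id,
            class = "vt_glcm_stack")
}

#' @export
print.vt_glcm_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vt_glcm_stack> %d channels of %dx%d (%s, %s)\n", d[3], d[1],
              d[2], if (attr(x, "normalized")) "normalized" else "raw counts",
              if (attr(x, "symmetric")) "symmetric" else "ordered pairs"))
  invisible(x)
}

#' GLCM stacks for a whole cohort
#'
#' Applies [glcm_stack()] to every patch of a cohort.
#'
#' @param cohort A `vt_cohort` from [generate_cohort()] or [read_cohort()].
#' @inheritParams glcm_stack
#' @return Named list of `vt_glcm_stack`, keyed by lesion_id.
#' @export
extract_stacks <- function(cohort, n_levels = 64L, normalize = TRUE,
                           symmetric = FALSE) {
  lapply(cohort$patches, glcm_stack, n_levels = n_levels,
         normalize = normalize, symmetric = symmetric)
}
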