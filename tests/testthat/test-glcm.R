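test_that("the canonical direction set covers half of the 26-neighborhood", {
  d <- canonical_directions()
  expect_equal(nrow(d), 13)
  has <- function(off) any(apply(d, 1, function(r) all(r == off)))
  expect_true(has(c(0, 0, 1)))
  expect_true(has(c(1, 1, 1)))
  expect_false(has(c(0, 0, -1)))
  # no member is the negation of another; union with negations = 26 offsets
  all26 <- rbind(d, -d)
  expect_equal(nrow(unique(all26)), 26)
  expect_true(all(rowSums(abs(all26)) > 0))
  # canonical rule: first nonzero component is +1
  expect_true(all(apply(d, 1, function(r) r[which(r != 0)[1]] == 1)))
})

test_that("co-occurrence counts match the pair definition on simple volumes", {
  vol <- array(3L, c(3, 3, 3))
  M <- glcm_single(vol, c(0, 0, 1), n_levels = 4)
  expect_equal(M[3, 3], 18)
  expect_equal(sum(M), 18)  # 3*3*(3-1)

  set.seed(8)
  vol <- random_quantized(c(4, 4, 4), 4)
  for (i in seq_len(13)) {
    off <- canonical_directions()[i, ]
    expect_equal(glcm_single(vol, off, 4), glcm_oracle(vol, off, 4),
                 ignore_attr = TRUE)
    # reversing the displacement transposes the matrix
    expect_equal(unclass(glcm_single(vol, -off, 4)),
                 t(unclass(glcm_single(vol, off, 4))), ignore_attr = TRUE)
  }
  expect_error(glcm_single(vol, c(0, 0, 0), 4), "nonzero")
})

test_that("a volume too small for the displacement yields a flagged empty matrix", {
  vol <- array(1L, c(1, 3, 3))
  M <- glcm_single(vol, c(1, 0, 0), n_levels = 2)
  expect_equal(sum(M), 0)
  expect_equal(attr(M, "pair_count"), 0)
})

test_that("axis permutation of the volume permutes the displacement", {
  set.seed(13)
  vol <- random_quantized(c(5, 4, 6), 6)
  perm <- c(2, 1, 3)
  volp <- aperm(vol, perm)
  for (off in list(c(1, 0, 0), c(0, 1, -1), c(1, -1, 1))) {
    expect_equal(unclass(glcm_single(volp, off, 6)),
                 unclass(glcm_single(vol, off[perm], 6)), ignore_attr = TRUE)
  }
})

test_that("the stack has 26 ordered normalized channels", {
  co <- tiny_cohort(n_patients = 2)
  p <- co$patches[[1]]
  st <- glcm_stack(p)
  expect_s3_class(st, "vt_glcm_stack")
  expect_equal(dim(st), c(64, 64, 26))
  sums <- apply(st, 3, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(attr(st, "channels")[1], "t2w_d01")
  expect_equal(attr(st, "channels")[14], "adc_d01")

  # swapping the input channels swaps stack halves
  swapped <- glcm_stack(list(t2w = p$adc, adc = p$t2w))
  expect_equal(swapped[, , 1:13], st[, , 14:26])
  expect_equal(swapped[, , 14:26], st[, , 1:13])

  # symmetric accumulation adds the transpose before normalization
  raw <- glcm_stack(p, normalize = FALSE)
  sym <- glcm_stack(p, normalize = FALSE, symmetric = TRUE)
  expect_equal(sym[, , 5], raw[, , 5] + t(raw[, , 5]))
})

test_that("raw pair counts follow the conservation identity", {
  set.seed(21)
  dims <- c(5, 7, 4)
  vol <- random_quantized(dims, 8)
  for (i in seq_len(13)) {
    off <- canonical_directions()[i, ]
    M <- glcm_single(vol, off, 8)
    expect_equal(sum(M), prod(dims - abs(off)))
  }
})
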