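test_that("AUC equals the Mann-Whitney pair-counting statistic", {
  expect_equal(auc_mw(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_mw(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mw(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mw(s, y), auc_oracle(s, y))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(80)
  y <- rbinom(80, 1, 0.5)
  expect_equal(auc_mw(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("bootstrap AUC interval is seeded and honest at perfect separation", {
  y <- rep(0:1, each = 100)
  s <- c(rnorm(100, 0), rnorm(100, 10))
  ci <- bootstrap_auc_ci(s, y, B = 200, seed = 1)
  expect_true(ci[["lower"]] >= 0.9 && ci[["upper"]] == 1)
  expect_identical(bootstrap_auc_ci(s, y, B = 200, seed = 7),
                   bootstrap_auc_ci(s, y, B = 200, seed = 7))
})

test_that("the Youden point maximizes sensitivity + specificity - 1", {
  yp <- youden_point(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1))
  expect_equal(yp$sensitivity, 1)
  expect_equal(yp$specificity, 1)
  expect_true(yp$threshold > 0.3 && yp$threshold <= 0.7)

  yp0 <- youden_point(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(yp0$youden, 0)

  set.seed(17)
  for (rep in 1:10) {
    s <- round(runif(50), 2)
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(youden_point(s, y)$youden, youden_oracle(s, y))
  }
})

test_that("Wald intervals follow the closed form and shrink with n", {
  ci <- wald_ci(0.5, 100)
  expect_equal(round(c(ci$lower, ci$upper), 3), c(0.402, 0.598))
  ci0 <- wald_ci(0, 20)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 0))
  ci1 <- wald_ci(1, 20)
  expect_equal(c(ci1$lower, ci1$upper), c(1, 1))
  widths <- vapply(c(10, 50, 200, 1000),
                   function(n) { w <- wald_ci(0.3, n); w$upper - w$lower },
                   numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(wald_ci(0.5, 0), "n must")
})

test_that("the DeLong test is exact under identity and matches pROC", {
  set.seed(23)
  y <- rbinom(120, 1, 0.5)
  s <- rnorm(120) + y
  d0 <- delong_test(s, s, y)
  expect_equal(d0$delta_auc, 0)
  expect_equal(d0$p_value, 1)

  skip_if_not_installed("pROC")
  s2 <- rnorm(120) + 0.8 * y
  ours <- delong_test(s, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("the DeLong p-value is invariant to monotone score transforms", {
  set.seed(29)
  y <- rbinom(90, 1, 0.5)
  a <- rnorm(90) + y
  b <- rnorm(90) + 0.5 * y
  p1 <- delong_test(a, b, y)$p_value
  p2 <- delong_test(exp(a), 2 * atan(b) + 5, y)$p_value
  expect_equal(p1, p2)
  expect_error(delong_test(a[1:10], b, y), "paired")
})

test_that("the DeLong variance tracks the bootstrap variance of the AUC difference", {
  set.seed(41)
  n <- 200
  y <- rep(0:1, each = n / 2)
  latent <- rnorm(n) + 1.2 * y
  a <- latent + rnorm(n, sd = 0.6)
  b <- latent + rnorm(n, sd = 0.6)
  d <- delong_test(a, b, y)
  se_delong <- abs(d$delta_auc - 0) / ifelse(d$statistic == 0, 1, abs(d$statistic))
  boot <- replicate(600, {
    idx <- sample.int(n, n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample.int(n, n, replace = TRUE)
    auc_mw(a[idx], y[idx]) - auc_mw(b[idx], y[idx])
  })
  expect_equal(se_delong, sd(boot), tolerance = 0.15)
})

test_that("McNemar routes between exact and corrected chi-square forms", {
  p <- mcnemar_test(c(rep(TRUE, 5), rep(FALSE, 15)),
                    c(rep(FALSE, 5), rep(TRUE, 15)))
  expect_equal(p$b, 5)
  expect_equal(p$c, 15)
  expect_equal(p$method, "exact binomial")
  expect_equal(p$p_value, 2 * pbinom(5, 20, 0.5), tolerance = 1e-9)

  sym <- mcnemar_test(c(rep(TRUE, 7), rep(FALSE, 7)),
                      c(rep(FALSE, 7), rep(TRUE, 7)))
  expect_gte(sym$p_value, 0.99)

  same <- mcnemar_test(rep(c(TRUE, FALSE), 10), rep(c(TRUE, FALSE), 10))
  expect_equal(same$p_value, 1)

  # asymptotic agreement at large discordance: b + c = 200
  a <- c(rep(TRUE, 110), rep(FALSE, 90))
  b <- c(rep(FALSE, 110), rep(TRUE, 90))
  chi <- mcnemar_test(a, b)
  expect_match(chi$method, "chi-square")
  exact <- 2 * pbinom(90, 200, 0.5)
  expect_lt(abs(chi$p_value - exact) / exact, 0.10)
})
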