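test_that("logistic fit recovers a planted log-odds ratio", {
  set.seed(21)
  n <- 6000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x))
  fit <- fit_glm(y ~ x, data.frame(x = x, y = y), family = "binomial")
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_lt(abs(est - 1.0), 0.15)  # ~2.5 standard errors at this n
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("constant covariates and missing data are handled explicitly", {
  d <- data.frame(y = rbinom(50, 1, 0.5), x = 1)
  expect_error(fit_glm(y ~ x, d), "constant")
  d2 <- data.frame(y = rbinom(50, 1, 0.5), x = c(NA, rnorm(49)))
  fit <- fit_glm(y ~ x, d2)
  expect_equal(fit$n, 49)
  expect_equal(fit$n_dropped, 1)
})

test_that("separation is flagged rather than silently reported", {
  d <- data.frame(y = rep(c(0, 1), each = 20), x = rep(c(0, 1), each = 20))
  fit <- suppressWarnings(fit_glm(y ~ x, d))
  expect_true(fit$separation)
})

test_that("stepwise removes the least significant term first", {
  set.seed(31)
  n <- 400
  strong <- rnorm(n)
  null1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * strong))
  d <- data.frame(y = y, strong = strong, null1 = null1)
  fit <- stepwise_backward(y ~ strong + null1, d, alpha = 0.05)
  expect_equal(fit$trace$removed, "null1")
  expect_true("strong" %in% fit$coefficients$term)
  # alpha = 1 is the identity; protection is honoured at alpha = 0
  fit_id <- stepwise_backward(y ~ strong + null1, d, alpha = 1)
  expect_equal(nrow(fit_id$trace), 0)
  fit_p <- stepwise_backward(y ~ strong + null1, d, alpha = 0,
                             protected = "null1")
  expect_equal(sort(fit_p$trace$removed), "strong")
  expect_true(any(grepl("null1", fit_p$coefficients$term)))
})

test_that("likelihood ratio test matches the chi-squared quantile oracle", {
  # df = 1, statistic 3.841 -> p = 0.05
  full <- structure(list(coefficients = data.frame(term = c("(Intercept)", "x")),
                         loglik = 0), class = "glm_fit")
  red <- structure(list(coefficients = data.frame(term = "(Intercept)"),
                        loglik = -3.841459 / 2), class = "glm_fit")
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, 0.05, tolerance = 1e-5)
  # identical models: statistic 0, p = 1
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(likelihood_ratio_test(red, full), "nested")
})

test_that("LRT and Wald agree on strong planted effects", {
  set.seed(41)
  hits <- replicate(40, {
    n <- 300
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-0.3 + 1.5 * x))
    d <- data.frame(x = x, y = y)
    full <- fit_glm(y ~ x, d)
    red <- fit_glm(y ~ 1, d)
    wald <- full$coefficients$p[full$coefficients$term == "x"]
    lrt <- likelihood_ratio_test(full, red)$p
    (wald < 0.05) == (lrt < 0.05)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("permutation lm attains the minimal p on perfect fits and is seeded", {
  d <- data.frame(y = 1:20, x = 1:20)
  p1 <- suppressWarnings(permutation_lm(y ~ x, d, n_perm = 199, seed = 5))
  expect_equal(p1$p_perm, 1 / 200)
  p2 <- suppressWarnings(permutation_lm(y ~ x, d, n_perm = 199, seed = 5))
  expect_equal(p1, p2)
})

test_that("permutation p-values are calibrated on null data", {
  set.seed(51)
  ps <- replicate(60, {
    d <- data.frame(y = rnorm(30), x = rnorm(30))
    permutation_lm(y ~ x, d, n_perm = 99, seed = sample.int(1e6, 1))$p_perm
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-sum comparisons match exact enumeration and BH fixed point", {
  # {1,2,3} vs {4,5,6}: the most extreme 3v3 split, exact two-sided p = 0.1
  out <- group_compare_bh(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(out$p, 0.1)
  # identical groups -> p = 1
  same <- group_compare_bh(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  # BH fixed point: m hypotheses all at p = alpha stay at alpha
  expect_equal(p.adjust(rep(0.03, 7), method = "BH"), rep(0.03, 7))
  # BH is monotone
  p_raw <- c(0.001, 0.04, 0.02, 0.5)
  expect_equal(order(p.adjust(p_raw, "BH")), order(p_raw))
  expect_warning(
    group_compare_bh(c(1, 2, 3, 4), c("a", "a", "a", "b")), "skipped")
})

test_that("pearson correlation wrapper handles the degenerate cases", {
  x <- rnorm(30)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 30)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("GLM MLE matches a generic optimizer on a small dataset", {
  set.seed(61)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  d <- data.frame(x = x, y = y)
  fit <- fit_glm(y ~ x, d)
  nll <- function(b) -sum(dbinom(y, 1, plogis(b[1] + b[2] * x), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(fit$coefficients$estimate, opt$par, tolerance = 1e-4)
})
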