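test_that("fit_linear recovers a known slope and rejects invalid model inputs", {
  set.seed(81)
  n <- 1000
  d <- data.frame(x = rnorm(n), sex = sample(c("f", "m"), n, TRUE),
                  age = runif(n, 40, 70))
  d$y <- 2 * d$x + 0.1 * d$age + rnorm(n)
  r <- fit_linear(d, "y", "x", c("age", "sex"))
  expect_lt(abs(r$beta - 2), 3 * r$se)
  expect_equal(r$n, n)
  expect_true(r$ci_low < r$beta && r$beta < r$ci_high)

  expect_error(fit_linear(d, "y", "x", c("x", "age")), "also listed")
  expect_error(fit_linear(d, "y", "missing_col"), "not in data")
  d$x2 <- d$x
  expect_error(fit_linear(d, "y", "x", c("x2")), "collinear")
})

test_that("fit_linear agrees with the normal-equations oracle", {
  set.seed(82)
  for (rep in 1:5) {
    n <- 150
    d <- data.frame(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
    d$y <- 0.6 * d$x - 0.4 * d$c1 + rnorm(n)
    r <- fit_linear(d, "y", "x", c("c1", "c2"))
    X <- cbind(1, d$x, d$c1, d$c2)
    beta_ne <- solve(t(X) %*% X, t(X) %*% d$y)
    expect_equal(r$beta, beta_ne[2], tolerance = 1e-8)
  }
})

test_that("bh_adjust reproduces the step-up procedure exactly", {
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(adj$adjusted, rep(0.04, 4))
  expect_true(all(adj$significant))
  expect_false(any(bh_adjust(rep(1, 6))$significant))
  expect_equal(bh_adjust(0.031)$adjusted, 0.031)   # single p unchanged

  set.seed(83)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    out <- bh_adjust(p)$adjusted
    expect_identical(out, bh_stepup_oracle(p))
    expect_true(all(out >= p))
  }
  expect_error(bh_adjust(c(0.1, 1.3)), "0, 1")
})

test_that("single-exposure scan reports per-IQR effects under one BH family", {
  set.seed(84)
  n <- 800
  d <- data.frame(e1 = rgamma(n, 3), e2 = rnorm(n), age = runif(n, 40, 70))
  d$out1 <- 0.4 * d$e1 + rnorm(n)
  d$out2 <- rnorm(n)
  res <- single_exposure_scan(d, c("e1", "e2"), c("out1", "out2"),
                              covariates = "age")
  expect_identical(nrow(res), 4L)

  # per-IQR slope equals raw slope times the IQR
  raw <- coef(lm(out1 ~ e1 + age, d))[["e1"]]
  row <- res[res$predictor == "e1" & res$outcome == "out1", ]
  expect_equal(row$beta, raw * row$iqr, tolerance = 1e-8)
  # the planted pair is flagged; the pure-noise pair is not
  expect_true(row$significant)
  expect_false(res[res$predictor == "e2" & res$outcome == "out2",
                   "significant"])
})

test_that("null scans keep the BH discovery fraction near the nominal rate", {
  set.seed(85)
  hits <- 0; total <- 0
  for (rep in 1:40) {
    n <- 150
    d <- data.frame(e1 = rnorm(n), e2 = rnorm(n), e3 = rnorm(n))
    d$o1 <- rnorm(n); d$o2 <- rnorm(n)
    res <- single_exposure_scan(d, paste0("e", 1:3), c("o1", "o2"),
                                covariates = character())
    hits <- hits + sum(res$significant)
    total <- total + nrow(res)
  }
  expect_lte(hits / total, 0.05 + 0.03)
})

test_that("stratified scans drop the stratifier and partition the cohort", {
  set.seed(86)
  n <- 1200
  d <- data.frame(e1 = rnorm(n), sex = sample(c("f", "m"), n, TRUE),
                  age = runif(n, 40, 70))
  beta_by_sex <- c(f = 1, m = -0.5)
  d$y <- beta_by_sex[d$sex] * d$e1 + rnorm(n)
  res <- stratified_scan(d, strata = "sex", exposures = "e1",
                         outcomes = "y", covariates = c("sex", "age"))
  expect_setequal(res$stratum, c("f", "m"))
  expect_equal(sum(res$n), n)                     # strata partition rows
  for (i in seq_len(nrow(res))) {
    expected <- beta_by_sex[res$stratum[i]] * res$iqr[i]
    expect_lt(abs(res$beta[i] - expected), 3 * res$se[i])
  }
  # a degenerate stratum is skipped with a message, not an error
  d2 <- d[1:30, ]
  d2$sex[1] <- "x"
  expect_message(
    res2 <- stratified_scan(d2, strata = "sex", exposures = "e1",
                            outcomes = "y", covariates = "sex"),
    "skipped")
  expect_false("x" %in% res2$stratum)
})

test_that("residence filter keeps long-term residents only", {
  d <- data.frame(residence_years = c(10, 4.9, 5, 0, 22), v = 1:5)
  expect_identical(residence_filter(d)$v, c(1L, 3L, 5L))
  all_ok <- data.frame(residence_years = c(6, 7), v = 1:2)
  expect_identical(residence_filter(all_ok), all_ok)
  expect_error(residence_filter(data.frame(v = 1)), "residence_years")
})

test_that("spearman_matrix handles monotone, antitone and tied data", {
  x <- 1:20
  m <- spearman_matrix(cbind(a = x, b = exp(x), c = -x^3))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))

  # ties: agree with an explicit average-rank oracle
  set.seed(87)
  u <- sample(1:5, 40, TRUE); v <- u + sample(0:2, 40, TRUE)
  expect_equal(spearman_matrix(cbind(u, v))["u", "v"],
               cor(rank(u), rank(v)))
})

test_that("describe_cohort separates shifted groups and not identical ones", {
  set.seed(88)
  d <- data.frame(g = rep(c("a", "b"), each = 150),
                  same = rnorm(300),
                  shifted = c(rnorm(150), rnorm(150, 2)),
                  cat = sample(c("x", "y"), 300, TRUE))
  tab <- describe_cohort(d, "g")
  expect_identical(sum(tab$n[tab$variable == "cat"]), 300L)
  expect_lt(tab$p[tab$variable == "shifted"][1], 1e-6)
  expect_gt(tab$p[tab$variable == "same"][1], 0.01)
})

test_that("identical groups are rarely flagged by the descriptive tests", {
  set.seed(89)
  rejections <- 0
  for (r in 1:30) {
    d <- data.frame(g = rep(c("a", "b"), each = 80), v = rnorm(160))
    tab <- describe_cohort(d, "g", "v")
    if (tab$p[1] < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 30, 0.10)
})

test_that("latent-class EM recovers separable patterns with monotone likelihood", {
  # two perfectly separated response patterns
  n <- 150
  d <- data.frame(
    income = rep(c("high", "low"), each = n),
    education = rep(c("degree", "none"), each = n),
    employment = rep(c("employed", "other"), each = n))
  fit <- lca_ses(d, k = 2, seed = 1)
  expect_gt(min(apply(fit$posterior, 1, max)), 0.999)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))   # EM never decreases
  agreement <- max(mean(fit$class[1:n] == fit$class[1]),
                   mean(fit$class[(n + 1):(2 * n)] == fit$class[n + 1]))
  expect_identical(agreement, 1)

  # k = 1 closed form: item-response probabilities are the marginals
  fit1 <- lca_ses(d, k = 1, seed = 1, n_start = 1)
  expect_equal(unname(fit1$item_probs$income[1, ]),
               as.vector(table(d$income) / nrow(d)), tolerance = 1e-6)
})

test_that("three-class SES model orders classes high/medium/low on planted data", {
  co <- simulate_cohort(cohort_config(n = 1500, seed = 90))
  fit <- lca_ses(co, seed = 90)
  expect_identical(sort(fit$labels), sort(c("high", "medium", "low")))
  # the class called "high" should be the one rich in high income
  expect_gt(fit$item_probs$income[1, "high"],
            fit$item_probs$income[3, "high"])
  expect_gt(mean(fit$class == co$truth_ses), 0.6)
})
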