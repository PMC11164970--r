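test_that("split_sample produces a deterministic disjoint 40/60 split", {
  sp <- split_sample(10, 0.4, seed = 1)
  expect_length(sp$train, 4)
  expect_length(sp$validation, 6)
  expect_identical(sort(c(sp$train, sp$validation)), 1:10)
  expect_identical(sp, split_sample(10, 0.4, seed = 1))
  expect_false(identical(split_sample(1000, 0.4, 1),
                         split_sample(1000, 0.4, 2)))
  expect_error(split_sample(5), "at least 10")
  expect_error(split_sample(100, 1.2), "train_fraction")
})

test_that("single-exposure fit reduces to the OLS slope", {
  set.seed(41)
  q1 <- matrix(sample(0:3, 300, TRUE), ncol = 1,
               dimnames = list(NULL, "e1"))
  y <- 0.7 * q1[, 1] + rnorm(300)
  fit <- fit_weights_once(q1, y, direction = "positive")
  expect_identical(unname(fit$weights), 1)
  expect_equal(unname(fit$beta), unname(coef(lm(y ~ q1))[2]),
               tolerance = 1e-10)
  # wrong direction: effect shrinks to the boundary at zero
  neg <- fit_weights_once(q1, y, direction = "negative")
  expect_identical(neg$beta, 0)
})

test_that("softmax optimizer matches the 0.05-grid simplex oracle", {
  set.seed(42)
  for (rep in 1:8) {
    x <- matrix(rnorm(200 * 3), 200)
    x[, 2] <- x[, 2] + 0.5 * x[, 1]
    colnames(x) <- paste0("e", 1:3)
    qs <- quantize_table(x, 4)$scores
    y <- 0.8 * drop(qs %*% c(0.7, 0.2, 0.1)) +
      rnorm(200, 0, runif(1, 0.3, 2))
    fit <- fit_weights_once(qs, y, direction = "positive", seed = rep)
    expect_true(fit$converged)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
    expect_lte(fit$sse, wqs_grid_oracle(qs, y) + 1e-6)
  }
})

test_that("a dominant planted exposure receives nearly all weight", {
  set.seed(43)
  x <- matrix(rnorm(200 * 3), 200, dimnames = list(NULL, paste0("e", 1:3)))
  qs <- quantize_table(x, 4)$scores
  y <- drop(qs %*% c(1, 0, 0)) + rnorm(200, 0, 0.3)
  fit <- fit_weights_once(qs, y, direction = "positive")
  expect_gt(fit$weights[["e1"]], 0.9)

  # outcome independent of exposures: index effect collapses toward zero
  null_fit <- fit_weights_once(qs, rnorm(200), direction = "positive")
  expect_lt(abs(null_fit$beta), 0.2)
})

test_that("average_weights stays on the simplex", {
  expect_equal(average_weights(rbind(c(0.2, 0.8), c(0.2, 0.8))),
               c(0.2, 0.8))
  expect_equal(average_weights(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(44)
  W <- t(replicate(20, { w <- rexp(5); w / sum(w) }))
  expect_equal(sum(average_weights(W)), 1, tolerance = 1e-12)
  expect_error(average_weights(W, converged = rep(FALSE, 20)),
               "no converged")
})

test_that("wqs_index is a convex combination of scores", {
  sc <- matrix(2L, 10, 3)
  expect_equal(wqs_index(sc, c(0.3, 0.3, 0.4)), rep(2, 10))
  sc2 <- cbind(a = c(0L, 1L, 3L), b = c(2L, 2L, 0L), c = c(1L, 0L, 2L))
  expect_equal(wqs_index(sc2, c(0, 1, 0)), as.numeric(sc2[, "b"]))
  # hand-computed dot products
  expect_equal(wqs_index(sc2, c(0.5, 0.25, 0.25)),
               c(0 * 0.5 + 2 * 0.25 + 1 * 0.25,
                 1 * 0.5 + 2 * 0.25 + 0 * 0.25,
                 3 * 0.5 + 0 * 0.25 + 2 * 0.25))
  expect_error(wqs_index(sc2, c(0.5, 0.5)), "length")
  expect_error(wqs_index(sc2, c(0.9, 0.9, -0.8)), "simplex")
})

test_that("validation inference recovers a planted index effect", {
  set.seed(45)
  idx <- runif(5000, 0, 3)
  cov1 <- rnorm(5000)
  y <- 0.05 * idx + 0.3 * cov1 + rnorm(5000)
  v <- validate_index(y, idx, cbind(cov1 = cov1))
  expect_lt(abs(v$beta - 0.05), 3 * v$se)
  expect_true(v$ci[1] < v$beta && v$beta < v$ci[2])
  expect_identical(v$n, 5000L)

  # duplicating the index as a covariate is a rank-deficiency error
  expect_error(validate_index(y, idx, cbind(dup = idx)),
               "collinear.*dup")
})

test_that("end-to-end wqs recovers planted weights and replays deterministically", {
  cfg <- wqs_test_config(n = 1500, seed = 46)
  x <- generate_exposures(cfg)
  qs <- quantize_table(x, 4)$scores
  gen <- generate_outcomes(qs, c(0.4, 0.4, 0.2, 0, 0, 0), beta = 1,
                           noise_sd = 1, seed = 46)
  d <- data.frame(y = gen$outcome, x)
  fit <- wqs(y ~ 1, d, exposures = cfg$exposures, n_boot = 30, seed = 2)
  expect_lt(max(abs(weights(fit) - c(0.4, 0.4, 0.2, 0, 0, 0))), 0.12)
  expect_equal(sum(weights(fit)), 1, tolerance = 1e-10)
  expect_gt(fit$n_converged, 0)

  replay <- wqs(y ~ 1, d, exposures = cfg$exposures, n_boot = 30, seed = 2)
  expect_identical(weights(fit), weights(replay))
  expect_identical(fit$validation, replay$validation)

  expect_error(wqs(y ~ e1, d, exposures = cfg$exposures),
               "also appear as covariates")
})

test_that("reversed protective exposures carry positive weight in the positive model", {
  set.seed(47)
  n <- 1200
  green <- rnorm(n)
  other <- matrix(rnorm(n * 2), n)
  d <- data.frame(green_300m = green, e2 = other[, 1], e3 = other[, 2])
  q_green <- quantize(green, 4)$scores
  # protective planted effect: more green, better (lower) outcome
  d$y <- -0.8 * q_green + rnorm(n)
  fit <- wqs(y ~ 1, d, exposures = c("green_300m", "e2", "e3"),
             n_boot = 20, seed = 3)   # green reversed by default
  expect_gt(weights(fit)[["green_300m"]], 0.6)
  expect_gt(fit$validation$beta, 0)
})

test_that("both-direction fitting returns a fit per direction", {
  set.seed(48)
  x <- matrix(rnorm(400 * 3), 400, dimnames = list(NULL, paste0("e", 1:3)))
  d <- data.frame(y = rnorm(400), x)
  both <- wqs(y ~ 1, d, exposures = paste0("e", 1:3), n_boot = 5,
              direction = "both", seed = 4)
  expect_s3_class(both, "wqs_both")
  expect_identical(both$positive$direction, "positive")
  expect_identical(both$negative$direction, "negative")
  expect_true(all(both$negative$bootstrap_betas <= 0))
  expect_true(all(both$positive$bootstrap_betas >= 0))
})

test_that("wqs methods expose weights, coefficients and index predictions", {
  cfg <- wqs_test_config(n = 600, seed = 49, p = 4,
                         weights = c(0.5, 0.5, 0, 0))
  x <- generate_exposures(cfg)
  qs <- quantize_table(x, 4)$scores
  d <- data.frame(y = generate_outcomes(qs, c(0.5, 0.5, 0, 0), 1,
                                        noise_sd = 0.8, seed = 49)$outcome,
                  x, z = rnorm(600))
  fit <- wqs(y ~ z, d, exposures = cfg$exposures, n_boot = 10, seed = 5)
  expect_equal(sum(weights(fit)), 1, tolerance = 1e-10)
  expect_named(coef(fit)[1], "wqs_index")
  idx <- predict(fit, d)
  expect_true(all(idx >= 0 & idx <= 3))
  expect_output(print(fit), "Weighted quantile sum")
  expect_output(print(summary(fit)), "validation index effect")
})
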