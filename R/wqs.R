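# Weighted quantile sum (WQS) regression implemented from definition:
# exposures are quantile-scored, a simplex-constrained weight vector is
# estimated by bootstrap on a training split, and the averaged index is
# tested on a disjoint validation split.

#' Split participants into disjoint training and validation sets
#'
#' @param n Number of rows (at least 10).
#' @param train_fraction Fraction assigned to training (default 0.4).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with integer index vectors `train` (size
#'   `floor(train_fraction * n)`) and `validation` (the rest).
#' @export
split_sample <- function(n, train_fraction = 0.4, seed = 1) {
  if (n < 10) stop("need at least 10 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  train <- .with_seed(.child_seed(seed, 101L), sample.int(n, n_train))
  list(train = sort(train), validation = setdiff(seq_len(n), train))
}

# Residualize y and the score columns against the covariate design once
# (Frisch-Waugh), so each weight evaluation reduces to a p x p quadratic
# form. Returns the sufficient statistics of the profiled SSE.
.wqs_suffstats <- function(scores, y, covariates = NULL) {
  C <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  qrC <- qr(C)
  ytil <- qr.resid(qrC, y)
  Qtil <- qr.resid(qrC, scores)
  list(A = crossprod(Qtil), b = drop(crossprod(Qtil, ytil)),
       yy = sum(ytil^2), qrC = qrC)
}

.softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

#' Fit WQS weights and index effect on one (bootstrap) sample
#'
#' Minimizes the residual sum of squares of
#' `y ~ beta1 * (scores %*% w) + covariates` subject to `w >= 0`,
#' `sum(w) = 1` and `sign(beta1)` fixed by `direction`. The simplex
#' constraint is kept exact through a softmax reparameterization and the
#' sign constraint through `beta1 = sign * exp(eta)`; covariate
#' coefficients are profiled out in closed form, and a quasi-Newton search
#' with random restarts optimizes the remaining low-dimensional objective.
#'
#' @param scores Integer/numeric matrix of quantile scores (rows =
#'   participants).
#' @param y Outcome vector.
#' @param covariates Optional numeric covariate matrix (no intercept
#'   column; one is added internally).
#' @param direction `"positive"` or `"negative"`: the enforced sign of the
#'   index effect.
#' @param n_restarts Number of optimizer starts (1 deterministic + the
#'   rest random).
#' @param seed Seed for the random restarts.
#' @param reltol Convergence tolerance passed to the optimizer.
#' @return List with `weights` (simplex vector), `beta` (signed index
#'   effect), `sse` and `converged`.
#' @export
fit_weights_once <- function(scores, y, covariates = NULL,
                             direction = c("positive", "negative"),
                             n_restarts = 5, seed = 1, reltol = 1e-10) {
  direction <- match.arg(direction)
  scores <- as.matrix(scores)
  s <- if (direction == "positive") 1 else -1
  p <- ncol(scores)
  st <- .wqs_suffstats(scores, y, covariates)
  A <- st$A; bv <- st$b; yy <- st$yy

  if (p == 1) {
    beta_free <- bv / A[1, 1]
    beta <- s * max(0, s * beta_free)
    return(list(weights = stats::setNames(1, colnames(scores)),
                beta = beta, sse = yy - 2 * beta * bv + beta^2 * A[1, 1],
                converged = TRUE))
  }

  obj <- function(theta) {
    beta <- s * exp(theta[1])
    w <- .softmax(c(0, theta[-1]))
    drop(yy - 2 * beta * sum(w * bv) + beta^2 * (w %*% A %*% w))
  }
  grad <- function(theta) {
    beta <- s * exp(theta[1])
    w <- .softmax(c(0, theta[-1]))
    Aw <- drop(A %*% w)
    dbeta <- -2 * sum(w * bv) + 2 * beta * sum(w * Aw)
    gw <- -2 * beta * bv + 2 * beta^2 * Aw
    ga <- w * (gw - sum(w * gw))
    c(dbeta * beta, ga[-1])
  }

  # deterministic first start: uniform weights, OLS-scale effect
  w0 <- rep(1 / p, p)
  b0 <- drop(w0 %*% bv) / drop(w0 %*% A %*% w0)
  eta0 <- log(max(s * b0, 1e-4))
  starts <- list(c(eta0, rep(0, p - 1)))
  if (n_restarts > 1) {
    rs <- .with_seed(.child_seed(seed, 211L), {
      lapply(seq_len(n_restarts - 1), function(i) {
        c(eta0 + stats::rnorm(1, 0, 0.5), stats::rnorm(p - 1, 0, 1.5))
      })
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  any_conv <- FALSE
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, obj, grad, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(weights = rep(NA_real_, p), beta = NA_real_,
                sse = NA_real_, converged = FALSE))
  }
  w <- .softmax(c(0, best$par[-1]))
  names(w) <- colnames(scores)
  list(weights = w, beta = s * exp(best$par[1]), sse = best$value,
       converged = any_conv)
}

#' Average bootstrap weight vectors onto the simplex
#'
#' Arithmetic mean of the converged bootstrap weight vectors, renormalized
#' so the result lies exactly on the simplex.
#'
#' @param weight_matrix Bootstraps x exposures matrix of simplex weights.
#' @param converged Logical vector flagging converged bootstraps (default
#'   all).
#' @return Averaged weight vector.
#' @export
average_weights <- function(weight_matrix,
                            converged = rep(TRUE, nrow(weight_matrix))) {
  weight_matrix <- as.matrix(weight_matrix)
  keep <- converged & !apply(weight_matrix, 1, anyNA)
  if (!any(keep)) stop("no converged bootstrap weight vectors to average")
  w <- colMeans(weight_matrix[keep, , drop = FALSE])
  w / sum(w)
}

#' Weighted quantile sum index
#'
#' Convex combination of quantile scores: `index = scores %*% w`, bounded
#' in `[0, q - 1]`.
#'
#' @param scores Quantile score matrix.
#' @param weights Simplex weight vector matching the score columns.
#' @return Per-participant index vector.
#' @export
wqs_index <- function(scores, weights) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(weights)) {
    stop("weights length does not match the number of score columns")
  }
  if (any(weights < -1e-10) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must lie on the simplex")
  }
  drop(scores %*% weights)
}

#' Validation-set inference on a WQS index
#'
#' Ordinary least squares of the outcome on the index plus covariates on
#' the validation rows, with normal-theory standard error, two-sided p
#' value and 95 percent confidence interval for the index effect.
#'
#' @param y Validation outcome vector.
#' @param index Validation WQS index (from training-set weights).
#' @param covariates Optional numeric covariate matrix.
#' @return List with `beta`, `se`, `ci` (length 2), `p`, `n` and
#'   `covariate_coefficients`.
#' @export
validate_index <- function(y, index, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, wqs_index = index, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("validation design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rdf <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  beta <- fit$coefficients[["wqs_index"]]
  se1 <- se[2]
  tval <- beta / se1
  p <- 2 * stats::pt(-abs(tval), rdf)
  list(beta = beta, se = se1,
       ci = beta + c(-1, 1) * stats::qnorm(0.975) * se1,
       p = p, n = length(y),
       covariate_coefficients = fit$coefficients[-2])
}

#' Weighted quantile sum regression
#'
#' Fits a WQS mixture model: exposures are scored into quantiles (q
#' groups), protective exposures are reversed so every component points
#' the same way, the sample is split into a training fraction used to
#' estimate simplex-constrained exposure weights over bootstrap resamples,
#' and the weight-averaged index is tested on the held-out validation
#' fraction with the covariate-adjusted linear model of `formula`.
#'
#' @param formula Model formula `outcome ~ covariates` (use `~ 1` for an
#'   unadjusted model). The exposures must not appear here.
#' @param data Data frame containing outcome, covariates and exposures.
#' @param exposures Character vector of exposure column names.
#' @param q Number of quantile groups (default 4).
#' @param n_boot Number of bootstrap samples for weight estimation
#'   (default 500).
#' @param train_fraction Training-set fraction (default 0.4; the remaining
#'   0.6 is the validation set).
#' @param direction `"positive"`, `"negative"`, or `"both"` (fits one
#'   model per direction and returns both).
#' @param reverse Exposure names whose quantile scores are reversed
#'   (protective exposures); defaults to any green/blue space columns
#'   among `exposures`.
#' @param seed Integer seed controlling split, bootstraps and optimizer
#'   restarts.
#' @param n_restarts Optimizer restarts per bootstrap.
#' @return An object of class `"wqs"` (or a named list of two for
#'   `direction = "both"`), with components `weights` (averaged simplex
#'   weights), `weight_matrix` (per-bootstrap), `validation` (index
#'   effect, SE, CI, p), `n_converged`, `n_direction_consistent`,
#'   `boundaries` and the call. Methods: `print`, `summary`, `coef`,
#'   `weights`, `predict`, `plot`.
#' @export
#' @examples
#' cfg <- cohort_config(n = 400, seed = 7,
#'                      exposures = c("e1", "e2", "e3"),
#'                      marginals = list(),
#'                      archetype_means = NULL,
#'                      planted_weights = c(0.6, 0.3, 0.1),
#'                      planted_beta = c(y = 1),
#'                      noise_sd = c(y = 0.5))
#' x <- generate_exposures(cfg)
#' qs <- quantize_table(x)$scores
#' y <- generate_outcomes(qs, c(0.6, 0.3, 0.1), 1, noise_sd = 0.5,
#'                        seed = 7)$outcome
#' d <- data.frame(y = y, x)
#' fit <- wqs(y ~ 1, d, exposures = c("e1", "e2", "e3"),
#'            n_boot = 10, seed = 1)
#' weights(fit)
wqs <- function(formula, data, exposures, q = 4, n_boot = 500,
                train_fraction = 0.4,
                direction = c("positive", "negative", "both"),
                reverse = NULL, seed = 1, n_restarts = 5) {
  direction <- match.arg(direction)
  if (direction == "both") {
    out <- list(
      positive = wqs(formula, data, exposures, q = q, n_boot = n_boot,
                     train_fraction = train_fraction,
                     direction = "positive", reverse = reverse,
                     seed = seed, n_restarts = n_restarts),
      negative = wqs(formula, data, exposures, q = q, n_boot = n_boot,
                     train_fraction = train_fraction,
                     direction = "negative", reverse = reverse,
                     seed = seed, n_restarts = n_restarts))
    class(out) <- "wqs_both"
    return(out)
  }
  if (n_boot < 1) stop("n_boot must be at least 1")
  missing_expo <- setdiff(exposures, names(data))
  if (length(missing_expo) > 0) {
    stop("exposure column(s) not in data: ",
         paste(missing_expo, collapse = ", "))
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  covariates <- stats::model.matrix(stats::terms(mf), mf)
  covariates <- covariates[, colnames(covariates) != "(Intercept)",
                           drop = FALSE]
  if (ncol(covariates) == 0) covariates <- NULL
  bad <- intersect(exposures, colnames(covariates))
  if (length(bad) > 0) {
    stop("exposure(s) also appear as covariates: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(reverse)) {
    reverse <- intersect(exposures, c("green_300m", "green_1000m",
                                      "blue_300m", "blue_1000m"))
  }

  n <- length(y)
  split <- split_sample(n, train_fraction, seed)
  expo_train <- data[split$train, exposures, drop = FALSE]
  qz <- quantize_table(expo_train, q = q)
  scores_train <- reverse_protective(qz$scores, q, reverse)
  scores_valid <- reverse_protective(
    quantize_table(data[split$validation, exposures, drop = FALSE],
                   q = q, boundaries = qz$boundaries)$scores, q, reverse)

  cov_train <- if (is.null(covariates)) NULL else
    covariates[split$train, , drop = FALSE]
  cov_valid <- if (is.null(covariates)) NULL else
    covariates[split$validation, , drop = FALSE]
  y_train <- y[split$train]
  y_valid <- y[split$validation]

  n_train <- length(split$train)
  W <- matrix(NA_real_, n_boot, length(exposures),
              dimnames = list(NULL, exposures))
  betas <- numeric(n_boot)
  converged <- logical(n_boot)
  boot_idx <- .with_seed(.child_seed(seed, 301L), {
    lapply(seq_len(n_boot), function(b) {
      sample.int(n_train, n_train, replace = TRUE)
    })
  })
  for (b in seq_len(n_boot)) {
    idx <- boot_idx[[b]]
    fit_b <- fit_weights_once(
      scores_train[idx, , drop = FALSE], y_train[idx],
      covariates = cov_train[idx, , drop = FALSE],
      direction = direction, n_restarts = n_restarts,
      seed = .child_seed(seed, 400L + b))
    W[b, ] <- fit_b$weights
    betas[b] <- fit_b$beta
    converged[b] <- fit_b$converged
  }
  w_bar <- average_weights(W, converged)
  index_valid <- wqs_index(scores_valid, w_bar)
  val <- validate_index(y_valid, index_valid, cov_valid)

  out <- list(
    call = match.call(),
    direction = direction,
    weights = w_bar,
    weight_matrix = W,
    bootstrap_betas = betas,
    n_converged = sum(converged),
    n_direction_consistent = sum(converged & abs(betas) > 1e-8),
    n_boot = n_boot,
    validation = val,
    q = q,
    reverse = reverse,
    boundaries = qz$boundaries,
    split = split,
    train_fraction = train_fraction,
    exposures = exposures,
    formula = formula,
    seed = seed)
  class(out) <- "wqs"
  out
}

#' @export
print.wqs <- function(x, ...) {
  cat("Weighted quantile sum regression (", x$direction, " direction)\n",
      sep = "")
  cat("  exposures: ", length(x$exposures), ", q = ", x$q,
      ", bootstraps: ", x$n_converged, "/", x$n_boot, " converged\n",
      sep = "")
  cat("  split: ", length(x$split$train), " train / ",
      length(x$split$validation), " validation\n", sep = "")
  cat("  index effect (validation): ",
      format(x$validation$beta, digits = 4), " (95% CI ",
      format(x$validation$ci[1], digits = 4), ", ",
      format(x$validation$ci[2], digits = 4), "; p = ",
      format.pval(x$validation$p, digits = 3), ")\n", sep = "")
  w <- sort(x$weights, decreasing = TRUE)
  cat("  top weights: ",
      paste0(names(w)[seq_len(min(3, length(w)))], " = ",
             format(w[seq_len(min(3, length(w)))], digits = 3),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.wqs <- function(object, ...) {
  ok <- !apply(object$weight_matrix, 1, anyNA)
  out <- list(
    direction = object$direction,
    weights = sort(object$weights, decreasing = TRUE),
    weight_sd = apply(object$weight_matrix[ok, , drop = FALSE], 2,
                      stats::sd),
    validation = object$validation,
    n_boot = object$n_boot,
    n_converged = object$n_converged,
    n_direction_consistent = object$n_direction_consistent)
  class(out) <- "summary.wqs"
  out
}

#' @export
print.summary.wqs <- function(x, ...) {
  cat("WQS summary (", x$direction, " direction)\n", sep = "")
  tab <- data.frame(weight = x$weights,
                    boot_sd = x$weight_sd[names(x$weights)])
  print(round(tab, 4))
  v <- x$validation
  cat("\nvalidation index effect: beta = ", format(v$beta, digits = 4),
      ", SE = ", format(v$se, digits = 4), ", p = ",
      format.pval(v$p, digits = 3), "\n", sep = "")
  cat("converged bootstraps: ", x$n_converged, "/", x$n_boot,
      " (direction-consistent: ", x$n_direction_consistent, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.wqs <- function(object, ...) {
  c(wqs_index = object$validation$beta,
    object$validation$covariate_coefficients)
}

#' @export
weights.wqs <- function(object, ...) object$weights

#' Predict the WQS index for new data
#'
#' Scores new exposures with the training-set quantile boundaries, applies
#' the fitted protective reversals, and returns the weighted index.
#'
#' @param object A fitted `"wqs"` object.
#' @param newdata Data frame containing the exposure columns.
#' @param ... Unused.
#' @return Numeric index vector in `[0, q - 1]`.
#' @export
predict.wqs <- function(object, newdata, ...) {
  scores <- quantize_table(newdata[, object$exposures, drop = FALSE],
                           q = object$q,
                           boundaries = object$boundaries)$scores
  scores <- reverse_protective(scores, object$q, object$reverse)
  wqs_index(scores, object$weights)
}

#' Plot WQS weights
#'
#' Horizontal barplot of the averaged bootstrap weights with the uniform
#' reference line 1/p (a weight above it contributes more than an
#' equal-share exposure).
#'
#' @param x A fitted `"wqs"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.wqs <- function(x, ...) {
  w <- sort(x$weights)
  graphics::barplot(w, horiz = TRUE, las = 1,
                    xlab = "averaged bootstrap weight",
                    main = paste0("WQS weights (", x$direction, ")"), ...)
  graphics::abline(v = 1 / length(w), lty = 2)
  invisible(x)
}

#' @export
print.wqs_both <- function(x, ...) {
  cat("WQS fits in both directions:\n\n")
  print(x$positive); cat("\n"); print(x$negative)
  invisible(x)
}
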