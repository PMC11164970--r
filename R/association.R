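# Covariate-adjusted linear association engine: single-model fits,
# Benjamini-Hochberg FDR families, IQR-scaled single-exposure scans,
# stratified and sensitivity variants, descriptive group tests and the
# latent-class socioeconomic-status model.

#' Default covariate set for adjusted models
#'
#' Age, sex, ethnicity, neighborhood socioeconomic status, smoking status,
#' BMI, alcohol intake frequency, regular exercise, healthy diet, and
#' history of CVD and cancer.
#'
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("age", "sex", "ethnicity", "nses", "smoking", "bmi", "alcohol",
    "exercise", "diet", "cvd", "cancer")
}

#' Covariate-adjusted linear regression for one predictor
#'
#' Ordinary least squares of `outcome` on `predictor` plus covariates,
#' complete cases only. Categorical covariates are dummy-coded with the
#' first level (alphabetical for character columns) as reference. Returns
#' the predictor's coefficient with normal-theory SE, 95 percent CI and
#' two-sided p value.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param predictor Predictor column name (must not be a covariate).
#' @param covariates Character vector of covariate column names.
#' @param family Optional FDR family id recorded in the result.
#' @return One-row data frame: `outcome`, `predictor`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n`, `family`.
#' @export
fit_linear <- function(data, outcome, predictor,
                       covariates = character(), family = "main") {
  if (predictor %in% covariates) {
    stop("predictor '", predictor, "' also listed among the covariates")
  }
  cols <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[, cols, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (nm in names(df)) if (is.character(df[[nm]])) {
    df[[nm]] <- factor(df[[nm]])  # alphabetical reference level
  }
  if (nrow(df) < length(covariates) + 10) {
    stop("too few complete cases (", nrow(df), ") for the model")
  }
  rhs <- paste(c(sprintf("`%s`", predictor),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  mm <- stats::model.matrix(fml, df)
  if (qr(mm)$rank < ncol(mm)) {
    bad <- colnames(mm)[qr(mm)$pivot[-seq_len(qr(mm)$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  row <- grep(sprintf("^`?%s`?$", predictor), rownames(sm))
  if (length(row) != 1) row <- 2L  # continuous predictor is the 2nd term
  data.frame(outcome = outcome, predictor = predictor,
             beta = sm[row, 1], se = sm[row, 2],
             ci_low = sm[row, 1] - stats::qnorm(0.975) * sm[row, 2],
             ci_high = sm[row, 1] + stats::qnorm(0.975) * sm[row, 2],
             p = sm[row, 4], n = nrow(df), family = family,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment of a p-value family
#'
#' Step-up adjusted p values (monotone-enforced `min over j >= i of
#' m * p_(j) / j`) and discovery decisions at the requested FDR level.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param fdr False-discovery-rate level for the decisions (default 0.05).
#' @return List with `adjusted` (same order as `p`) and `significant`
#'   (logical).
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, significant = adjusted < fdr)
}

#' IQR-scaled single-exposure association scan
#'
#' One covariate-adjusted linear model per exposure x outcome pair, with
#' the exposure divided by its interquartile range so each coefficient
#' reads as the effect of an IQR increase. All models form one BH family.
#'
#' @param data Data frame.
#' @param exposures Character vector of exposure columns.
#' @param outcomes Character vector of outcome columns.
#' @param covariates Covariate columns (default [default_covariates()]
#'   intersected with `data`).
#' @param fdr FDR level (default 0.05).
#' @return Data frame, one row per model, with `iqr`, BH-`adjusted_p` and
#'   `significant` columns added to the [fit_linear()] fields.
#' @export
single_exposure_scan <- function(data, exposures, outcomes,
                                 covariates = intersect(default_covariates(),
                                                        names(data)),
                                 fdr = 0.05) {
  rows <- list()
  for (ex in exposures) {
    scaled <- iqr_scale(data[[ex]])
    d2 <- data
    scaled_name <- paste0(ex, "_per_iqr")
    d2[[scaled_name]] <- scaled$scaled
    for (out in outcomes) {
      r <- fit_linear(d2, out, scaled_name, covariates,
                      family = "single_exposure")
      r$predictor <- ex
      r$iqr <- scaled$iqr
      rows[[length(rows) + 1]] <- r
    }
  }
  res <- do.call(rbind, rows)
  adj <- bh_adjust(res$p, fdr)
  res$adjusted_p <- adj$adjusted
  res$significant <- adj$significant
  res
}

#' Stratified association scan
#'
#' Repeats an exposure-outcome scan within strata (e.g. sex, age >= 60,
#' smoking status, alcohol frequency), dropping the stratifying covariate
#' from each stratum's model. Empty or too-small strata are skipped with a
#' message.
#'
#' @param data Data frame.
#' @param strata Named list: each element a factor/vector defining one
#'   stratification (e.g. `list(sex = data$sex)`), or a character vector
#'   of column names.
#' @param exposures,outcomes,covariates As in [single_exposure_scan()].
#' @param fdr FDR level applied within each stratification family.
#' @return Data frame with `stratification` and `stratum` columns.
#' @export
stratified_scan <- function(data, strata, exposures, outcomes,
                            covariates = intersect(default_covariates(),
                                                   names(data)),
                            fdr = 0.05) {
  if (is.character(strata)) {
    strata <- stats::setNames(lapply(strata, function(s) data[[s]]), strata)
  }
  out <- list()
  for (sname in names(strata)) {
    svec <- strata[[sname]]
    cov_s <- setdiff(covariates, sname)
    for (lev in sort(unique(as.character(svec)))) {
      rows <- !is.na(svec) & as.character(svec) == lev
      sub <- data[rows, , drop = FALSE]
      res <- tryCatch(
        single_exposure_scan(sub, exposures, outcomes, cov_s, fdr),
        error = function(e) {
          message("stratum ", sname, "=", lev, " skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      res$stratification <- sname
      res$stratum <- lev
      out[[length(out) + 1]] <- res
    }
  }
  do.call(rbind, out)
}

#' Residential-stability sensitivity filter
#'
#' Keeps participants who have lived at their current address at least
#' `min_years` years, so home-based exposure assignment reflects
#' long-term exposure.
#'
#' @param data Data frame with a `residence_years` column.
#' @param min_years Minimum years at the current address (default 5).
#' @return Filtered data frame.
#' @export
residence_filter <- function(data, min_years = 5) {
  if (!"residence_years" %in% names(data)) {
    stop("data has no 'residence_years' column")
  }
  data[!is.na(data$residence_years) & data$residence_years >= min_years, ,
       drop = FALSE]
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations (average ranks on ties): symmetric with
#' unit diagonal.
#'
#' @param x Numeric matrix or data frame.
#' @return Correlation matrix.
#' @export
spearman_matrix <- function(x) {
  stats::cor(as.matrix(x), method = "spearman")
}

#' Descriptive comparison of cohort groups
#'
#' Means (SD) with Mann-Whitney U tests for continuous variables and
#' counts (percent) with chi-squared tests for categorical ones, compared
#' across the levels of `grouping`.
#'
#' @param data Data frame.
#' @param grouping Grouping column name (2+ levels).
#' @param variables Columns to describe (default: all except the
#'   grouping).
#' @return Data frame: one row per variable x group for the descriptive
#'   statistics, with the test p value repeated per variable.
#' @export
describe_cohort <- function(data, grouping,
                            variables = setdiff(names(data), grouping)) {
  g <- factor(data[[grouping]])
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 5) {
      p <- if (nlevels(g) == 2) {
        stats::wilcox.test(x ~ g, exact = FALSE)$p.value
      } else {
        stats::kruskal.test(x, g)$p.value
      }
      for (lev in levels(g)) {
        xi <- x[g == lev]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, group = lev, type = "continuous",
          summary = sprintf("%.2f (%.2f)", mean(xi, na.rm = TRUE),
                            stats::sd(xi, na.rm = TRUE)),
          n = sum(!is.na(xi)), p = p)
      }
    } else {
      tab <- table(x, g)
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      for (lev in levels(g)) {
        cnt <- sum(g == lev & !is.na(x))
        top <- names(sort(table(x[g == lev]), decreasing = TRUE))[1]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, group = lev, type = "categorical",
          summary = sprintf("mode %s, n = %d", top, cnt),
          n = cnt, p = p)
      }
    }
  }
  do.call(rbind, rows)
}

#' Latent-class model for individual socioeconomic status
#'
#' Fits a k-class latent-class model with multinomial item-response
#' probabilities to categorical SES indicators (household income,
#' education level, employment status) by the EM algorithm with multiple
#' seeded starts, keeping the best log-likelihood. Classes are ordered by
#' their probability of the highest income level and labeled high /
#' medium / low (for k = 3; otherwise `class_1` ...).
#'
#' @param data Data frame with the indicator columns.
#' @param indicators Character vector of categorical indicator columns
#'   (default income, education, employment).
#' @param k Number of latent classes (default 3).
#' @param seed Integer seed.
#' @param n_start Number of EM starts (default 5).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Log-likelihood convergence tolerance.
#' @return Object of class `"lca_ses"`: `class` (per-row label),
#'   `posterior` (n x k), `item_probs` (per indicator: k x levels),
#'   `mixing` (class proportions), `loglik_trace`, `loglik`.
#' @export
lca_ses <- function(data,
                    indicators = c("income", "education", "employment"),
                    k = 3, seed = 1, n_start = 5, max_iter = 500,
                    tol = 1e-8) {
  missing_cols <- setdiff(indicators, names(data))
  if (length(missing_cols) > 0) {
    stop("indicator column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }
  items <- lapply(indicators, function(v) factor(data[[v]]))
  names(items) <- indicators
  n <- nrow(data)
  if (n < 100) stop("latent-class model needs at least 100 rows")
  ycode <- lapply(items, as.integer)
  nlev <- vapply(items, nlevels, integer(1))

  run_em <- function(start_seed) {
    # random responsibilities as the starting E-step
    resp <- .with_seed(start_seed, {
      r <- matrix(stats::runif(n * k, 0.05, 1), n, k)
      r / rowSums(r)
    })
    ll_trace <- numeric(0)
    ll_old <- -Inf
    mixing <- rep(1 / k, k)
    item_probs <- NULL
    for (iter in seq_len(max_iter)) {
      # M-step: class proportions and multinomial item-response probs
      mixing <- colMeans(resp)
      item_probs <- lapply(seq_along(items), function(j) {
        pr <- matrix(0, k, nlev[j])
        for (lev in seq_len(nlev[j])) {
          pr[, lev] <- colSums(resp[ycode[[j]] == lev, , drop = FALSE])
        }
        pr <- pr + 1e-10
        pr / rowSums(pr)
      })
      # E-step: posterior responsibilities and log-likelihood
      logp <- matrix(log(mixing), n, k, byrow = TRUE)
      for (j in seq_along(items)) {
        logp <- logp + t(log(item_probs[[j]])[, ycode[[j]], drop = FALSE])
      }
      m <- apply(logp, 1, max)
      lse <- m + log(rowSums(exp(logp - m)))
      ll <- sum(lse)
      resp <- exp(logp - lse)
      if (ll < ll_old - 1e-6) {
        stop("EM log-likelihood decreased (", ll_old, " -> ", ll,
             "): implementation error")
      }
      ll_trace <- c(ll_trace, ll)
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    names(item_probs) <- indicators
    for (j in seq_along(item_probs)) {
      colnames(item_probs[[j]]) <- levels(items[[j]])
    }
    list(loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
         mixing = mixing, item_probs = item_probs, posterior = resp)
  }

  best <- NULL
  for (s in seq_len(n_start)) {
    fit <- run_em(.child_seed(seed, 600L + s))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # order classes by affinity for the top income level -> high/medium/low
  inc <- best$item_probs[[indicators[1]]]
  top_level <- if ("high" %in% colnames(inc)) "high" else colnames(inc)[1]
  ord <- order(inc[, top_level], decreasing = TRUE)
  labels <- if (k == 3) c("high", "medium", "low") else
    paste0("class_", seq_len(k))
  best$posterior <- best$posterior[, ord, drop = FALSE]
  best$mixing <- best$mixing[ord]
  best$item_probs <- lapply(best$item_probs,
                            function(pr) pr[ord, , drop = FALSE])
  cls <- labels[max.col(best$posterior, ties.method = "first")]
  structure(list(class = cls, posterior = best$posterior,
                 item_probs = best$item_probs, mixing = best$mixing,
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 labels = labels, k = k, indicators = indicators),
            class = "lca_ses")
}

#' @export
print.lca_ses <- function(x, ...) {
  cat("Latent-class SES model: k = ", x$k, ", log-likelihood = ",
      format(x$loglik, digits = 8), "\n", sep = "")
  cat("class proportions: ",
      paste0(x$labels, " = ", format(x$mixing, digits = 3),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}
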