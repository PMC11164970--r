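# Seeded synthetic cohorts emulating the exposure correlation structure,
# demographics, planted mixture effects and exposure archetypes of a UK
# population cohort. All randomness is drawn under a locally scoped RNG so
# generation never disturbs the caller's random stream.

.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage child seeds derived from one master seed,
# kept inside the 32-bit integer range.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

# Polynomial rolling hash of a serialized R object, as a hex string; used
# only to fingerprint configurations in run manifests and cohort file
# headers. Closures (marginal quantile functions) are excluded so the
# fingerprint depends only on plain data.
.config_hash <- function(x) {
  if (is.list(x)) x <- x[!vapply(x, is.function, logical(1))]
  x <- rapply(x, function(el) if (is.function(el)) NULL else el,
              how = "replace")
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default exposure column names
#'
#' The eleven environmental exposures the package models: five air
#' pollutants (ug/m3), green and blue space percentages at 300 m and
#' 1000 m residential buffers, and day-evening-night and night-time road
#' traffic noise (dB).
#'
#' @return Character vector of length 11.
#' @export
exposure_names <- function() {
  c("pm10", "pm25", "pm_coarse", "no2", "nox",
    "green_300m", "green_1000m", "blue_300m", "blue_1000m",
    "noise_24h", "noise_night")
}

#' Default Spearman rank-correlation targets for the exposures
#'
#' Encodes the qualitative and quantitative correlation structure the
#' generator emulates: the four co-emitted pollutants (PM10, PM2.5, NO2,
#' NOx) pairwise 0.70; coarse particulate matter weakly tied to the rest;
#' green-space buffers 0.813 and blue-space buffers 0.629; green-blue
#' cross-pairs 0.18; the two noise metrics 0.85 (one is an energy component
#' of the other). Entries with no stated or structurally implied value
#' default to a weak positive 0.2.
#'
#' @return Symmetric 11 x 11 matrix with unit diagonal.
#' @export
default_spearman_targets <- function() {
  nm <- exposure_names()
  m <- matrix(0.2, 11, 11, dimnames = list(nm, nm))
  pollutants <- c("pm10", "pm25", "no2", "nox")
  m[pollutants, pollutants] <- 0.70
  m["green_300m", "green_1000m"] <- m["green_1000m", "green_300m"] <- 0.813
  m["blue_300m", "blue_1000m"] <- m["blue_1000m", "blue_300m"] <- 0.629
  for (g in c("green_300m", "green_1000m")) {
    for (b in c("blue_300m", "blue_1000m")) {
      m[g, b] <- m[b, g] <- 0.18
    }
  }
  m["noise_24h", "noise_night"] <- m["noise_night", "noise_24h"] <- 0.85
  diag(m) <- 1
  m
}

#' Default standardized archetype mean profiles
#'
#' Five exposure archetypes on the standardized (z) exposure scale:
#' an air-pollution profile (high particulates and nitrogen oxides, least
#' green space), a green-space profile (lowest pollution, greenest), a
#' rural-urban fringe profile (moderate everything), a noise profile
#' (most severe road-traffic noise) and a blue-space profile (most blue
#' space).
#'
#' @return 5 x 11 numeric matrix, rows named by archetype.
#' @export
default_archetype_means <- function() {
  nm <- exposure_names()
  m <- rbind(
    air_pollution      = c(1.4, 1.4, 1.0, 1.5, 1.5, -1.2, -1.2, -0.2, -0.2, 0.6, 0.6),
    green_space        = c(-1.1, -1.1, -0.8, -1.1, -1.1, 1.4, 1.4, 0.0, 0.0, -0.8, -0.8),
    rural_urban_fringe = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    noise              = c(0.4, 0.4, 0.3, 0.4, 0.4, -0.4, -0.4, -0.2, -0.2, 1.8, 1.8),
    blue_space         = c(-0.4, -0.4, -0.3, -0.4, -0.4, 0.3, 0.3, 1.8, 1.8, -0.2, -0.2)
  )
  colnames(m) <- nm
  m
}

# Marginal quantile functions mapping copula uniforms to plausible units:
# pollutants log-normal, green/blue logit-normal on [0, 100] percent,
# noise normal truncated to [30, 90] dB. Plausible ranges, not fit to data.
.qtrunc_norm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

.default_marginals <- function() {
  list(
    pm10        = function(p) stats::qlnorm(p, log(16), 0.15),
    pm25        = function(p) stats::qlnorm(p, log(10), 0.12),
    pm_coarse   = function(p) stats::qlnorm(p, log(6.1), 0.18),
    no2         = function(p) stats::qlnorm(p, log(26), 0.30),
    nox         = function(p) stats::qlnorm(p, log(42), 0.35),
    green_300m  = function(p) 100 * stats::plogis(-0.3 + 0.9 * stats::qnorm(p)),
    green_1000m = function(p) 100 * stats::plogis(-0.1 + 0.8 * stats::qnorm(p)),
    blue_300m   = function(p) 100 * stats::plogis(-4.2 + 1.1 * stats::qnorm(p)),
    blue_1000m  = function(p) 100 * stats::plogis(-3.8 + 1.0 * stats::qnorm(p)),
    noise_24h   = function(p) .qtrunc_norm(p, 55, 7, 30, 90),
    noise_night = function(p) .qtrunc_norm(p, 48, 7, 30, 90)
  )
}

#' Synthetic cohort generator configuration
#'
#' Collects every knob of the synthetic cohort generator with defaults that
#' encode the study conditions the package emulates: imaging-subcohort
#' demographics (age mean 55.46 y, SD 7.37 y), the default rank-correlation
#' targets of [default_spearman_targets()], five exposure archetypes, and a
#' planted weighted-quantile mixture effect on each outcome.
#'
#' @param n Number of participants (default 10000, a desk-scale cohort).
#' @param seed Integer master seed; stage-specific child seeds are derived
#'   from it, so one configuration fully determines the cohort.
#' @param exposures Character vector of exposure column names.
#' @param spearman_targets Symmetric target Spearman matrix over
#'   `exposures` with unit diagonal.
#' @param marginals Named list of quantile functions (one per exposure)
#'   mapping uniforms to measurement units; exposures without an entry get
#'   a standard-normal marginal.
#' @param archetype_means Matrix of standardized archetype mean profiles
#'   (rows = archetypes, columns = exposures), pairwise distinct rows.
#' @param archetype_proportions Archetype mixing proportions (simplex).
#' @param archetype_scatter_sd Within-archetype spherical Gaussian scatter
#'   SD on the standardized scale (default 0.5).
#' @param planted_weights Named per-outcome list (or single vector) of
#'   exposure weights on the simplex used to plant a mixture effect.
#' @param planted_beta Per-outcome scalar index effect (same names).
#' @param noise_sd Residual SD per outcome.
#' @param q Quantile count used to build the planted index.
#' @param age_mean,age_sd Chronological age distribution in years.
#' @param structure Either `"archetype"` (mixture of archetype profiles;
#'   the default, so subpopulation structure is present) or `"copula"`
#'   (pure Gaussian copula at the target correlations).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 10000,
                          seed = 1,
                          exposures = exposure_names(),
                          spearman_targets = NULL,
                          marginals = NULL,
                          archetype_means = NULL,
                          archetype_proportions = c(0.20, 0.25, 0.30, 0.125, 0.125),
                          archetype_scatter_sd = 0.5,
                          planted_weights = NULL,
                          planted_beta = c(phenoage_accel = 1.5,
                                           brain_volume_z = -0.15,
                                           cognitive_z = -0.1),
                          noise_sd = c(phenoage_accel = 4,
                                       brain_volume_z = 1,
                                       cognitive_z = 1),
                          q = 4,
                          age_mean = 55.46,
                          age_sd = 7.37,
                          structure = c("archetype", "copula")) {
  structure <- match.arg(structure)
  p <- length(exposures)
  if (is.null(spearman_targets)) {
    spearman_targets <- if (identical(exposures, exposure_names())) {
      default_spearman_targets()
    } else {
      diag(p)
    }
  }
  spearman_targets <- as.matrix(spearman_targets)
  if (!isTRUE(all.equal(spearman_targets, t(spearman_targets),
                        tolerance = 1e-12)) ||
      any(abs(diag(spearman_targets) - 1) > 1e-12)) {
    stop("spearman_targets must be symmetric with unit diagonal")
  }
  if (nrow(spearman_targets) != p) {
    stop("spearman_targets dimension does not match number of exposures")
  }
  dimnames(spearman_targets) <- list(exposures, exposures)
  if (is.null(marginals)) {
    marginals <- .default_marginals()[intersect(exposures,
                                                names(.default_marginals()))]
  }
  if (is.null(archetype_means)) {
    archetype_means <- if (identical(exposures, exposure_names())) {
      default_archetype_means()
    } else {
      NULL
    }
  }
  if (!is.null(archetype_means)) {
    archetype_means <- as.matrix(archetype_means)
    if (ncol(archetype_means) != p) {
      stop("archetype_means must have one column per exposure")
    }
    if (anyDuplicated(as.data.frame(archetype_means)) > 0) {
      stop("archetype_means rows must be pairwise distinct ",
           "(planted structure would be unrecoverable)")
    }
    if (length(archetype_proportions) != nrow(archetype_means)) {
      stop("archetype_proportions length must match archetype count")
    }
  }
  if (any(archetype_proportions < 0) ||
      abs(sum(archetype_proportions) - 1) > 1e-8) {
    stop("archetype_proportions must be nonnegative and sum to 1")
  }
  if (is.null(planted_weights)) {
    w <- stats::setNames(rep(0, p), exposures)
    if (identical(exposures, exposure_names())) {
      w[c("pm10", "pm25", "nox", "noise_24h")] <- c(0.35, 0.35, 0.2, 0.1)
    } else {
      w[1] <- 1
    }
    planted_weights <- w
  }
  if (!is.list(planted_weights)) {
    planted_weights <- stats::setNames(
      rep(list(planted_weights), length(planted_beta)), names(planted_beta))
  }
  for (w in planted_weights) {
    if (length(w) != p || any(w < -1e-12) || abs(sum(w) - 1) > 1e-8) {
      stop("each planted weight vector must lie on the exposure simplex")
    }
  }
  if (any(noise_sd < 0)) stop("noise_sd must be nonnegative")
  out <- list(n = n, seed = as.integer(seed), exposures = exposures,
              spearman_targets = spearman_targets, marginals = marginals,
              archetype_means = archetype_means,
              archetype_proportions = archetype_proportions,
              archetype_scatter_sd = archetype_scatter_sd,
              planted_weights = planted_weights,
              planted_beta = planted_beta, noise_sd = noise_sd, q = q,
              age_mean = age_mean, age_sd = age_sd, structure = structure)
  class(out) <- "cohort_config"
  out
}

# Pearson correlation of the latent Gaussian copula that induces a given
# Spearman correlation; tiny eigenvalue deficits are repaired to the
# nearest positive-semidefinite matrix with a warning, clear indefiniteness
# is an error.
.copula_correlation <- function(spearman_targets) {
  r <- 2 * sin(pi * spearman_targets / 6)
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) {
    stop("implied Gaussian-copula correlation for 'spearman_targets' is ",
         "not positive semidefinite (min eigenvalue ",
         format(min(ev), digits = 3), ")")
  }
  if (min(ev) < 0) {
    warning("repairing near-singular copula correlation to nearest PSD",
            call. = FALSE)
    ed <- eigen(r, symmetric = TRUE)
    r <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
  }
  r
}

# Symmetric square root usable for singular (comonotone) targets where
# Cholesky would fail.
.corr_sqrt <- function(r) {
  ed <- eigen(r, symmetric = TRUE)
  ed$vectors %*% diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
}

.apply_marginals <- function(z, config, scale_sd = 1) {
  u <- stats::pnorm(z / scale_sd)
  x <- z
  for (j in seq_along(config$exposures)) {
    nm <- config$exposures[j]
    qf <- config$marginals[[nm]]
    x[, j] <- if (is.null(qf)) stats::qnorm(u[, j]) else qf(u[, j])
  }
  colnames(x) <- config$exposures
  x
}

#' Generate copula-correlated synthetic exposures
#'
#' Draws a latent Gaussian vector with correlation chosen so the rank
#' correlations converge to `config$spearman_targets` (Pearson latent
#' correlation `2 sin(pi rho_s / 6)`), then pushes each margin through its
#' configured quantile function. Monotone margins preserve rank
#' correlations exactly, so the empirical Spearman matrix converges to the
#' targets as n grows. Pairs with a target of exactly 1 are made
#' comonotone (identical latent draws).
#'
#' @param config A [cohort_config()].
#' @return n x p numeric matrix of exposures in measurement units.
#' @export
generate_exposures <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  r <- .copula_correlation(config$spearman_targets)
  root <- .corr_sqrt(r)
  z <- .with_seed(.child_seed(config$seed, 1L), {
    matrix(stats::rnorm(config$n * ncol(r)), config$n) %*% root
  })
  # exact comonotonicity where the target says rho_s = 1
  tgt <- config$spearman_targets
  for (i in seq_len(ncol(tgt) - 1)) {
    for (j in seq(i + 1, ncol(tgt))) {
      if (tgt[i, j] >= 1 - 1e-12) z[, j] <- z[, i]
    }
  }
  .apply_marginals(z, config)
}

#' Generate archetype-structured synthetic exposures
#'
#' Draws each participant's archetype from the configured mixing
#' proportions, then scatters the standardized exposure vector spherically
#' (SD `archetype_scatter_sd`) around the archetype's mean profile before
#' mapping to measurement units through the marginal quantile functions.
#'
#' @param config A [cohort_config()] with non-NULL `archetype_means`.
#' @return List with `exposures` (n x p matrix in units), `labels`
#'   (integer archetype index per participant) and `archetypes` (row names
#'   of the mean matrix).
#' @export
generate_archetype_exposures <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$archetype_means)) {
    stop("config has no archetype_means; archetype structure undefined")
  }
  am <- config$archetype_means
  k <- nrow(am)
  res <- .with_seed(.child_seed(config$seed, 2L), {
    labels <- sample.int(k, config$n, replace = TRUE,
                         prob = config$archetype_proportions)
    z <- am[labels, , drop = FALSE] +
      config$archetype_scatter_sd *
        matrix(stats::rnorm(config$n * ncol(am)), config$n)
    list(labels = labels, z = z)
  })
  # total SD of the standardized mixture, used so marginal pushforward
  # keeps units in a plausible range
  mu <- colSums(am * config$archetype_proportions)
  between <- colSums(config$archetype_proportions * (am - rep(mu, each = k))^2)
  total_sd <- sqrt(between + config$archetype_scatter_sd^2)
  x <- .apply_marginals(sweep(res$z, 2, mu, "-"), config,
                        scale_sd = max(total_sd))
  list(exposures = x, labels = res$labels,
       archetypes = rownames(am) %||% paste0("archetype_", seq_len(k)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a plausible PhenoAge biomarker panel from age
#'
#' Draws the nine clinical biomarkers with age-linked means and
#' physiological spreads so that the computed phenotypic age is finite,
#' centered near chronological age, and strongly age-correlated. The
#' marginal choices are plausible clinical ranges, not fits to any cohort.
#'
#' @param age Numeric vector of chronological ages in years.
#' @param seed Integer seed.
#' @return Data frame with the ten [phenoage_biomarkers()] columns
#'   (including `age`).
#' @export
generate_biomarkers <- function(age, seed = 1) {
  if (any(!is.finite(age)) || any(age < 18) || any(age > 100)) {
    stop("ages must be finite and within [18, 100]")
  }
  n <- length(age)
  a <- age - 55
  .with_seed(.child_seed(seed, 3L), {
    data.frame(
      albumin        = stats::rnorm(n, 46 - 0.05 * a, 2.5),
      creatinine     = pmax(stats::rnorm(n, 72 + 0.15 * a, 12), 25),
      glucose        = pmax(stats::rnorm(n, 5.0 + 0.02 * a, 0.6), 2.5),
      crp            = stats::rlnorm(n, log(1.3) + 0.015 * a, 0.7),
      lymphocyte_pct = pmin(pmax(stats::rnorm(n, 29 - 0.08 * a, 6), 2), 70),
      mcv            = stats::rnorm(n, 91 + 0.05 * a, 4),
      rdw            = pmax(stats::rnorm(n, 13.5 + 0.025 * a, 0.85), 10),
      alp            = pmax(stats::rnorm(n, 83 + 0.3 * a, 20), 20),
      wbc            = pmax(stats::rnorm(n, 6.9, 1.6), 2),
      age            = age
    )
  })
}

#' Generate outcomes with a planted weighted-quantile mixture effect
#'
#' Linear structural model `y = beta * sum_i(w_i q_i) + C gamma + eps`
#' over quantized exposure scores, mirroring the weighted quantile sum
#' estimand, with the per-participant true index returned for recovery
#' tests.
#'
#' @param qscores Integer matrix of quantile scores (participants x
#'   exposures).
#' @param weights Exposure weight vector on the simplex.
#' @param beta Scalar index effect.
#' @param covariates Optional numeric matrix of covariates.
#' @param covariate_coefs Coefficients for `covariates` (recycled 0.5 if
#'   missing).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `outcome` and `index` (true weighted quantile index).
#' @export
generate_outcomes <- function(qscores, weights, beta, covariates = NULL,
                              covariate_coefs = NULL, noise_sd = 1,
                              seed = 1) {
  qscores <- as.matrix(qscores)
  if (length(weights) != ncol(qscores)) {
    stop("weights length must equal the number of exposure columns")
  }
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must lie on the simplex")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  index <- drop(qscores %*% weights)
  y <- beta * index
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(covariate_coefs)) {
      covariate_coefs <- rep(0.5, ncol(covariates))
    }
    y <- y + drop(covariates %*% covariate_coefs)
  }
  eps <- .with_seed(.child_seed(seed, 4L),
                    stats::rnorm(length(index), 0, noise_sd))
  list(outcome = y + eps, index = index)
}

#' Simulate a complete synthetic cohort
#'
#' Assembles exposures (archetype-structured by default), demographics,
#' PhenoAge biomarkers, frailty components, socioeconomic indicators
#' generated from a latent three-class SES structure, covariates and
#' outcomes carrying the configured planted mixture effects. Ground-truth
#' columns (`truth_archetype`, `truth_ses`, `truth_index_*`) are namespaced
#' with a `truth_` prefix so pipeline stages cannot read them by accident;
#' [read_cohort()] strips them by default.
#'
#' Outcomes: `phenoage` (years, computed from the generated biomarkers with
#' the planted exposure effect added on the year scale), `frailty_score`
#' (0-5, exposure-linked through the planted index), `brain_volume_z` and
#' `cognitive_z` (standardized continuous outcomes with planted negative
#' effects).
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `"cohort"`, one row per participant,
#'   with attribute `generator` carrying seed and config hash.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n

  if (config$structure == "archetype" && !is.null(config$archetype_means)) {
    arch <- generate_archetype_exposures(config)
    expo <- arch$exposures
    truth_archetype <- arch$archetypes[arch$labels]
  } else {
    expo <- generate_exposures(config)
    truth_archetype <- rep(NA_character_, n)
  }

  demo <- .with_seed(.child_seed(config$seed, 5L), {
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    sex <- sample(c("female", "male"), n, TRUE, prob = c(0.54, 0.46))
    ethnicity <- sample(c("white", "other"), n, TRUE, prob = c(0.94, 0.06))
    smoking <- sample(c("never", "previous", "current"), n, TRUE,
                      prob = c(0.55, 0.35, 0.10))
    bmi <- pmax(stats::rnorm(n, 27, 4.5), 15)
    alcohol <- sample(c("never", "monthly", "weekly", "daily"), n, TRUE,
                      prob = c(0.15, 0.25, 0.45, 0.15))
    exercise <- stats::runif(n) < 0.6
    diet <- stats::runif(n) < 0.4
    cvd <- stats::runif(n) < 0.07
    cancer <- stats::runif(n) < 0.05
    nses <- stats::rnorm(n)
    residence_years <- round(stats::rgamma(n, shape = 2.2, scale = 8), 1)
    # latent 3-class individual SES with class-separated indicator
    # multinomials, so the latent-class model is recoverable
    ses_class <- sample(c("high", "medium", "low"), n, TRUE,
                        prob = c(0.30, 0.40, 0.30))
    pr <- list(
      high   = list(income = c(0.70, 0.25, 0.05),
                    education = c(0.75, 0.20, 0.05),
                    employment = c(0.85, 0.10, 0.05)),
      medium = list(income = c(0.20, 0.60, 0.20),
                    education = c(0.25, 0.60, 0.15),
                    employment = c(0.60, 0.25, 0.15)),
      low    = list(income = c(0.05, 0.25, 0.70),
                    education = c(0.05, 0.25, 0.70),
                    employment = c(0.30, 0.25, 0.45))
    )
    draw_cat <- function(levels, item) {
      vapply(ses_class, function(cl) {
        sample(levels, 1, prob = pr[[cl]][[item]])
      }, character(1), USE.NAMES = FALSE)
    }
    list(age = age, sex = sex, ethnicity = ethnicity, smoking = smoking,
         bmi = bmi, alcohol = alcohol, exercise = exercise, diet = diet,
         cvd = cvd, cancer = cancer, nses = nses,
         residence_years = residence_years, ses_class = ses_class,
         income = draw_cat(c("high", "middle", "low"), "income"),
         education = draw_cat(c("degree", "secondary", "none"), "education"),
         employment = draw_cat(c("employed", "retired", "other"),
                               "employment"))
  })

  biomarkers <- generate_biomarkers(demo$age, seed = config$seed)

  # planted mixture effects act through the quantized exposure index
  qz <- quantize_table(expo, q = config$q)
  scores <- reverse_protective(
    qz$scores, q = config$q,
    which = intersect(colnames(qz$scores),
                      c("green_300m", "green_1000m",
                        "blue_300m", "blue_1000m")))

  out <- data.frame(id = seq_len(n), expo, check.names = FALSE)
  for (nm in names(demo)[names(demo) != "ses_class"]) out[[nm]] <- demo[[nm]]
  for (nm in setdiff(names(biomarkers), "age")) {
    out[[nm]] <- biomarkers[[nm]]
  }

  phenoage_base <- compute_phenoage(biomarkers, warn_ranges = FALSE)
  truth_index <- list()
  for (k in seq_along(config$planted_beta)) {
    onm <- names(config$planted_beta)[k]
    w <- config$planted_weights[[onm]] %||% config$planted_weights[[1]]
    gen <- generate_outcomes(scores, w, config$planted_beta[[onm]],
                             noise_sd = config$noise_sd[[onm]],
                             seed = .child_seed(config$seed, 10L + k))
    truth_index[[onm]] <- gen$index
    if (onm == "phenoage_accel") {
      out[["phenoage"]] <- phenoage_base + gen$outcome - mean(gen$outcome)
    } else {
      out[[onm]] <- gen$outcome
    }
  }

  # frailty components: age- and exposure-linked Bernoulli draws
  fr_index <- truth_index[[1]] - mean(truth_index[[1]])
  comp <- .with_seed(.child_seed(config$seed, 30L), {
    p_base <- stats::plogis(-2.6 + 0.035 * (demo$age - 55) + 0.25 * fr_index)
    data.frame(
      weight_loss  = stats::runif(n) < p_base * 0.8,
      exhaustion   = stats::runif(n) < p_base * 1.2,
      weakness     = stats::runif(n) < p_base,
      slow_gait    = stats::runif(n) < p_base * 0.9,
      low_activity = stats::runif(n) < p_base * 1.1
    )
  })
  out <- cbind(out, comp)
  out$frailty_score <- frailty_score(comp)

  out$truth_archetype <- truth_archetype
  out$truth_ses <- demo$ses_class
  for (onm in names(truth_index)) {
    out[[paste0("truth_index_", onm)]] <- truth_index[[onm]]
  }

  attr(out, "generator") <- list(seed = config$seed,
                                 config_hash = .config_hash(config),
                                 package_version =
                                   as.character(utils::packageVersion("envage")))
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort table to CSV with a metadata header
#'
#' Serializes the cohort as plain CSV preceded by `#`-commented header
#' lines recording the generator seed, configuration hash and column list,
#' so a written cohort can be re-read and schema-checked exactly.
#'
#' @param cohort A cohort data frame (as from [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  gen <- attr(cohort, "generator")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# envage cohort v1"),
    paste0("# seed: ", gen$seed %||% NA),
    paste0("# config_hash: ", gen$config_hash %||% NA),
    paste0("# columns: ", paste(names(cohort), collapse = ","))
  ), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' Validates the stored schema: columns recorded in the header must all be
#' present (missing ones are an error listing them); columns in the file
#' but not in the header produce a warning. Ground-truth columns
#' (`truth_*`) are stripped unless `keep_truth = TRUE`, so analysis stages
#' cannot read planted labels by accident.
#'
#' @param path CSV path written by [write_cohort()].
#' @param keep_truth Keep the `truth_*` ground-truth columns.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path, keep_truth = FALSE) {
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "#")]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^# ([a-z_]+): (.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(meta$columns)) {
    expected <- strsplit(meta$columns, ",", fixed = TRUE)[[1]]
    missing_cols <- setdiff(expected, names(df))
    if (length(missing_cols) > 0) {
      stop("cohort file is missing recorded column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    extra <- setdiff(names(df), expected)
    if (length(extra) > 0) {
      warning("cohort file has unrecorded column(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (!keep_truth) {
    df <- df[, !startsWith(names(df), "truth_"), drop = FALSE]
  }
  attr(df, "generator") <- list(
    seed = suppressWarnings(as.integer(meta$seed)),
    config_hash = meta$config_hash)
  class(df) <- c("cohort", "data.frame")
  df
}
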