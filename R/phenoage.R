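#' PhenoAge model constants
#'
#' The published coefficients of the phenotypic-age (PhenoAge) model: a
#' Gompertz parametric proportional-hazards fit of 10-year mortality on nine
#' clinical biomarkers plus chronological age, whose predicted risk is then
#' mapped back to a year scale. All values are fixed constants of the
#' published model and must not be re-estimated.
#'
#' Units expected by the linear predictor: albumin g/L, creatinine umol/L,
#' glucose mmol/L, C-reactive protein mg/L (entering as its natural log),
#' lymphocyte percent, mean corpuscular volume fL, red-cell distribution
#' width percent, alkaline phosphatase U/L, white-blood-cell count 10^9/L,
#' chronological age years.
#'
#' @return A named list with elements `intercept` (141.50225 years),
#'   `log_divisor` (0.090165), `hazard_scale` (-0.00553), `gamma`
#'   (0.0076927, the Gompertz shape per month), `horizon_months` (120),
#'   `xb_intercept` (-19.907) and `coefficients`, a named numeric vector
#'   over the nine biomarkers and age.
#' @export
#' @examples
#' phenoage_constants()$gamma
phenoage_constants <- function() {
  list(
    intercept      = 141.50225,
    log_divisor    = 0.090165,
    hazard_scale   = -0.00553,
    gamma          = 0.0076927,
    horizon_months = 120,
    xb_intercept   = -19.907,
    coefficients = c(
      albumin        = -0.0336,
      creatinine     =  0.0095,
      glucose        =  0.1953,
      log_crp        =  0.0954,
      lymphocyte_pct = -0.012,
      mcv            =  0.0268,
      rdw            =  0.3306,
      alp            =  0.00188,
      wbc            =  0.0554,
      age            =  0.0804
    )
  )
}

#' Biomarker column names of the PhenoAge panel
#'
#' @return Character vector of the ten columns `compute_xb()` consumes.
#' @export
phenoage_biomarkers <- function() {
  c("albumin", "creatinine", "glucose", "crp", "lymphocyte_pct",
    "mcv", "rdw", "alp", "wbc", "age")
}

# Plausible adult physiological ranges used only to warn on suspect input
# units; deliberately generous so real clinical spread never trips them.
.biomarker_ranges <- list(
  albumin        = c(25, 60),     # g/L
  creatinine     = c(20, 300),    # umol/L
  glucose        = c(2, 30),      # mmol/L
  crp            = c(0.01, 200),  # mg/L
  lymphocyte_pct = c(0, 100),     # %
  mcv            = c(60, 130),    # fL
  rdw            = c(9, 25),      # %
  alp            = c(10, 500),    # U/L
  wbc            = c(1, 50),      # 10^9/L
  age            = c(0, 120)      # years
)

.check_panel <- function(panel, warn_ranges = TRUE) {
  needed <- phenoage_biomarkers()
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0) {
    stop("biomarker panel is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in needed) {
    v <- panel[[nm]]
    if (!is.numeric(v)) stop("biomarker column '", nm, "' is not numeric")
    if (any(!is.finite(v))) {
      stop("non-finite value in biomarker column '", nm, "'")
    }
  }
  if (any(panel$crp <= 0)) {
    stop("crp must be strictly positive (its natural log enters the model)")
  }
  if (any(panel$lymphocyte_pct < 0 | panel$lymphocyte_pct > 100)) {
    stop("lymphocyte_pct must lie in [0, 100]")
  }
  if (warn_ranges) {
    for (nm in needed) {
      rng <- .biomarker_ranges[[nm]]
      bad <- sum(panel[[nm]] < rng[1] | panel[[nm]] > rng[2])
      if (bad > 0) {
        warning(bad, " value(s) of '", nm, "' outside the plausible range [",
                rng[1], ", ", rng[2], "]; check units", call. = FALSE)
      }
    }
  }
  invisible(panel)
}

#' Linear predictor of the PhenoAge mortality model
#'
#' Computes `xb`, the dimensionless Gompertz linear predictor, from a panel
#' of nine clinical biomarkers and chronological age. C-reactive protein
#' enters as its natural logarithm; every other marker enters on its raw
#' scale in the units listed under [phenoage_constants()].
#'
#' @param panel A data frame (or named list of equal-length numeric vectors)
#'   with columns `albumin`, `creatinine`, `glucose`, `crp`,
#'   `lymphocyte_pct`, `mcv`, `rdw`, `alp`, `wbc`, `age`.
#' @param warn_ranges Warn (without failing) when a value falls outside a
#'   generous physiological range, which usually indicates a unit mix-up.
#' @return Numeric vector of linear-predictor values, one per row.
#' @export
#' @examples
#' compute_xb(data.frame(albumin = 46, creatinine = 70, glucose = 4.9,
#'                       crp = 1.2, lymphocyte_pct = 30, mcv = 91,
#'                       rdw = 13.4, alp = 83, wbc = 6.9, age = 55))
compute_xb <- function(panel, warn_ranges = TRUE) {
  .check_panel(panel, warn_ranges = warn_ranges)
  k <- phenoage_constants()
  b <- k$coefficients
  k$xb_intercept +
    b[["albumin"]]        * panel$albumin +
    b[["creatinine"]]     * panel$creatinine +
    b[["glucose"]]        * panel$glucose +
    b[["log_crp"]]        * log(panel$crp) +
    b[["lymphocyte_pct"]] * panel$lymphocyte_pct +
    b[["mcv"]]            * panel$mcv +
    b[["rdw"]]            * panel$rdw +
    b[["alp"]]            * panel$alp +
    b[["wbc"]]            * panel$wbc +
    b[["age"]]            * panel$age
}

#' Ten-year mortality risk from the Gompertz linear predictor
#'
#' Maps `xb` to the model's 120-month mortality risk,
#' `1 - exp(-exp(xb) * (exp(120 * gamma) - 1) / gamma)`.
#' Strictly increasing in `xb` with range (0, 1).
#'
#' @param xb Numeric vector of finite linear-predictor values.
#' @return Mortality risks in (0, 1).
#' @export
mortality_risk_10yr <- function(xb) {
  if (any(!is.finite(xb))) stop("xb must be finite")
  k <- phenoage_constants()
  cum <- (exp(k$horizon_months * k$gamma) - 1) / k$gamma
  -expm1(-exp(xb) * cum)
}

#' Phenotypic age from ten-year mortality risk
#'
#' The published year-scale transform
#' `141.50225 + log(-0.00553 * log(1 - risk)) / 0.090165`.
#'
#' For risks extremely close to 1 the complement `1 - risk` underflows
#' when `risk` is stored directly, so the survival probability
#' `survival = 1 - risk` can be supplied instead; the transform then uses
#' `log(survival)` without ever forming the unrepresentable risk.
#'
#' @param risk Mortality risks, each strictly inside (0, 1). Ignored when
#'   `survival` is given.
#' @param survival Optional ten-year survival probabilities in (0, 1),
#'   the complement of `risk` on a numerically safe scale.
#' @return Phenotypic age in years.
#' @export
phenoage_from_risk <- function(risk, survival = NULL) {
  k <- phenoage_constants()
  if (is.null(survival)) {
    if (any(!is.finite(risk)) || any(risk <= 0) || any(risk >= 1)) {
      stop("risk must lie strictly inside (0, 1)")
    }
    log_surv <- log1p(-risk)
  } else {
    if (any(!is.finite(survival)) || any(survival <= 0) ||
        any(survival >= 1)) {
      stop("survival must lie strictly inside (0, 1)")
    }
    log_surv <- log(survival)
  }
  inner <- k$hazard_scale * log_surv       # -0.00553 * log(1 - risk) > 0
  k$intercept + log(inner) / k$log_divisor
}

#' Phenotypic age from a biomarker panel
#'
#' Composition of [compute_xb()], [mortality_risk_10yr()] and
#' [phenoage_from_risk()]: fully deterministic, vectorized over rows.
#' Internally the composition runs on the log-survival scale
#' (`-exp(xb) * (exp(120 gamma) - 1) / gamma`), which is algebraically
#' identical but immune to the risk saturating at 1 for extreme panels.
#'
#' @inheritParams compute_xb
#' @return Phenotypic age in years, one value per row of `panel`.
#' @export
compute_phenoage <- function(panel, warn_ranges = TRUE) {
  k <- phenoage_constants()
  xb <- compute_xb(panel, warn_ranges)
  cum <- (exp(k$horizon_months * k$gamma) - 1) / k$gamma
  log_surv <- -exp(xb) * cum
  inner <- k$hazard_scale * log_surv
  k$intercept + log(inner) / k$log_divisor
}

#' Fried frailty phenotype score
#'
#' Counts how many of the five Fried criteria (unintentional weight loss,
#' exhaustion, weakness, slow gait speed, low physical activity) are
#' present. The score is complete-case: any missing component makes the
#' whole score missing rather than imputing absence.
#'
#' @param components A data frame (or named list) with logical/0-1 columns
#'   `weight_loss`, `exhaustion`, `weakness`, `slow_gait`, `low_activity`.
#' @return Integer vector in 0..5, `NA_integer_` where any component is NA.
#' @export
#' @examples
#' frailty_score(data.frame(weight_loss = TRUE, exhaustion = FALSE,
#'                          weakness = TRUE, slow_gait = FALSE,
#'                          low_activity = FALSE))
frailty_score <- function(components) {
  needed <- c("weight_loss", "exhaustion", "weakness", "slow_gait",
              "low_activity")
  missing_cols <- setdiff(needed, names(components))
  if (length(missing_cols) > 0) {
    stop("frailty components missing: ", paste(missing_cols, collapse = ", "))
  }
  m <- sapply(needed, function(nm) {
    v <- components[[nm]]
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v[!is.na(v)] %in% c(0L, 1L))) {
      stop("frailty component '", nm, "' must be logical or 0/1")
    }
    v
  })
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  out <- as.integer(rowSums(m))
  out[apply(m, 1, anyNA)] <- NA_integer_
  out
}

#' Default Fried-criterion binarization of raw questionnaire fields
#'
#' An optional adapter that derives the five frailty components from raw
#' cohort fields. The cutoffs are this package's interpretation of the
#' standard Fried operationalization (sex-specific grip-strength thresholds,
#' lowest physical-activity category, self-reported slow walking pace,
#' self-reported exhaustion more than half the days, any self-reported
#' unintentional weight loss); they are a documented convention, not values
#' fixed by the source model.
#'
#' @param data Data frame with columns `grip_strength` (kg), `sex`
#'   (\"female\"/\"male\"), `activity_level` (integer, 1 = lowest category),
#'   `walking_pace` (\"slow\"/\"average\"/\"brisk\"), `exhausted_days`
#'   (0-3 ordinal frequency), `weight_loss_reported` (logical).
#' @return Data frame of the five logical components.
#' @export
fried_components <- function(data) {
  needed <- c("grip_strength", "sex", "activity_level", "walking_pace",
              "exhausted_days", "weight_loss_reported")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("fried_components missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  grip_cut <- ifelse(data$sex == "female", 17, 26)  # kg, sex-specific
  data.frame(
    weight_loss  = as.logical(data$weight_loss_reported),
    exhaustion   = data$exhausted_days >= 2,
    weakness     = data$grip_strength < grip_cut,
    slow_gait    = data$walking_pace == "slow",
    low_activity = data$activity_level <= 1
  )
}

#' Z-score a numeric vector
#'
#' Centers and scales to unit variance with the n-1 (sample) SD divisor.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
zscore <- function(x) {
  if (any(!is.finite(x))) stop("zscore: input must be finite")
  s <- stats::sd(x)
  if (length(x) < 2 || s == 0) stop("zscore: input is constant")
  (x - mean(x)) / s
}

#' Sample skewness (third standardized moment)
#' @param x Numeric vector.
#' @return Scalar skewness; 0 for constant input.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean(((x - mean(x)) / s)^3)
}

#' Normalize a skewed score, then z-score it
#'
#' Cognitive and volumetric scores are z-scored directly when approximately
#' normal; otherwise a rank-based inverse-normal (Blom) transform is applied
#' first. The normality screen is |skewness| > `skew_threshold` (default 1),
#' a concrete, testable rule. The rank transform preserves the ordering of
#' the input exactly (average ranks on ties).
#'
#' @param x Numeric vector, at least 10 finite observations.
#' @param skew_threshold Absolute skewness above which the inverse-normal
#'   transform is applied before z-scoring.
#' @return Z-scored (possibly rank-normalized) vector.
#' @export
normalize_then_zscore <- function(x, skew_threshold = 1) {
  if (sum(is.finite(x)) < 10) {
    stop("normalize_then_zscore needs at least 10 finite observations")
  }
  if (abs(skewness(x)) > skew_threshold) {
    r <- rank(x, ties.method = "average")
    x <- stats::qnorm((r - 0.375) / (length(x) + 0.25))
  }
  zscore(x)
}
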