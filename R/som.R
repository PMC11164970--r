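# Self-organizing-map discovery of exposure-pattern subpopulations:
# a rectangular batch-trained SOM on standardized exposures, Ward
# clustering of the codebook weighted by unit occupancy, WSS/BSS elbow
# selection of the subpopulation count, and profile-based naming.

#' Column-wise standardization of an exposure matrix
#'
#' Applies [zscore()] to every column so SOM distances are comparable
#' across exposures with different units.
#'
#' @param x Numeric matrix or data frame.
#' @return Matrix of z-scored columns with attributes `center` and
#'   `scale` for reuse on new data.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant column(s): ", paste(colnames(x)[scl == 0], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

# Squared Euclidean distances between the rows of two matrices.
.cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

#' Train a batch self-organizing map
#'
#' Rectangular grid, Gaussian neighborhood kernel, batch updates with a
#' linearly decaying neighborhood radius (from half the larger grid side
#' down to 0.1, so the final epochs refine units almost independently).
#' The codebook is linearly initialized along the first two principal
#' components of the data (the standard batch-SOM initialization), which
#' makes the fit fully deterministic; `seed` is kept in the interface for
#' provenance records and any seeded extensions. Quantization error (mean
#' distance to the best-matching unit) is recorded each epoch.
#'
#' @param x Numeric matrix of (standardized) observations, more rows than
#'   grid units.
#' @param grid Integer vector `c(rows, cols)`, each at least 2.
#' @param epochs Number of batch epochs (default 20).
#' @param seed Integer seed recorded with the model.
#' @return Object of class `"som_model"` with `codebook` (units x
#'   variables), `grid`, `grid_coords`, `qerror` (per epoch) and `seed`.
#' @export
train_som <- function(x, grid = c(10, 10), epochs = 20, seed = 1) {
  x <- as.matrix(x)
  if (length(grid) != 2 || any(grid < 2)) {
    stop("grid must be c(rows, cols) with both dimensions >= 2")
  }
  n_units <- prod(grid)
  if (nrow(x) <= n_units) stop("need more observations than grid units")
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("degenerate (constant) data: SOM training undefined")
  }
  coords <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                  col = seq_len(grid[2])))
  grid_d2 <- .cross_dist2(coords, coords)
  # linear initialization: grid spread over +/- 2 SD along the leading
  # principal components
  ctr <- colMeans(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v1 <- pc$rotation[, 1] * pc$sdev[1]
  v2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2] * pc$sdev[2] else
    rep(0, ncol(x))
  a <- seq(-2, 2, length.out = grid[1])[coords[, "row"]]
  b <- seq(-2, 2, length.out = grid[2])[coords[, "col"]]
  codebook <- rep(1, n_units) %o% ctr + a %o% v1 + b %o% v2
  radius0 <- max(grid) / 2
  qerror <- numeric(epochs)
  for (e in seq_len(epochs)) {
    sigma <- radius0 + (0.1 - radius0) * (e - 1) / max(epochs - 1, 1)
    d2 <- .cross_dist2(x, codebook)
    bmu_idx <- max.col(-d2, ties.method = "first")
    qerror[e] <- mean(sqrt(d2[cbind(seq_len(nrow(x)), bmu_idx)]))
    h <- exp(-grid_d2 / (2 * sigma^2))            # units x units kernel
    cnt <- tabulate(bmu_idx, n_units)
    sums <- rowsum(x, bmu_idx)                   # rows sorted by unit id
    S <- matrix(0, n_units, ncol(x))
    S[as.integer(rownames(sums)), ] <- sums
    num <- h %*% S
    den <- drop(h %*% cnt)
    upd <- den > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  structure(list(codebook = codebook, grid = grid, grid_coords = coords,
                 qerror = qerror, epochs = epochs, seed = seed,
                 center = attr(x, "center"), scale = attr(x, "scale")),
            class = "som_model")
}

#' Best-matching unit
#'
#' Index of the codebook vector nearest (Euclidean) to each observation;
#' exact ties resolve to the lowest unit index.
#'
#' @param x Numeric vector or matrix of observations (same columns as the
#'   codebook).
#' @param model A `"som_model"`.
#' @return Integer vector of unit indices.
#' @export
bmu <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d2 <- .cross_dist2(as.matrix(x), model$codebook)
  max.col(-d2, ties.method = "first")
}

#' Select the number of subpopulations by the WSS/BSS elbow
#'
#' Ward-clusters the SOM codebook (unit occupancy as cluster weights,
#' empty units excluded) and, for every candidate k, computes the within-
#' and between-subpopulation sums of squares of the induced participant
#' partition. The selected k maximizes the second difference of
#' WSS(k)/TSS - the sharpest flattening of the within-group variance curve.
#' Endpoint k values cannot host a second difference, so with fewer than
#' three candidates the smallest k is returned and the trace records that
#' no elbow comparison was possible.
#'
#' @param model A `"som_model"`.
#' @param x The (standardized) data matrix the map was trained on.
#' @param k_range Candidate subpopulation counts (within 2..units-1).
#' @return Object of class `"k_selection"`: `k` (selected), `k_range`,
#'   `wss`, `bss`, `tss`, `ratio` (WSS/TSS), `second_diff`, `hclust` (the
#'   Ward tree over occupied units), `unit_bmu` (participant BMUs) and
#'   `occupied` (indices of occupied units).
#' @export
select_k <- function(model, x, k_range = 2:8) {
  x <- as.matrix(x)
  n_units <- nrow(model$codebook)
  if (any(k_range < 2) || any(k_range > n_units - 1)) {
    stop("k_range must lie within [2, units - 1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  unit_bmu <- bmu(x, model)
  occ <- tabulate(unit_bmu, n_units)
  occupied <- which(occ > 0)
  hc <- stats::hclust(stats::dist(model$codebook[occupied, , drop = FALSE])^2,
                      method = "ward.D", members = occ[occupied])
  grand <- colMeans(x)
  tss <- sum(sweep(x, 2, grand)^2)
  wss <- bss <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    unit_cl <- integer(n_units)
    unit_cl[occupied] <- stats::cutree(hc, k = k_range[i])
    lab <- unit_cl[unit_bmu]
    for (cl in unique(lab)) {
      rows <- lab == cl
      ctr <- colMeans(x[rows, , drop = FALSE])
      wss[i] <- wss[i] + sum(sweep(x[rows, , drop = FALSE], 2, ctr)^2)
      bss[i] <- bss[i] + sum(rows) * sum((ctr - grand)^2)
    }
  }
  ratio <- wss / tss
  if (length(k_range) >= 3) {
    sd2 <- c(NA, diff(diff(ratio)), NA)  # ratio[i-1] - 2 ratio[i] + ratio[i+1]
    k <- k_range[which.max(sd2)]
    note <- "elbow: max second difference of WSS/TSS"
  } else {
    sd2 <- rep(NA_real_, length(k_range))
    k <- k_range[1]
    note <- "fewer than 3 candidates: no elbow comparison, smallest k kept"
  }
  structure(list(k = k, k_range = k_range, wss = wss, bss = bss, tss = tss,
                 ratio = ratio, second_diff = sd2, hclust = hc,
                 unit_bmu = unit_bmu, occupied = occupied, note = note),
            class = "k_selection")
}

#' Assign participants to subpopulations
#'
#' A participant's label is the cluster of its best-matching unit.
#'
#' @param x (Standardized) data matrix.
#' @param model A `"som_model"`.
#' @param unit_cluster Integer vector mapping every codebook unit to a
#'   cluster (0 allowed for empty units).
#' @return Integer cluster labels.
#' @export
assign_subpopulations <- function(x, model, unit_cluster) {
  if (length(unit_cluster) != nrow(model$codebook)) {
    stop("unit_cluster must map every codebook unit")
  }
  unit_cluster[bmu(x, model)]
}

# exposure family membership used for subpopulation naming
.exposure_families <- function(cols) {
  fam <- list(
    "air pollution" = intersect(cols, c("pm10", "pm25", "pm_coarse",
                                        "no2", "nox")),
    "green space"   = grep("^green", cols, value = TRUE),
    "blue space"    = grep("^blue", cols, value = TRUE),
    "noise"         = grep("^noise", cols, value = TRUE)
  )
  fam[lengths(fam) > 0]
}

#' Name subpopulations from their exposure profiles
#'
#' Each cluster is named after the exposure family (air pollution, green
#' space, blue space, noise) with the largest elevated mean standardized
#' exposure; a cluster whose family means all stay below `threshold` in
#' magnitude is the moderate-everything \"rural-urban fringe\" profile.
#' Duplicate names get numeric suffixes.
#'
#' @param labels Integer cluster labels per participant.
#' @param z Standardized exposure matrix (named columns).
#' @param threshold Magnitude below which a profile counts as moderate
#'   (default 0.25 z units).
#' @return Named character vector: one name per cluster (names are the
#'   cluster ids).
#' @export
name_subpopulations <- function(labels, z, threshold = 0.25) {
  z <- as.matrix(z)
  fams <- .exposure_families(colnames(z))
  if (length(fams) == 0) {
    fams <- stats::setNames(lapply(colnames(z), identity), colnames(z))
  }
  cls <- sort(unique(labels))
  nm <- character(length(cls))
  for (i in seq_along(cls)) {
    mz <- colMeans(z[labels == cls[i], , drop = FALSE])
    fmeans <- vapply(fams, function(cols) mean(mz[cols]), numeric(1))
    if (all(abs(fmeans) < threshold)) {
      nm[i] <- "rural-urban fringe"
    } else if (any(fmeans > threshold)) {
      nm[i] <- names(fmeans)[which.max(fmeans)]
    } else {
      nm[i] <- names(fmeans)[which.max(abs(fmeans))]
    }
  }
  # disambiguate duplicates deterministically
  for (dup in unique(nm[duplicated(nm)])) {
    at <- which(nm == dup)
    nm[at[-1]] <- paste0(dup, "-", seq_along(at[-1]) + 1)
  }
  stats::setNames(nm, cls)
}

#' Discover exposure-pattern subpopulations with a SOM
#'
#' End-to-end estimator: standardizes the exposures, trains a batch SOM,
#' Ward-clusters the codebook with WSS/BSS elbow selection of the number
#' of subpopulations, assigns every participant to the cluster of its
#' best-matching unit, and names clusters from their mean exposure
#' profiles.
#'
#' @param x Data frame or matrix of exposures (or a cohort data frame
#'   together with `exposures`).
#' @param exposures Optional character vector selecting exposure columns.
#' @param grid SOM grid `c(rows, cols)` (default 10 x 10).
#' @param k_range Candidate subpopulation counts (default 2:8).
#' @param epochs Training epochs (default 20).
#' @param seed Integer seed (codebook initialization).
#' @param name_threshold Moderate-profile threshold passed to
#'   [name_subpopulations()].
#' @param reference Name of the reference subpopulation for contrasts
#'   (default \"green space\").
#' @return Object of class `"som_subpop"` with the fitted `model`,
#'   `k_selection`, `unit_cluster`, integer `labels`, per-cluster `names`,
#'   per-participant `assignment` (factor of subpopulation names) and
#'   `reference`. Methods: `print`, `summary`, `plot`, `predict`.
#' @export
som_subpop <- function(x, exposures = NULL, grid = c(10, 10),
                       k_range = 2:8, epochs = 20, seed = 1,
                       name_threshold = 0.25, reference = "green space") {
  if (!is.null(exposures)) x <- x[, exposures, drop = FALSE]
  z <- standardize(x)
  model <- train_som(z, grid = grid, epochs = epochs, seed = seed)
  ks <- select_k(model, z, k_range = k_range)
  unit_cluster <- integer(nrow(model$codebook))
  unit_cluster[ks$occupied] <- stats::cutree(ks$hclust, k = ks$k)
  labels <- assign_subpopulations(z, model, unit_cluster)
  # name from skew-robust profiles: heavily skewed exposures (blue space
  # percentages especially) would otherwise drag every other cluster's
  # mean z negative and mask the moderate-everything profile
  z_name <- apply(as.matrix(x), 2, normalize_then_zscore)
  colnames(z_name) <- colnames(z)
  cl_names <- name_subpopulations(labels, z_name,
                                  threshold = name_threshold)
  assignment <- factor(cl_names[as.character(labels)],
                       levels = unname(cl_names))
  if (!reference %in% cl_names) {
    reference <- names(sort(table(assignment), decreasing = TRUE))[1]
  }
  structure(list(model = model, k_selection = ks,
                 unit_cluster = unit_cluster, labels = labels,
                 names = cl_names, assignment = assignment,
                 reference = reference, seed = seed,
                 exposures = colnames(z)),
            class = "som_subpop")
}

#' @export
print.som_subpop <- function(x, ...) {
  cat("SOM exposure-pattern subpopulations\n")
  cat("  grid ", x$model$grid[1], "x", x$model$grid[2], ", ",
      x$model$epochs, " epochs, selected k = ", x$k_selection$k,
      " (", x$k_selection$note, ")\n", sep = "")
  print(table(subpopulation = x$assignment))
  cat("  reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

#' @export
summary.som_subpop <- function(object, ...) {
  cat("Subpopulation selection trace (k, WSS/TSS, second difference):\n")
  print(data.frame(k = object$k_selection$k_range,
                   wss_over_tss = round(object$k_selection$ratio, 4),
                   second_diff = round(object$k_selection$second_diff, 5)))
  print(object)
  invisible(object)
}

#' Assign new observations to fitted subpopulations
#'
#' @param object A `"som_subpop"` fit.
#' @param newdata Data frame or matrix with the fitted exposure columns.
#' @param ... Unused.
#' @return Factor of subpopulation names.
#' @export
predict.som_subpop <- function(object, newdata, ...) {
  m <- object$model
  z <- sweep(sweep(as.matrix(newdata[, object$exposures, drop = FALSE]),
                   2, m$center), 2, m$scale, "/")
  labels <- assign_subpopulations(z, m, object$unit_cluster)
  factor(object$names[as.character(labels)], levels = unname(object$names))
}

#' Plot the subpopulation-count selection curve
#'
#' @param x A `"som_subpop"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.som_subpop <- function(x, ...) {
  ks <- x$k_selection
  graphics::plot(ks$k_range, ks$ratio, type = "b",
                 xlab = "number of subpopulations k",
                 ylab = "WSS / TSS", ...)
  graphics::abline(v = ks$k, lty = 2)
  invisible(x)
}

#' Contrast subpopulation aging metrics against a reference group
#'
#' Dummy-coded multiple linear regression of an aging metric on
#' subpopulation membership plus covariates; every non-reference
#' subpopulation gets a coefficient (difference vs the reference), with
#' normal-theory SE, 95 percent CI and two-sided p value.
#'
#' @param assignment Factor of subpopulation names (e.g. from
#'   [som_subpop()] `$assignment` or [predict.som_subpop()]).
#' @param outcome Numeric aging-metric vector.
#' @param data Optional data frame of covariates.
#' @param covariates Character vector of covariate columns in `data`.
#' @param reference Reference subpopulation name.
#' @return Data frame with one row per non-reference subpopulation:
#'   `subpopulation`, `beta`, `se`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
compare_subpopulations <- function(assignment, outcome, data = NULL,
                                   covariates = character(),
                                   reference = "green space") {
  assignment <- droplevels(as.factor(assignment))
  if (!reference %in% levels(assignment)) {
    stop("reference group '", reference, "' not present")
  }
  assignment <- stats::relevel(assignment, ref = reference)
  df <- data.frame(.y = outcome, .grp = assignment)
  rhs <- ".grp"
  if (length(covariates) > 0) {
    df <- cbind(df, data[, covariates, drop = FALSE])
    rhs <- paste(c(".grp", covariates), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  sm <- summary(fit)$coefficients
  rows <- grep("^\\.grp", rownames(sm))
  out <- data.frame(
    subpopulation = sub("^\\.grp", "", rownames(sm)[rows]),
    beta = sm[rows, 1], se = sm[rows, 2],
    ci_low = sm[rows, 1] - stats::qnorm(0.975) * sm[rows, 2],
    ci_high = sm[rows, 1] + stats::qnorm(0.975) * sm[rows, 2],
    p = sm[rows, 4], n = length(fit$residuals),
    row.names = NULL)
  attr(out, "reference") <- reference
  out
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions; 1 for identical
#' partitions (up to relabeling), around 0 for independent ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
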