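test_that("copula generator calibrates to rank-correlation targets", {
  # independence case
  cfg0 <- cohort_config(n = 10000, seed = 3,
                        exposures = paste0("v", 1:6),
                        spearman_targets = diag(6), marginals = list(),
                        archetype_means = NULL,
                        planted_weights = c(1, 0, 0, 0, 0, 0),
                        planted_beta = c(y = 0), noise_sd = c(y = 1))
  s0 <- spearman_matrix(generate_exposures(cfg0))
  expect_lt(max(abs(s0[upper.tri(s0)])), 0.05)

  # default targets at n = 20000: stated buffer correlations recovered
  cfg <- cohort_config(n = 20000, seed = 4, structure = "copula")
  s <- spearman_matrix(generate_exposures(cfg))
  expect_equal(s["green_300m", "green_1000m"], 0.813, tolerance = 0.03 / 0.813)
  expect_equal(s["blue_300m", "blue_1000m"], 0.629, tolerance = 0.03 / 0.629)
  expect_lt(max(abs(s - cfg$spearman_targets)), 0.03)

  # degenerate comonotone target gives exact rank agreement
  tgt <- matrix(c(1, 1, 1, 1), 2, 2)
  cfg1 <- cohort_config(n = 500, seed = 5, exposures = c("a", "b"),
                        spearman_targets = tgt, marginals = list(),
                        archetype_means = NULL, planted_weights = c(1, 0),
                        planted_beta = c(y = 0), noise_sd = c(y = 1))
  x1 <- suppressWarnings(generate_exposures(cfg1))
  expect_identical(cor(x1, method = "spearman")[1, 2], 1)

  # identical seed means identical output
  expect_identical(generate_exposures(cfg0), generate_exposures(cfg0))
})

test_that("clearly indefinite targets are rejected with a named error", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  cfg <- cohort_config(n = 100, seed = 1, exposures = c("a", "b", "c"),
                       spearman_targets = bad, marginals = list(),
                       archetype_means = NULL, planted_weights = c(1, 0, 0),
                       planted_beta = c(y = 0), noise_sd = c(y = 1))
  expect_error(generate_exposures(cfg), "spearman_targets")
  expect_error(cohort_config(n = 10, spearman_targets = diag(3)),
               "dimension")
})

test_that("archetype mixture plants recoverable subpopulation structure", {
  # zero-scatter limit: every member sits exactly on its archetype profile
  cfg0 <- cohort_config(n = 300, seed = 6, archetype_scatter_sd = 0)
  a0 <- generate_archetype_exposures(cfg0)
  for (lab in unique(a0$labels)) {
    rows <- a0$exposures[a0$labels == lab, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }

  # degenerate proportions put everyone in one archetype
  cfg1 <- cohort_config(n = 100, seed = 7,
                        archetype_proportions = c(1, 0, 0, 0, 0))
  expect_true(all(generate_archetype_exposures(cfg1)$labels == 1))

  # default scatter keeps the planted labels separable
  cfg <- cohort_config(n = 2000, seed = 8)
  a <- generate_archetype_exposures(cfg)
  z <- apply(a$exposures, 2, normalize_then_zscore)
  expect_gt(mean_silhouette(z, a$labels), 0.2)

  # duplicate archetype rows are unrecoverable and rejected
  am <- default_archetype_means()
  am[2, ] <- am[1, ]
  expect_error(cohort_config(archetype_means = am), "distinct")
})

test_that("biomarker panel is deterministic, physiological, and age-linked", {
  ages <- runif(400, 40, 70)
  p1 <- generate_biomarkers(ages, seed = 9)
  expect_identical(p1, generate_biomarkers(ages, seed = 9))
  expect_true(all(p1$crp > 0))
  expect_true(all(p1$lymphocyte_pct >= 0 & p1$lymphocyte_pct <= 100))
  expect_error(generate_biomarkers(c(30, 300)), "ages")

  big <- generate_biomarkers(rnorm(10000, 55.46, 7.37), seed = 10)
  pa <- compute_phenoage(big, warn_ranges = FALSE)
  expect_true(all(is.finite(pa)))
  expect_gt(cor(big$age, pa), 0.5)

  # with constant age, phenoage variance comes only from biomarker noise
  flat <- generate_biomarkers(rep(55, 500), seed = 11)
  expect_gt(var(compute_phenoage(flat, warn_ranges = FALSE)), 0)
})

test_that("outcome generator plants the configured index effect", {
  set.seed(12)
  qs <- matrix(sample(0:3, 5000 * 4, TRUE), ncol = 4)
  w <- c(0.5, 0.3, 0.2, 0)

  # null effect: outcome uncorrelated with the true index
  g0 <- generate_outcomes(qs, w, beta = 0, noise_sd = 1, seed = 13)
  expect_lt(abs(cor(g0$outcome, g0$index)), 3 / sqrt(5000))

  # noiseless: outcome is exactly beta * index
  g1 <- generate_outcomes(qs, w, beta = 2, noise_sd = 0, seed = 13)
  expect_equal(g1$outcome, 2 * g1$index)

  # OLS on the true index recovers the planted slope
  g2 <- generate_outcomes(qs, w, beta = 1, noise_sd = 1, seed = 14)
  expect_equal(unname(coef(lm(g2$outcome ~ g2$index))[2]), 1,
               tolerance = 0.1)

  expect_error(generate_outcomes(qs, w, 1, noise_sd = -1), "noise_sd")
  expect_error(generate_outcomes(qs, c(0.5, 0.5), 1), "length")
})

test_that("cohort files round-trip with schema checking and truth stripping", {
  co <- simulate_cohort(cohort_config(n = 120, seed = 15))
  expect_true(any(startsWith(names(co), "truth_")))

  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, keep_truth = TRUE)
  expect_identical(names(back), names(co))
  expect_equal(back$phenoage, co$phenoage, tolerance = 1e-10)
  expect_identical(back$truth_archetype, co$truth_archetype)

  clean <- read_cohort(path)
  expect_false(any(startsWith(names(clean), "truth_")))

  # extra unknown column: warning, not failure
  lines <- readLines(path)
  hdr_at <- max(grep("^#", lines))
  lines[hdr_at + 1] <- paste0(lines[hdr_at + 1], ",mystery")
  lines[-seq_len(hdr_at + 1)] <- paste0(lines[-seq_len(hdr_at + 1)], ",1")
  path2 <- tempfile(fileext = ".csv")
  writeLines(lines, path2)
  expect_warning(read_cohort(path2), "unrecorded")

  # missing exposure column: error listing it
  co2 <- co
  co2$pm10 <- NULL
  path3 <- tempfile(fileext = ".csv")
  attr(co2, "generator") <- attr(co, "generator")
  con <- file(path3, "w")
  writeLines(c("# envage cohort v1", paste0("# columns: ",
                                            paste(names(co), collapse = ","))),
             con)
  write.csv(as.data.frame(co2), con, row.names = FALSE)
  close(con)
  expect_error(read_cohort(path3), "pm10")
})

test_that("identical configuration reproduces the cohort byte for byte", {
  cfg <- cohort_config(n = 150, seed = 16)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
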