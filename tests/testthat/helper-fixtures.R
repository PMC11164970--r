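# Shared fixtures and independent oracles used across the suite.

# A mid-range clinical biomarker panel (units: g/L, umol/L, mmol/L, mg/L,
# %, fL, %, U/L, 10^9/L, years).
tiny_panel <- function(age = 55) {
  data.frame(albumin = 46, creatinine = 70, glucose = 4.9, crp = 1.2,
             lymphocyte_pct = 30, mcv = 91, rdw = 13.4, alp = 83,
             wbc = 6.9, age = age)
}

# Exhaustive 0.05-resolution simplex grid search for the 3-exposure WQS
# single-fit problem: the independent oracle for the softmax optimizer.
wqs_grid_oracle <- function(scores, y, direction = "positive") {
  s <- if (direction == "positive") 1 else -1
  qrC <- qr(matrix(1, length(y), 1))
  yt <- qr.resid(qrC, y)
  Qt <- qr.resid(qrC, scores)
  A <- crossprod(Qt); b <- drop(crossprod(Qt, yt)); yy <- sum(yt^2)
  best <- Inf
  for (w1 in seq(0, 1, 0.05)) {
    for (w2 in seq(0, 1 - w1, 0.05)) {
      w <- c(w1, w2, 1 - w1 - w2)
      quad <- drop(w %*% A %*% w)
      beta <- if (quad > 0) s * max(0, s * sum(w * b) / quad) else 0
      sse <- yy - 2 * beta * sum(w * b) + beta^2 * quad
      if (sse < best) best <- sse
    }
  }
  best
}

# Textbook Benjamini-Hochberg step-up: sort, m*p/i, running minimum from
# the largest p down, cap at 1 -- written independently of p.adjust.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m / seq_len(m)) * p[o]   # m * p_(i) / i
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Mean silhouette width of a labeling, computed by direct pairwise
# distances on a subsample.
mean_silhouette <- function(x, labels, max_n = 800, seed = 1) {
  set.seed(seed)
  if (nrow(x) > max_n) {
    keep <- sample.int(nrow(x), max_n)
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  d <- as.matrix(stats::dist(x))
  sil <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { sil[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

# Small exchangeably-correlated exposure generator config used in several
# WQS tests.
wqs_test_config <- function(n, seed, p = 6, rho = 0.3,
                            weights = c(0.4, 0.4, 0.2, rep(0, p - 3)),
                            beta = 1, noise_sd = 1) {
  tgt <- matrix(rho, p, p); diag(tgt) <- 1
  cohort_config(n = n, seed = seed, exposures = paste0("e", seq_len(p)),
                spearman_targets = tgt, marginals = list(),
                archetype_means = NULL, planted_weights = weights,
                planted_beta = c(y = beta), noise_sd = c(y = noise_sd))
}
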