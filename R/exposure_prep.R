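#' Quantile-score exposures
#'
#' Maps continuous exposure values to integer quantile scores 0..q-1, the
#' `q_i` entering a weighted quantile sum index. Boundaries are the interior
#' empirical quantiles (type-7, the default linear-interpolation rule) of
#' the data the scorer is fitted on; they can be reused to score new data
#' with the training boundaries, so a validation set never leaks into the
#' fit. Intervals are right-closed: a value exactly equal to a boundary
#' falls in the lower bin, and values outside the fitted range clamp to the
#' extreme scores.
#'
#' @param x Numeric vector to score (or to fit boundaries on).
#' @param q Number of quantile groups, at least 2. Default 4 (quartiles).
#' @param boundaries Optional numeric vector of q-1 non-decreasing interior
#'   boundaries from a previous fit; when supplied, `x` is scored with them
#'   and no fitting happens.
#' @return A list with `scores` (integer vector in 0..q-1) and `boundaries`
#'   (the q-1 boundaries used).
#' @export
#' @examples
#' quantize(c(1, 2, 3, 4), q = 4)$scores
quantize <- function(x, q = 4, boundaries = NULL) {
  if (q < 2) stop("q must be at least 2")
  if (any(!is.finite(x))) stop("quantize: input must be finite")
  if (is.null(boundaries)) {
    if (length(unique(x)) < q) {
      stop("quantize: need at least q distinct values to fit boundaries",
           " (constant or near-constant column)")
    }
    boundaries <- stats::quantile(x, probs = seq_len(q - 1) / q,
                                  type = 7, names = FALSE)
  } else {
    if (length(boundaries) != q - 1) {
      stop("boundaries must have length q - 1")
    }
    if (is.unsorted(boundaries)) stop("boundaries must be non-decreasing")
  }
  scores <- integer(length(x))
  for (b in boundaries) scores <- scores + (x > b)
  list(scores = as.integer(scores), boundaries = boundaries)
}

#' Quantile-score a table of exposures
#'
#' Column-wise [quantize()] over a data frame or matrix, optionally reusing
#' boundaries fitted earlier (e.g. fit on a training split, apply to a
#' validation split).
#'
#' @param x Data frame or numeric matrix of exposures.
#' @param q Number of quantile groups.
#' @param boundaries Optional named list of per-column boundary vectors.
#' @return List with `scores` (integer matrix, same dimnames) and
#'   `boundaries` (named list).
#' @export
quantize_table <- function(x, q = 4, boundaries = NULL) {
  x <- as.data.frame(x)
  out <- matrix(NA_integer_, nrow(x), ncol(x),
                dimnames = list(NULL, names(x)))
  fitted <- vector("list", ncol(x))
  names(fitted) <- names(x)
  for (nm in names(x)) {
    qz <- quantize(x[[nm]], q = q, boundaries = boundaries[[nm]])
    out[, nm] <- qz$scores
    fitted[[nm]] <- qz$boundaries
  }
  list(scores = out, boundaries = fitted)
}

#' Reverse protective exposure scores
#'
#' Flips quantile scores `s -> (q - 1) - s` for the named columns so that
#' larger scores represent *less* of a protective exposure (less green or
#' blue space). This keeps every component of a single-direction weighted
#' index pointing the same way. Applying the reversal twice restores the
#' original scores.
#'
#' @param scores Integer matrix of quantile scores in 0..q-1 with column
#'   names.
#' @param q Number of quantile groups the scores were fitted with.
#' @param which Character vector of column names to reverse.
#' @return The score matrix with the selected columns reversed.
#' @export
reverse_protective <- function(scores, q, which) {
  unknown <- setdiff(which, colnames(scores))
  if (length(unknown) > 0) {
    stop("unknown column(s) in 'which': ", paste(unknown, collapse = ", "))
  }
  if (any(scores < 0 | scores > q - 1)) {
    stop("scores outside 0..q-1 for the given q")
  }
  scores[, which] <- (as.integer(q) - 1L) - scores[, which]
  scores
}

#' Scale a predictor to interquartile-range units
#'
#' Divides by the IQR (type-7 quartiles) so that a regression slope on the
#' scaled variable reads as the effect of an IQR increase in the raw
#' exposure.
#'
#' @param x Numeric vector with positive IQR.
#' @return List with `scaled` (x / IQR) and `iqr`.
#' @export
iqr_scale <- function(x) {
  if (any(!is.finite(x))) stop("iqr_scale: input must be finite")
  qs <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  if (iqr <= 0) stop("iqr_scale: IQR is zero")
  list(scaled = x / iqr, iqr = iqr)
}

#' Day-evening-night weighted 24-hour noise level
#'
#' Energy-averages the three period levels over 24 hours with the standard
#' +5 dB evening and +10 dB night penalties:
#' `10 log10((h_d 10^(L_d/10) + h_e 10^((L_e+5)/10) + h_n 10^((L_n+10)/10)) / 24)`.
#' Default period spans are 12/4/8 h (07:00-19:00, 19:00-23:00,
#' 23:00-07:00, matching a 23:00-07:00 night window).
#'
#' @param l_day,l_evening,l_night Sound levels in dB (vectors recycle to a
#'   common length). `-Inf` denotes a silent period.
#' @param hours Numeric length-3 vector of day/evening/night spans; must
#'   partition 24 h.
#' @return Penalized 24-h average level in dB.
#' @export
#' @examples
#' lden(55, 55, 55)  # ~ 55 + 6.4 dB
lden <- function(l_day, l_evening, l_night, hours = c(12, 4, 8)) {
  if (length(hours) != 3 || abs(sum(hours) - 24) > 1e-9) {
    stop("hours must be three period spans summing to 24")
  }
  if (any(is.na(l_day)) || any(is.na(l_evening)) || any(is.na(l_night))) {
    stop("noise levels must not be missing")
  }
  e <- hours[1] * 10^(l_day / 10) +
    hours[2] * 10^((l_evening + 5) / 10) +
    hours[3] * 10^((l_night + 10) / 10)
  10 * log10(e / 24)
}
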