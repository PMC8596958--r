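#' Band-pass filter and decimate by spectral truncation
#'
#' Each region's series is Fourier-transformed; bins whose frequency
#' `k / duration` falls outside `[f_low, f_high]` are zeroed (the DC bin is
#' always zeroed), bins above `k_max = floor(f_high * duration)` are
#' discarded, and the remaining spectrum is inverse-transformed onto
#' `T' = 2 * k_max + 1` samples.  Decimation this way loses no in-band
#' information and removes the long-range autocorrelation a band-pass filter
#' would otherwise leave on the original grid.  With the default band and a
#' 1,200-point, 864-s session this yields 155 timepoints and a virtual
#' sampling interval of 864/155 = 5.57 s.
#'
#' @param series a [region_ts].
#' @param f_low,f_high band edges in Hz (inclusive); `f_high` must not exceed
#'   the Nyquist frequency `1 / (2 * tr)`.
#' @return A [region_ts] with `2 * floor(f_high * duration) + 1` timepoints
#'   and `tr = duration / T'`.
#' @examples
#' ts <- region_ts(matrix(rnorm(1200 * 3), 1200, 3), tr = 0.72)
#' out <- bandpass_decimate(ts, 0.008, 0.09)
#' nrow(out$values)  # 155
#' @export
bandpass_decimate <- function(series, f_low = 0.008, f_high = 0.09) {
  stopifnot(inherits(series, "region_ts"))
  Tn <- nrow(series$values)
  if (Tn < 4) stop("need at least 4 timepoints")
  if (!(f_low >= 0 && f_low < f_high)) stop("need 0 <= f_low < f_high")
  dur <- series$duration
  k_max <- floor(f_high * dur)
  # representable-bin check (equivalent to f_high <= Nyquist up to bin
  # rounding, so that re-filtering an already decimated series is a no-op)
  if (k_max > floor((Tn - 1) / 2)) {
    stop(sprintf("f_high = %g Hz exceeds the Nyquist frequency %g Hz",
                 f_high, 1 / (2 * series$tr)))
  }
  Tp <- 2L * as.integer(k_max) + 1L
  k <- seq_len(k_max)                    # positive-frequency bins kept
  freq <- k / dur
  keep <- freq >= f_low & freq <= f_high # DC (k = 0) excluded by construction

  spec <- stats::mvfft(series$values)    # Tn x R complex
  pos <- spec[1L + k, , drop = FALSE]
  pos[!keep, ] <- 0
  new_spec <- matrix(0 + 0i, Tp, ncol(series$values))
  new_spec[1L + k, ] <- pos * (Tp / Tn)
  new_spec[Tp + 1L - k, ] <- Conj(pos) * (Tp / Tn)
  out <- Re(stats::mvfft(new_spec, inverse = TRUE)) / Tp
  region_ts(out, tr = dur / Tp, region_ids = series$region_ids)
}

#' Standardize each region's series
#'
#' Per column: subtract the mean and divide by the standard deviation with
#' divisor T - 1 (the same divisor used for saliency temporal variance and
#' the delta-C normalizer, so that a standardized column has squared norm
#' exactly T - 1).
#'
#' @param series a [region_ts].
#' @param ddof degrees-of-freedom correction for the scale (default 1).
#' @return A [region_ts] with column means 0 and standard deviations 1.
#' @export
standardize <- function(series, ddof = 1L) {
  stopifnot(inherits(series, "region_ts"))
  X <- series$values
  Tn <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- sqrt(colSums(Xc^2) / (Tn - ddof))
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    stop("zero-variance region(s): ", paste(series$region_ids[bad], collapse = ", "))
  }
  region_ts(sweep(Xc, 2L, s, "/"), tr = series$tr, region_ids = series$region_ids)
}

#' Leakage-free confound decorrelation of the trait
#'
#' `fit_decorrelation` regresses the trait on the confounds plus an intercept
#' by ordinary least squares on *training* subjects only, and records the
#' coefficients together with the mean and standard deviation of the training
#' residuals.  `apply_decorrelation` residualizes any trait vector with the
#' stored coefficients and rescales with the stored training center/scale, so
#' no validation statistic ever enters the transformation.
#'
#' @param g_train numeric trait vector of training subjects.
#' @param confounds_train matrix of confounds (rows match `g_train`).
#' @return `fit_decorrelation`: a `decorrelation_model` with `coefficients`
#'   (intercept first), `train_center`, `train_scale`.
#'   `apply_decorrelation`: the adjusted, unit-scaled trait vector.
#' @examples
#' g <- rnorm(100); conf <- matrix(rnorm(200), 100, 2)
#' m <- fit_decorrelation(g, conf)
#' adj <- apply_decorrelation(m, g, conf)
#' round(c(mean(adj), sd(adj)), 6)
#' @export
fit_decorrelation <- function(g_train, confounds_train) {
  confounds_train <- as.matrix(confounds_train)
  if (nrow(confounds_train) != length(g_train)) {
    stop("rows of `confounds_train` must match length of `g_train`")
  }
  Xd <- cbind(`(Intercept)` = 1, confounds_train)
  if (qr(Xd)$rank < ncol(Xd)) stop("confound design matrix is rank deficient")
  fit <- stats::lm.fit(Xd, g_train)
  res <- fit$residuals
  ctr <- mean(res)
  scl <- stats::sd(res)
  if (!is.finite(scl) || scl <= 1e-12) {
    stop("training residual variance is zero: trait is linear in the confounds")
  }
  structure(
    list(coefficients = fit$coefficients, train_center = ctr, train_scale = scl),
    class = "decorrelation_model"
  )
}

#' @rdname fit_decorrelation
#' @param model a `decorrelation_model`.
#' @param g,confounds trait vector and confound matrix to transform (training
#'   or validation subjects).
#' @export
apply_decorrelation <- function(model, g, confounds) {
  stopifnot(inherits(model, "decorrelation_model"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != length(g)) stop("rows of `confounds` must match length of `g`")
  res <- g - cbind(1, confounds) %*% model$coefficients
  as.numeric((res - model$train_center) / model$train_scale)
}

#' Preprocess every session of a cohort
#'
#' Applies [bandpass_decimate()] then [standardize()] to each session in
#' place; the standard preparation before training or feature extraction.
#'
#' @param cohort a `cohort` with `sessions` (see [generate_dataset()]).
#' @param f_low,f_high band edges in Hz.
#' @return The cohort with filtered, standardized sessions.
#' @export
preprocess_cohort <- function(cohort, f_low = 0.008, f_high = 0.09) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$sessions))
  cohort$sessions <- lapply(cohort$sessions, function(sess) {
    lapply(sess, function(ts) standardize(bandpass_decimate(ts, f_low, f_high)))
  })
  cohort$preprocessed <- TRUE
  cohort
}
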