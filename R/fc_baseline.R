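#' Session-averaged functional-connectivity features
#'
#' Per session, the Pearson correlation matrix of the regional timeseries;
#' features are the upper triangle vectorized in fixed row-major (i < j)
#' order and averaged element-wise across sessions (R(R-1)/2 features;
#' 64,620 for R = 360).
#'
#' @param sessions list of standardized [region_ts] (or T x R matrices).
#' @return An `rsfc_features` list: `values` (feature vector), `pairs`
#'   (2-column matrix of region indices), `region_ids`.
#' @export
compute_rsfc <- function(sessions) {
  if (!is.list(sessions) || inherits(sessions, "region_ts")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  region_ids <- if (inherits(sessions[[1]], "region_ts")) {
    sessions[[1]]$region_ids
  } else {
    colnames(sessions[[1]]) %||% paste0("R", seq_len(ncol(sessions[[1]])))
  }
  R <- length(region_ids)
  ut <- upper.tri(matrix(0, R, R))
  acc <- 0
  for (s in sessions) {
    m <- as_session_matrix(s)
    sds <- apply(m, 2L, stats::sd)
    if (any(sds <= 0)) {
      stop("zero-variance region(s): ",
           paste(region_ids[sds <= 0], collapse = ", "))
    }
    C <- cor(m)
    acc <- acc + t(C)[t(ut)]  # row-major upper triangle (i < j)
  }
  pairs <- which(ut, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(values = acc / length(sessions), pairs = pairs,
                 region_ids = region_ids),
            class = "rsfc_features")
}

#' Elastic-net baseline on RSFC features
#'
#' The comparison model: features are filtered univariately on training data
#' (two-sided correlation test against the adjusted trait, p below
#' `filter_p`), then an elastic net with mixing parameter `alpha` is fit over
#' a 50-value lambda grid (log-spaced over four decades down from the
#' smallest lambda that zeroes every coefficient), selecting lambda by inner
#' k-fold cross-validated MSE on training data only.
#'
#' @param features n x P matrix of training RSFC features (rows = subjects),
#'   e.g. stacked `compute_rsfc(...)$values`.
#' @param g_adjusted adjusted trait of the training subjects.
#' @param alpha LASSO/ridge mixing parameter (default 0.05, near-ridge).
#' @param n_lambda size of the lambda grid (default 50).
#' @param inner_k inner CV folds for lambda selection (default 3).
#' @param filter_p univariate filter threshold (default 0.01).
#' @param seed seed for the inner-CV fold split.
#' @return An `fc_baseline_model` with the glmnet fit, the selected lambda,
#'   the surviving feature indices, and the filter/grid settings.
#' @export
fit_baseline <- function(features, g_adjusted, alpha = 0.05, n_lambda = 50L,
                         inner_k = 3L, filter_p = 0.01, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(g_adjusted) == n, n > inner_k)

  # univariate filter: correlation t-test p-value per feature, train only
  r <- suppressWarnings(as.numeric(cor(features, g_adjusted)))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pvals <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep <- which(pvals < filter_p)
  if (length(keep) < 2) {
    stop("fewer than 2 features survive the univariate filter; ",
         "raise `filter_p`")
  }
  Xf <- features[, keep, drop = FALSE]

  # lambda grid: glmnet-style path from lambda_max down four decades
  xs <- scale(Xf)
  lmax <- max(abs(crossprod(xs, g_adjusted - mean(g_adjusted)))) / (n * max(alpha, 1e-3))
  grid <- 10^seq(log10(lmax), log10(lmax) - 4, length.out = n_lambda)

  foldid <- with_seed(substream_seed(seed, "inner_cv"),
                      sample(rep_len(seq_len(inner_k), n)))
  cvfit <- glmnet::cv.glmnet(Xf, g_adjusted, alpha = alpha, lambda = grid,
                             foldid = foldid, standardize = TRUE)
  structure(list(fit = cvfit$glmnet.fit, lambda = cvfit$lambda.min,
                 keep = keep, alpha = alpha, filter_p = filter_p,
                 n_features_in = ncol(features)),
            class = "fc_baseline_model")
}

#' @rdname fit_baseline
#' @param object a fitted `fc_baseline_model`.
#' @param newdata feature matrix with the same columns as at fit time.
#' @param ... unused.
#' @export
predict.fc_baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features_in) {
    stop("`newdata` must have ", object$n_features_in, " features")
  }
  as.numeric(predict(object$fit, newdata[, object$keep, drop = FALSE],
                     s = object$lambda))
}

#' Cross-validated elastic-net baseline
#'
#' Runs the baseline under the same fold assignment and decorrelation scheme
#' as [run_cv()], so its metrics are directly comparable with the recurrent
#' ensemble's.
#'
#' @inheritParams run_cv
#' @param ... passed to [fit_baseline()].
#' @return List with per-fold metrics, `summary` (mean/stderr), and a
#'   predictions data.frame.
#' @export
run_cv_baseline <- function(cohort, fold_spec, ...) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$sessions))
  subj <- cohort$subjects
  feats <- t(vapply(cohort$sessions, function(s) compute_rsfc(s)$values,
                    numeric(length(compute_rsfc(cohort$sessions[[1]])$values))))
  folds_of <- fold_spec$subject_folds[subj$subject_id]
  fold_results <- lapply(seq_len(fold_spec$k), function(f) {
    tr <- which(folds_of != f); va <- which(folds_of == f)
    dec <- fit_decorrelation(subj$g[tr], cohort$confounds[tr, , drop = FALSE])
    g_tr <- apply_decorrelation(dec, subj$g[tr], cohort$confounds[tr, , drop = FALSE])
    g_va <- apply_decorrelation(dec, subj$g[va], cohort$confounds[va, , drop = FALSE])
    model <- fit_baseline(feats[tr, , drop = FALSE], g_tr, ...)
    yhat <- predict(model, feats[va, , drop = FALSE])
    list(fold = f, subject_ids = subj$subject_id[va], y = g_va, yhat = yhat,
         metrics = evaluate(g_va, yhat))
  })
  metric_mat <- vapply(fold_results, function(fr) unlist(fr$metrics), numeric(3))
  list(folds = fold_results,
       summary = list(mean = rowMeans(metric_mat),
                      stderr = apply(metric_mat, 1L, stats::sd) / sqrt(fold_spec$k)),
       predictions = do.call(rbind, lapply(fold_results, function(fr) {
         data.frame(subject_id = fr$subject_ids, fold = fr$fold, y = fr$y,
                    yhat = fr$yhat, stringsAsFactors = FALSE)
       })))
}
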