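#' Family-stratified k-fold assignment
#'
#' Families (not subjects) are the unit of assignment so that related
#' subjects never straddle a train/validation boundary.  Families are placed
#' into nine strata — terciles of family-averaged trait crossed with family
#' size groups (1, 2, 3+) — and dealt round-robin into the k folds.  Within a
#' stratum, families are first shuffled (seeded, randomizing ties) and then
#' stably ordered by family-averaged trait, so the round-robin deal spreads
#' the within-stratum trait gradient evenly across folds; the dealing
#' position carries over from stratum to stratum so fold sizes stay balanced
#' overall.
#'
#' @param records data.frame with columns `subject_id`, `family_id`, `g`
#'   (e.g. `cohort$subjects`).
#' @param k number of folds (default 10).
#' @param seed integer seed for the within-stratum shuffles.
#' @return A `fold_spec`: list with `k`, `assignment` (named integer vector
#'   family_id -> fold), `subject_folds` (named integer vector subject_id ->
#'   fold), and `seed`.
#' @export
make_folds <- function(records, k = 10L, seed = 1L) {
  stopifnot(all(c("subject_id", "family_id", "g") %in% names(records)))
  k <- stopifnot_scalar_count(k, "k")
  if (k < 2) stop("`k` must be at least 2")
  fam_g <- tapply(records$g, records$family_id, mean)
  fam_size <- tapply(records$g, records$family_id, length)
  fams <- names(fam_g)
  if (length(fams) < k) stop("fewer families than folds")

  edges <- quantile(fam_g, c(1 / 3, 2 / 3), names = FALSE)
  # ties at an edge go to the lower tercile
  tercile <- 1L + (fam_g > edges[1]) + (fam_g > edges[2])
  size_group <- pmin(fam_size, 3L)
  stratum <- paste(tercile, size_group, sep = ":")

  assignment <- integer(length(fams))
  names(assignment) <- fams
  pos <- 0L
  with_seed(substream_seed(seed, "folds"), {
    for (s in sort(unique(stratum))) {
      members <- fams[stratum == s]
      members <- members[sample.int(length(members))]
      members <- members[order(fam_g[members])]  # stable: ties stay shuffled
      for (f in members) {
        assignment[f] <- (pos %% k) + 1L
        pos <- pos + 1L
      }
    }
  })
  subject_folds <- assignment[records$family_id]
  names(subject_folds) <- records$subject_id
  structure(list(k = k, assignment = assignment,
                 subject_folds = subject_folds, seed = as.integer(seed)),
            class = "fold_spec")
}

#' Regression metrics: MSE, coefficient of determination, squared correlation
#'
#' `R^2 = 1 - MSE(y, yhat) / Var(y)` with the population variance (divisor
#' n, matching the MSE divisor), so that predicting the mean gives exactly 0.
#' `rho^2` is the squared Pearson correlation.
#'
#' @param y numeric vector of true values (length >= 3, nonzero variance).
#' @param yhat numeric vector of predictions.
#' @return List with `mse`, `r2`, `rho2`.
#' @examples
#' evaluate(c(1, 2, 3), c(1, 1, 3))  # mse 1/3, r2 0.5, rho2 0.75
#' @export
evaluate <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("`y` and `yhat` must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  vy <- mean((y - mean(y))^2)
  if (vy <= 0) stop("`y` has zero variance")
  if (stats::var(yhat) <= 0) stop("`yhat` has zero variance: rho^2 undefined")
  mse <- mean((y - yhat)^2)
  list(mse = mse, r2 = 1 - mse / vy, rho2 = cor(y, yhat)^2)
}

# per-subject ensemble predictions for a set of subjects, batched per member
predict_subjects <- function(members, session_mats, subject_index) {
  outs <- member_session_outputs(members, session_mats)  # members x sessions
  per_session <- colMeans(outs)
  as.numeric(tapply(per_session, subject_index, mean))
}

#' Run the full cross-validated pipeline
#'
#' For each fold: fit the confound decorrelation on training subjects and
#' apply it to both partitions; train an ensemble on all training sessions
#' (each session an independent sample, its subject's adjusted trait as
#' target); predict validation subjects by the flat mean over members and
#' sessions; and compute metrics.
#'
#' @param cohort a preprocessed `cohort` (see [preprocess_cohort()]).
#' @param fold_spec a [make_folds()] result.
#' @param arch an [arch_spec()]; its `input_dim` must match the cohort.
#' @param config a [training_config()].
#' @return A `cv_run`: list with per-fold `folds` (each holding `members`,
#'   `decorrelation`, validation `subject_ids`, `y`, `yhat`, `metrics`),
#'   `summary` (mean and stderr of each metric across folds), `predictions`
#'   data.frame, and the inputs needed to re-evaluate (`fold_spec`, `arch`,
#'   `config`).
#' @export
run_cv <- function(cohort, fold_spec, arch, config) {
  stopifnot(inherits(cohort, "cohort"), inherits(fold_spec, "fold_spec"))
  if (is.null(cohort$sessions)) stop("cohort has no sessions; run generate_dataset()")
  if (!isTRUE(cohort$preprocessed)) {
    stop("cohort must be preprocessed (bandpass + standardize) before training")
  }
  k <- fold_spec$k
  subj <- cohort$subjects
  folds_of <- fold_spec$subject_folds[subj$subject_id]
  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(folds_of != f)
    va_idx <- which(folds_of == f)
    if (length(va_idx) < 2) stop("fold ", f, " has fewer than 2 validation subjects")
    dec <- fit_decorrelation(subj$g[tr_idx], cohort$confounds[tr_idx, , drop = FALSE])
    g_tr <- apply_decorrelation(dec, subj$g[tr_idx], cohort$confounds[tr_idx, , drop = FALSE])
    g_va <- apply_decorrelation(dec, subj$g[va_idx], cohort$confounds[va_idx, , drop = FALSE])

    tr_mats <- unlist(lapply(cohort$sessions[tr_idx], function(s)
      lapply(s, function(x) x$values)), recursive = FALSE)
    n_sess <- vapply(cohort$sessions[tr_idx], length, integer(1))
    tr_targets <- rep(g_tr, times = n_sess)

    cfg_f <- config
    cfg_f$seed <- substream_seed(config$seed, "fold", index = f)
    members <- train_ensemble(arch, tr_mats, tr_targets, cfg_f)

    va_mats <- unlist(lapply(cohort$sessions[va_idx], function(s)
      lapply(s, function(x) x$values)), recursive = FALSE)
    va_sess_counts <- vapply(cohort$sessions[va_idx], length, integer(1))
    va_subject_index <- rep(seq_along(va_idx), times = va_sess_counts)
    yhat <- predict_subjects(members, va_mats, va_subject_index)

    fold_results[[f]] <- list(
      fold = f, members = members, decorrelation = dec,
      subject_ids = subj$subject_id[va_idx], y = g_va, yhat = yhat,
      metrics = evaluate(g_va, yhat)
    )
  }
  metric_mat <- vapply(fold_results, function(fr) unlist(fr$metrics), numeric(3))
  summary <- list(
    mean = rowMeans(metric_mat),
    stderr = apply(metric_mat, 1L, stats::sd) / sqrt(k)
  )
  predictions <- do.call(rbind, lapply(fold_results, function(fr) {
    data.frame(subject_id = fr$subject_ids, fold = fr$fold, y = fr$y,
               yhat = fr$yhat, stringsAsFactors = FALSE)
  }))
  structure(list(folds = fold_results, summary = summary,
                 predictions = predictions, fold_spec = fold_spec,
                 arch = arch, config = config),
            class = "cv_run")
}

#' @export
print.cv_run <- function(x, ...) {
  m <- x$summary$mean; s <- x$summary$stderr
  cat(sprintf("<cv_run> k = %d folds, %d members/fold\n", x$fold_spec$k,
              x$config$ensemble_size))
  cat(sprintf("  R^2   = %.3f (stderr %.3f)\n", m["r2"], s["r2"]))
  cat(sprintf("  rho^2 = %.3f (stderr %.3f)\n", m["rho2"], s["rho2"]))
  cat(sprintf("  MSE   = %.3f (stderr %.3f)\n", m["mse"], s["mse"]))
  invisible(x)
}

#' Cross-validated performance as a function of ensemble size
#'
#' For each n from 1 to the ensemble size, recomputes validation predictions
#' per fold using only the first n members in training order, and averages
#' the metric across folds.
#'
#' @param cv a `cv_run`.
#' @param cohort the same preprocessed cohort passed to [run_cv()].
#' @param metric `"r2"`, `"rho2"`, or `"mse"`.
#' @return Numeric vector of length `ensemble_size`: mean metric by size.
#' @export
ensemble_size_curve <- function(cv, cohort, metric = "r2") {
  stopifnot(inherits(cv, "cv_run"))
  N <- length(cv$folds[[1]]$members)
  subj <- cohort$subjects
  folds_of <- cv$fold_spec$subject_folds[subj$subject_id]
  # cache per-member per-session outputs once per fold
  per_fold <- lapply(cv$folds, function(fr) {
    va_idx <- which(folds_of == fr$fold)
    mats <- unlist(lapply(cohort$sessions[va_idx], function(s)
      lapply(s, function(x) x$values)), recursive = FALSE)
    counts <- vapply(cohort$sessions[va_idx], length, integer(1))
    list(outs = member_session_outputs(fr$members, mats),
         subject_index = rep(seq_along(va_idx), times = counts),
         y = fr$y)
  })
  vapply(seq_len(N), function(n) {
    vals <- vapply(per_fold, function(pf) {
      per_session <- colMeans(pf$outs[seq_len(n), , drop = FALSE])
      yhat <- as.numeric(tapply(per_session, pf$subject_index, mean))
      evaluate(pf$y, yhat)[[metric]]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
}
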