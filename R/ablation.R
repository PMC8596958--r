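#' Ablate regions from a standardized session
#'
#' Replaces the listed regions' columns with zeros — the post-standardization
#' mean — leaving everything else untouched, so the model loses the regions'
#' information with minimal distribution shift.
#'
#' @param session a standardized [region_ts].
#' @param region_set character vector of region ids (or integer indices).
#' @return The ablated [region_ts].
#' @export
ablate_regions <- function(session, region_set) {
  stopifnot(inherits(session, "region_ts"))
  idx <- resolve_regions(region_set, session$region_ids)
  if (length(idx)) session$values[, idx] <- 0
  session
}

resolve_regions <- function(region_set, region_ids) {
  if (length(region_set) == 0) return(integer(0))
  if (is.numeric(region_set)) {
    idx <- as.integer(region_set)
    if (any(idx < 1 | idx > length(region_ids))) stop("region index out of range")
    return(idx)
  }
  idx <- match(region_set, region_ids)
  if (anyNA(idx)) {
    stop("unknown region label(s): ",
         paste(region_set[is.na(idx)], collapse = ", "))
  }
  idx
}

# Precompute everything ablation needs: per fold, the validation batch cube,
# the session -> subject map, targets, baseline metrics.  Reused across the
# hundreds of ablations a resampling null performs.
ablation_cache <- function(cv, cohort, metric = "r2") {
  stopifnot(inherits(cv, "cv_run"))
  subj <- cohort$subjects
  folds_of <- cv$fold_spec$subject_folds[subj$subject_id]
  region_ids <- cohort$truth$region_ids %||% cohort$sessions[[1]][[1]]$region_ids
  folds <- lapply(cv$folds, function(fr) {
    va_idx <- which(folds_of == fr$fold)
    mats <- unlist(lapply(cohort$sessions[va_idx], function(s)
      lapply(s, function(x) x$values)), recursive = FALSE)
    counts <- vapply(cohort$sessions[va_idx], length, integer(1))
    list(cube = sessions_to_cube(mats),
         subject_index = rep(seq_along(va_idx), times = counts),
         y = fr$y, members = fr$members,
         baseline = fr$metrics[[metric]])
  })
  structure(list(folds = folds, metric = metric, region_ids = region_ids,
                 k = cv$fold_spec$k), class = "ablation_cache")
}

fold_metric_ablated <- function(fold, idx, metric) {
  X <- fold$cube
  if (length(idx)) X[idx, , ] <- 0
  outs <- t(vapply(fold$members, function(p) as.numeric(cpp_bilstm_forward(p, X)),
                   numeric(dim(X)[2])))
  per_session <- colMeans(outs)
  yhat <- as.numeric(tapply(per_session, fold$subject_index, mean))
  metric_value(fold$y, yhat, metric)
}

# (n_sets x k) matrix of ablated validation metrics.  All sets of one fold
# are evaluated in a single C++ call (members parsed once), which is what
# makes 300-iteration resampling nulls and per-draw null pools affordable.
ablated_metric_matrix <- function(cache, idx_list) {
  k <- length(cache$folds)
  metric <- cache$metric
  sets_cpp <- lapply(idx_list, as.integer)
  out <- matrix(0, length(idx_list), k)
  for (f in seq_len(k)) {
    fold <- cache$folds[[f]]
    outs <- cpp_forward_ablate_sets(fold$members, fold$cube, sets_cpp)
    counts <- as.vector(table(fold$subject_index))
    yhat <- t(rowsum(t(outs), fold$subject_index) / counts)  # n_sets x n_subj
    y <- fold$y
    out[, f] <- switch(metric,
      mse = rowMeans(sweep(yhat, 2, y)^2),
      r2 = 1 - rowMeans(sweep(yhat, 2, y)^2) / mean((y - mean(y))^2),
      rho2 = apply(yhat, 1, function(v) metric_value(y, v, "rho2"))
    )
  }
  out
}

# like evaluate() but tolerant of degenerate (e.g. fully ablated) predictions:
# a constant yhat has no correlation skill, so rho^2 is reported as 0.
metric_value <- function(y, yhat, metric) {
  switch(metric,
    mse = mean((y - yhat)^2),
    r2 = 1 - mean((y - yhat)^2) / mean((y - mean(y))^2),
    rho2 = if (stats::var(yhat) > 0) cor(y, yhat)^2 else 0,
    stop("unknown metric: ", metric)
  )
}

#' Paired ablation test of a region set
#'
#' Re-evaluates each fold's validation metric with the region set zeroed out
#' and forms the paired T statistic (df = k - 1) of the per-fold degradation
#' `baseline - ablated`; positive t means ablation degrades performance.
#'
#' @param cv a `cv_run`.
#' @param cohort the preprocessed cohort used for `cv`.
#' @param region_set region ids (or indices) to ablate.
#' @param metric metric to compare (default `"r2"`).
#' @param cache optional precomputed `ablation_cache` (built internally
#'   otherwise; pass one when testing many sets).
#' @return An `ablation_result`: list with `region_set`, `per_fold_baseline`,
#'   `per_fold_ablated`, `deltas`, `t_stat`, `flag` (`"ok"`, `"zero_delta"`
#'   or `"degenerate_variance"`).
#' @export
ablation_test <- function(cv, cohort, region_set, metric = "r2", cache = NULL) {
  cache <- cache %||% ablation_cache(cv, cohort, metric)
  if (cache$k < 3) stop("paired T over folds needs k >= 3")
  idx <- resolve_regions(region_set, cache$region_ids)
  ablated <- ablated_metric_matrix(cache, list(idx))[1, ]
  baseline <- vapply(cache$folds, function(f) f$baseline, numeric(1))
  deltas <- baseline - ablated
  sd_d <- stats::sd(deltas)
  if (all(deltas == 0)) {
    t_stat <- 0; flag <- "zero_delta"
  } else if (sd_d == 0) {
    t_stat <- sign(mean(deltas)) * 1e6; flag <- "degenerate_variance"
  } else {
    t_stat <- mean(deltas) / (sd_d / sqrt(length(deltas))); flag <- "ok"
  }
  structure(list(region_set = cache$region_ids[idx],
                 per_fold_baseline = baseline, per_fold_ablated = ablated,
                 deltas = deltas, t_stat = t_stat, flag = flag,
                 metric = cache$metric),
            class = "ablation_result")
}

#' Size-matched resampling null for ablation statistics
#'
#' Draws `n_iter` uniformly random region subsets of size `set_size` (without
#' replacement within a subset) and records the paired T statistic of each,
#' giving the null distribution against which a named network's degradation
#' is judged.
#'
#' @inheritParams ablation_test
#' @param set_size number of regions per random subset.
#' @param n_iter number of resampled subsets (default 300).
#' @param seed integer seed.
#' @return A `null_distribution`: list with `set_size`, `n_iter`, `t_values`,
#'   `seed`.
#' @export
resample_null <- function(cv, cohort, set_size, n_iter = 300L, seed = 1L,
                          metric = "r2", cache = NULL) {
  cache <- cache %||% ablation_cache(cv, cohort, metric)
  R <- length(cache$region_ids)
  stopifnot(set_size >= 1, set_size <= R)
  sets <- with_seed(substream_seed(seed, "null", index = set_size), {
    lapply(seq_len(n_iter), function(i) sample.int(R, set_size))
  })
  ablated <- ablated_metric_matrix(cache, sets)
  baseline <- vapply(cache$folds, function(f) f$baseline, numeric(1))
  deltas <- matrix(baseline, nrow(ablated), ncol(ablated), byrow = TRUE) - ablated
  t_values <- apply(deltas, 1, paired_t)
  structure(list(set_size = as.integer(set_size), n_iter = as.integer(n_iter),
                 t_values = t_values, seed = as.integer(seed)),
            class = "null_distribution")
}

#' Empirical p-value against a resampling null
#'
#' One-sided toward degradation with the add-one correction:
#' `p = (1 + #\{t_null >= t_obs\}) / (n_iter + 1)`, so p is never zero.
#'
#' @param t_obs observed paired T statistic.
#' @param null a `null_distribution`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(t_obs, null) {
  stopifnot(inherits(null, "null_distribution"), length(null$t_values) >= 1)
  (1 + sum(null$t_values >= t_obs)) / (length(null$t_values) + 1)
}

#' FDR adjustment of ablation p-values
#'
#' Benjamini-Yekutieli (default) or Benjamini-Hochberg step-up adjustment
#' over the hypothesis family of one analysis.
#'
#' @param p_list numeric vector of p-values.
#' @param method `"BY"` or `"BH"`.
#' @return Vector of adjusted q-values.
#' @export
fdr_adjust <- function(p_list, method = c("BY", "BH")) {
  if (length(p_list) == 0) stop("empty p-value list")
  method <- match.arg(method)
  stats::p.adjust(p_list, method = method)
}

#' Ablation analysis of a family of region sets
#'
#' Runs [ablation_test()] for every named set, builds one size-matched null
#' per distinct set size, and reports empirical p-values with FDR-adjusted
#' q-values across the family.
#'
#' @inheritParams ablation_test
#' @param sets named list of region-id vectors (e.g. networks of a
#'   partition via [partition_sets()], or saliency-defined networks).
#' @param n_iter null iterations per distinct size (default 300).
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @param seed integer seed for the null resampling.
#' @return A data.frame with columns `set`, `M`, `t`, `p`, `q`, `flag`, plus
#'   attribute `nulls` (the `null_distribution`s keyed by size).
#' @export
ablation_study <- function(cv, cohort, sets, n_iter = 300L, metric = "r2",
                           fdr_method = c("BY", "BH"), seed = 1L) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  cache <- ablation_cache(cv, cohort, metric)
  results <- lapply(sets, function(s)
    ablation_test(cv, cohort, s, metric = metric, cache = cache))
  sizes <- vapply(sets, length, integer(1))
  nulls <- lapply(unique(sizes), function(M)
    resample_null(cv, cohort, M, n_iter = n_iter, seed = seed,
                  metric = metric, cache = cache))
  names(nulls) <- as.character(unique(sizes))
  p <- mapply(function(res, M) empirical_p(res$t_stat, nulls[[as.character(M)]]),
              results, sizes)
  out <- data.frame(set = names(sets), M = sizes,
                    t = vapply(results, function(r) r$t_stat, numeric(1)),
                    p = p, q = fdr_adjust(p, fdr_method),
                    flag = vapply(results, function(r) r$flag, character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "nulls") <- nulls
  out
}

#' Region sets of a partition
#'
#' @param partition a `network_partition`.
#' @return Named list mapping network label to its region ids.
#' @export
partition_sets <- function(partition) {
  stopifnot(inherits(partition, "network_partition"))
  split(names(partition$assignment), partition$assignment)[names(partition$sizes)]
}
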