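#' Input-gradient saliency through standardization
#'
#' The exact gradient of a model's (or ensemble's) scalar session output with
#' respect to the input timeseries, with the per-region standardization stage
#' inside the differentiable graph.  Writing z = (x - mean(x)) / sd(x) per
#' region and G for the gradient with respect to z, the chain rule gives
#'
#'   dN/dx = (1/sd) * (G - mean_t(G) - z * <G, z> / (T - 1))
#'
#' which forces two structural invariants: each region's saliency sums to
#' zero over time, and is orthogonal to that region's standardized series.
#' The ensemble saliency is the mean of member saliencies (the ensemble
#' output is the mean output).
#'
#' @param model trained `rnn_params`, or a list of members (ensemble).
#' @param session a [region_ts]: the raw (post-decimation) series when
#'   `input = "raw"`, or an already standardized series when
#'   `input = "standardized"` (the projection is still applied; only the
#'   1/sd rescaling differs).
#' @param input whether `session` is pre- or post-standardization.
#' @return A `saliency_tensor`: list with `values` (T x R), `region_ids`,
#'   `n_members`.
#' @export
input_saliency <- function(model, session, input = c("standardized", "raw")) {
  input <- match.arg(input)
  stopifnot(inherits(session, "region_ts"))
  is_single <- inherits(model, "rnn_params") ||
    (is.list(model) && !is.null(model$l1f))
  members <- if (is_single) list(model) else model
  raw <- input == "raw"
  z_ts <- if (raw) standardize(session) else session
  sal <- batch_saliency(members, list(z_ts$values))[, 1, , drop = TRUE]  # d x T
  if (!all(is.finite(sal))) stop("non-finite saliency gradient")
  values <- t(sal)
  if (raw) {
    Tn <- nrow(session$values)
    mu <- colMeans(session$values)
    sds <- sqrt(colSums(sweep(session$values, 2L, mu)^2) / (Tn - 1))
    values <- sweep(values, 2L, sds, "/")
  }
  structure(list(values = values, region_ids = session$region_ids,
                 n_members = length(members)),
            class = "saliency_tensor")
}

# Ensemble-mean saliency for a batch of *standardized* session matrices.
# Returns a cube (d, B, T): for each session, the mean over members of the
# gradient of the scalar output w.r.t. the session, projected through the
# standardization Jacobian (zero-sum and data-orthogonal per region).
batch_saliency <- function(members, mats, chunk = 128L) {
  d <- ncol(mats[[1]]); Tn <- nrow(mats[[1]]); B <- length(mats)
  out <- array(0, c(d, B, Tn))
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    X <- sessions_to_cube(mats[idx])
    acc <- array(0, c(d, length(idx), Tn))
    for (p in members) {
      acc <- acc + cpp_bilstm_backward(p, X, rep(1, length(idx)))$dX
    }
    acc <- acc / length(members)
    # project through standardization per session
    for (j in seq_along(idx)) {
      G <- acc[, j, , drop = TRUE]            # d x T
      Z <- t(mats[[idx[j]]])                  # d x T
      G <- G - rowMeans(G) - Z * (rowSums(G * Z) / (Tn - 1))
      out[, idx[j], ] <- G
    }
  }
  out
}

#' Temporal variance of saliency per region
#'
#' Sum of squared saliencies over time divided by T - 1; because saliencies
#' sum to zero over time by construction, this is their sample variance.
#'
#' @param sal a `saliency_tensor` or a T x R saliency matrix.
#' @return Named nonnegative vector, one value per region.
#' @export
saliency_temporal_variance <- function(sal) {
  values <- if (inherits(sal, "saliency_tensor")) sal$values else as.matrix(sal)
  Tn <- nrow(values)
  if (Tn < 2) stop("need at least 2 timepoints")
  v <- colSums(values^2) / (Tn - 1)
  names(v) <- if (inherits(sal, "saliency_tensor")) sal$region_ids else colnames(values)
  v
}

# Mean saliency-temporal-variance map over a set of standardized sessions.
saliency_variance_map <- function(members, mats, region_ids = NULL) {
  Tn <- nrow(mats[[1]])
  sal <- batch_saliency(members, mats)
  v <- apply(sal^2, 1L, sum) / ((Tn - 1) * length(mats))  # mean over sessions
  names(v) <- region_ids %||% colnames(mats[[1]])
  v
}

#' Saliency-defined networks
#'
#' For each distinct size M among the reference partition's network sizes
#' (duplicate sizes collapse, e.g. 14 atlas networks yield 12 sizes), the set
#' of the M regions with the largest mean saliency temporal variance.  Sets
#' are nested by construction: every smaller network is a subset of every
#' bigger one.  Ties are broken by region order for reproducibility.
#'
#' @param variance_map named per-region saliency variance (from training-fold
#'   data, to keep the downstream ablation free of circularity).
#' @param sizes integer vector of reference network sizes (e.g.
#'   `partition$sizes`).
#' @return Named list: one region-id vector per unique size, names are the
#'   sizes.
#' @export
build_saliency_networks <- function(variance_map, sizes) {
  stopifnot(length(variance_map) >= 1, !is.null(names(variance_map)))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > length(variance_map))) {
    stop("network sizes must be between 1 and the number of regions")
  }
  ord <- order(-variance_map, seq_along(variance_map))
  ranked <- names(variance_map)[ord]
  out <- lapply(sizes, function(M) ranked[seq_len(M)])
  names(out) <- as.character(sizes)
  out
}

#' Per-fold saliency networks from training data
#'
#' For each cross-validation fold, averages the ensemble saliency temporal
#' variance over all *training* subjects' sessions and derives the
#' saliency-defined networks, so ablating them on validation data is free of
#' double-dipping.
#'
#' @param cv a `cv_run`.
#' @param cohort the preprocessed cohort used for `cv`.
#' @param sizes reference network sizes (see [build_saliency_networks()]).
#' @return List of length k: each element the named list of networks for that
#'   fold, plus attribute `variance_maps`.
#' @export
saliency_networks_cv <- function(cv, cohort, sizes) {
  subj <- cohort$subjects
  folds_of <- cv$fold_spec$subject_folds[subj$subject_id]
  maps <- lapply(cv$folds, function(fr) {
    tr_idx <- which(folds_of != fr$fold)
    mats <- unlist(lapply(cohort$sessions[tr_idx], function(s)
      lapply(s, function(x) x$values)), recursive = FALSE)
    saliency_variance_map(fr$members, mats,
                          region_ids = cohort$sessions[[1]][[1]]$region_ids)
  })
  out <- lapply(maps, build_saliency_networks, sizes = sizes)
  attr(out, "variance_maps") <- maps
  out
}

#' Ablate per-fold saliency networks and compare with random sets
#'
#' Ablates, in each fold's validation data, that fold's own saliency-defined
#' network of size M (from [saliency_networks_cv()]), forms the paired T
#' statistic of the degradation, and compares it against `n_random`
#' size-matched random sets (each ablated identically in all folds).
#'
#' @inheritParams saliency_networks_cv
#' @param size network size M.
#' @param n_random number of size-matched random comparison sets.
#' @param metric metric to compare (default `"r2"`).
#' @param seed seed for the random sets.
#' @return List with `t_saliency`, `deltas_saliency`, `t_random`,
#'   `mean_delta_saliency`, `mean_delta_random` (per random set), and `sets`
#'   (the per-fold saliency networks used).
#' @export
saliency_ablation_study <- function(cv, cohort, size, n_random = 20L,
                                    metric = "r2", seed = 1L) {
  nets <- saliency_networks_cv(cv, cohort, sizes = size)
  cache <- ablation_cache(cv, cohort, metric)
  sets <- lapply(nets, function(x) x[[as.character(size)]])
  ablated <- vapply(seq_along(cache$folds), function(f) {
    idx <- resolve_regions(sets[[f]], cache$region_ids)
    fold_metric_ablated(cache$folds[[f]], idx, metric)
  }, numeric(1))
  baseline <- vapply(cache$folds, function(f) f$baseline, numeric(1))
  deltas <- baseline - ablated
  t_sal <- paired_t(deltas)
  R <- length(cache$region_ids)
  rand_sets <- with_seed(substream_seed(seed, "saliency_random"), {
    lapply(seq_len(n_random), function(i) sample.int(R, size))
  })
  rand_ablated <- ablated_metric_matrix(cache, rand_sets)
  rand_deltas <- matrix(baseline, n_random, length(baseline), byrow = TRUE) -
    rand_ablated
  list(t_saliency = t_sal, deltas_saliency = deltas,
       mean_delta_saliency = mean(deltas),
       t_random = apply(rand_deltas, 1, paired_t),
       mean_delta_random = rowMeans(rand_deltas),
       sets = sets)
}

paired_t <- function(deltas) {
  sd_d <- stats::sd(deltas)
  if (all(deltas == 0)) return(0)
  if (sd_d == 0) return(sign(mean(deltas)) * 1e6)
  mean(deltas) / (sd_d / sqrt(length(deltas)))
}

#' First-order propagation of saliency to functional connectivity
#'
#' Perturbing the standardized data X along the saliency direction D changes
#' the correlation matrix, to first order in the step size, proportionally to
#' `delta_C = (D'X + X'D) / (T - 1)` — the covariance between data and
#' saliency.  This is the direction in which functional connectivity moves
#' when activity changes so as to increase the trait estimate.
#'
#' @param session standardized [region_ts] (or T x R matrix) X.
#' @param sal a `saliency_tensor` or T x R matrix D for the same session.
#' @return An `fc_saliency`: list with `delta_c` (R x R symmetric), `c`
#'   (the session's correlation matrix `X'X / (T - 1)`), `region_ids`.
#' @export
fc_saliency <- function(session, sal) {
  X <- as_session_matrix(session)
  D <- if (inherits(sal, "saliency_tensor")) sal$values else as.matrix(sal)
  if (!all(dim(X) == dim(D))) stop("session and saliency shapes differ")
  M <- nrow(X) - 1
  dC <- (crossprod(D, X) + crossprod(X, D)) / M
  C <- crossprod(X) / M
  ids <- colnames(X)
  dimnames(dC) <- dimnames(C) <- if (is.null(ids)) NULL else list(ids, ids)
  structure(list(delta_c = dC, c = C, region_ids = ids),
            class = "fc_saliency")
}

#' Aggregate and categorize connectivity saliency across a cross-validated run
#'
#' Computes per-session ensemble saliency and its delta-C on every fold's
#' validation sessions, accumulates the mean and SD of delta-C (and the mean
#' correlation) per region pair, and categorizes the strongest effects by the
#' direction of change relative to the sign of the underlying correlation:
#' IMPC/DMPC for increased/decreased magnitude of positive correlations,
#' IMNC/DMNC likewise for negative ones.  Only the top `top_frac` pairs by
#' |mean / SD| receive a category; the rest are `"none"`.
#'
#' @inheritParams saliency_networks_cv
#' @param top_frac fraction of pairs to categorize (default 0.05).
#' @return List with matrices `mean`, `sd`, `mean_c`, `score` (|mean/SD|),
#'   `category` (character matrix), and `pairs`: a data.frame of the
#'   categorized pairs.
#' @export
fc_saliency_aggregate <- function(cv, cohort, top_frac = 0.05) {
  subj <- cohort$subjects
  folds_of <- cv$fold_spec$subject_folds[subj$subject_id]
  region_ids <- cohort$sessions[[1]][[1]]$region_ids
  R <- length(region_ids)
  s1 <- matrix(0, R, R); s2 <- matrix(0, R, R); sc <- matrix(0, R, R)
  n <- 0L
  for (fr in cv$folds) {
    va_idx <- which(folds_of == fr$fold)
    mats <- unlist(lapply(cohort$sessions[va_idx], function(s)
      lapply(s, function(x) x$values)), recursive = FALSE)
    sal <- batch_saliency(fr$members, mats)
    for (j in seq_along(mats)) {
      fcs <- fc_saliency(mats[[j]], t(sal[, j, , drop = TRUE]))
      s1 <- s1 + fcs$delta_c; s2 <- s2 + fcs$delta_c^2; sc <- sc + fcs$c
      n <- n + 1L
    }
  }
  mu <- s1 / n
  sdm <- sqrt(pmax(s2 / n - mu^2, 0) * n / max(n - 1, 1))
  mc <- sc / n
  score <- abs(mu / sdm)
  score[!is.finite(score)] <- 0
  ut <- upper.tri(score)
  thr <- quantile(score[ut], 1 - top_frac, names = FALSE)
  category <- matrix("none", R, R, dimnames = list(region_ids, region_ids))
  selected <- score >= thr & ut
  category[selected & mc > 0 & mu > 0] <- "IMPC"
  category[selected & mc > 0 & mu < 0] <- "DMPC"
  category[selected & mc < 0 & mu > 0] <- "DMNC"
  category[selected & mc < 0 & mu < 0] <- "IMNC"
  idx <- which(selected, arr.ind = TRUE)
  pairs <- data.frame(region_i = region_ids[idx[, 1]],
                      region_j = region_ids[idx[, 2]],
                      mean = mu[idx], sd = sdm[idx],
                      category = category[idx], stringsAsFactors = FALSE)
  list(mean = mu, sd = sdm, mean_c = mc, score = score,
       category = category, pairs = pairs)
}

svd_signed <- function(X) {
  sv <- svd(X)
  # deterministic sign convention: largest-magnitude entry of each V column
  # is positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    col <- sv$v[, j]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  flip[flip == 0] <- 1
  sv$u <- sweep(sv$u, 2L, flip, "*")
  sv$v <- sweep(sv$v, 2L, flip, "*")
  sv
}

#' ZCA whitening of a standardized session
#'
#' Factorizes X = Z W with Z'Z = I via the thin SVD X = U S V':
#' Z = U V' are the whitened "innovations" closest to the original series,
#' and W = V S V' is the symmetric PSD dewhitening matrix (a scaled square
#' root of the correlation matrix: W^2 = X'X = (T - 1) * Corr(X)).
#'
#' @param session standardized [region_ts] or T x R matrix with T > R and
#'   full column rank.
#' @return A `zca_factorization`: list `u`, `d` (singular values), `v`, `z`,
#'   `w`, `region_ids`.
#' @export
zca <- function(session) {
  X <- as_session_matrix(session)
  if (nrow(X) <= ncol(X)) stop("ZCA needs more timepoints than regions")
  sv <- svd_signed(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  if (min(sv$d) < tol) {
    stop(sprintf("X is rank deficient (smallest singular value %.3e)", min(sv$d)))
  }
  structure(list(u = sv$u, d = sv$d, v = sv$v,
                 z = sv$u %*% t(sv$v),
                 w = sv$v %*% (sv$d * t(sv$v)),
                 region_ids = colnames(X)),
            class = "zca_factorization")
}

#' Directional derivative of the ZCA innovations along a saliency
#'
#' Propagates a saliency tensor D through the whitening map Z(X) = U V' by
#' the analytic differential of the thin SVD: with P = U' D V and
#' `F_ij = 1 / (s_j^2 - s_i^2)` off the diagonal,
#' `dU = U (F o (P S + S P')) + (I - U U') D V S^-1` and
#' `dV = V (F o (S P + P' S))`, giving `dZ = dU V' + U dV'`.  When two
#' singular values nearly coincide the analytic formula is ill-conditioned
#' and a central finite difference of Z is used instead, with a warning.
#'
#' @param session standardized [region_ts] or T x R matrix X.
#' @param sal `saliency_tensor` or T x R matrix D.
#' @param gap_tol relative singular-value gap below which the finite
#'   difference fallback kicks in (default 1e-8).
#' @return List with `dz` (T x R), `temporal_variance` (per region,
#'   `sum_t dz^2 / (T - 1)`), and `method` (`"analytic"` or
#'   `"finite_difference"`).
#' @export
zca_saliency <- function(session, sal, gap_tol = 1e-8) {
  X <- as_session_matrix(session)
  D <- if (inherits(sal, "saliency_tensor")) sal$values else as.matrix(sal)
  if (!all(dim(X) == dim(D))) stop("session and saliency shapes differ")
  f <- zca(X)
  s2 <- f$d^2
  gaps <- abs(outer(s2, s2, "-"))
  diag(gaps) <- Inf
  if (min(gaps) < gap_tol * max(s2)) {
    warning("nearly degenerate singular values; falling back to finite differences")
    eta <- 1e-6 * max(abs(X)) / max(max(abs(D)), .Machine$double.eps)
    zp <- zca(X + eta * D)$z
    zm <- zca(X - eta * D)$z
    dz <- (zp - zm) / (2 * eta)
    method <- "finite_difference"
  } else {
    P <- crossprod(f$u, D %*% f$v)
    Fm <- 1 / outer(s2, s2, function(a, b) b - a)
    diag(Fm) <- 0
    S <- diag(f$d, length(f$d))
    dU <- f$u %*% (Fm * (P %*% S + S %*% t(P))) +
      (D %*% f$v - f$u %*% (crossprod(f$u, D %*% f$v))) %*% diag(1 / f$d, length(f$d))
    dV <- f$v %*% (Fm * (S %*% P + t(P) %*% S))
    dz <- dU %*% t(f$v) + f$u %*% t(dV)
    method <- "analytic"
  }
  tv <- colSums(dz^2) / (nrow(X) - 1)
  names(tv) <- colnames(X)
  list(dz = dz, temporal_variance = tv, method = method)
}
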