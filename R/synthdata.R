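#' Region-to-network partition
#'
#' Builds a partition of `n_regions` regions into `n_networks` named networks,
#' standing in for an atlas-based resting-state-network assignment.  Sizes are
#' balanced (differ by at most one) unless explicit `sizes` are given.
#'
#' @param n_regions number of regions.
#' @param n_networks number of networks, between 2 and `n_regions`.
#' @param seed integer seed; only used by `method = "random"`.
#' @param method `"contiguous"` assigns consecutive region blocks;
#'   `"random"` permutes regions across networks.
#' @param sizes optional integer vector of explicit network sizes (must sum to
#'   `n_regions`); names become the network labels.
#' @param region_ids optional region labels (default `"R1"..."Rn"`).
#' @return A `network_partition`: list with `region_ids`, `assignment` (named
#'   character vector mapping region id to network label), `n_networks`, and
#'   `sizes`.
#' @examples
#' p <- make_partition(5, 2)
#' p$sizes
#' @export
make_partition <- function(n_regions, n_networks, seed = 1L,
                           method = c("contiguous", "random"),
                           sizes = NULL, region_ids = NULL) {
  stopifnot_scalar_count(n_regions, "n_regions")
  stopifnot_scalar_count(n_networks, "n_networks")
  method <- match.arg(method)
  if (n_networks < 2) stop("a partition needs at least 2 networks")
  if (n_networks > n_regions) stop("`n_networks` cannot exceed `n_regions`")
  region_ids <- as.character(region_ids %||% paste0("R", seq_len(n_regions)))
  if (length(region_ids) != n_regions || anyDuplicated(region_ids)) {
    stop("`region_ids` must be ", n_regions, " unique labels")
  }
  if (is.null(sizes)) {
    base <- n_regions %/% n_networks
    extra <- n_regions %% n_networks
    sizes <- rep(base, n_networks) + c(rep(1L, extra), rep(0L, n_networks - extra))
    names(sizes) <- sprintf("net%02d", seq_len(n_networks))
  } else {
    if (sum(sizes) != n_regions) stop("`sizes` must sum to `n_regions`")
    if (length(sizes) != n_networks) stop("`sizes` length must equal `n_networks`")
    if (is.null(names(sizes))) names(sizes) <- sprintf("net%02d", seq_along(sizes))
  }
  labels <- rep(names(sizes), times = sizes)
  order_idx <- if (method == "random") {
    with_seed(substream_seed(seed, "partition"), sample.int(n_regions))
  } else {
    seq_len(n_regions)
  }
  assignment <- character(n_regions)
  assignment[order_idx] <- labels
  names(assignment) <- region_ids
  structure(
    list(region_ids = region_ids, assignment = assignment,
         n_networks = length(sizes), sizes = sizes),
    class = "network_partition"
  )
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d regions in %d networks (sizes %s)\n",
              length(x$region_ids), x$n_networks,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Configuration of a synthetic cohort
#'
#' Collects every knob of the generative model: a latent scalar trait g per
#' subject (shared in part within families) modulates the spatial covariance
#' of AR(1)-filtered Gaussian innovations in a `salient_fraction` subset of
#' regions, and a set of confound variables shares `confound_r2` of g's
#' variance.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of parcellated regions (default 360).
#' @param n_timepoints timepoints per session before filtering (default 1200).
#' @param n_sessions sessions per subject (default 4).
#' @param tr sampling interval in seconds (default 0.72).
#' @param family_size_probs probabilities of family sizes 1, 2 and 3+ (names
#'   `"1"`, `"2"`, `"3+"`).
#' @param heritability weight of the family-shared component of g in `[0,1]`.
#' @param n_confounds number of confound variables.
#' @param confound_r2 population R-squared of g regressed on the confounds,
#'   in `[0,1)`; default 0.138.
#' @param effect_scale magnitude of the trait effect on the innovation
#'   covariance: `Sigma(g) = Sigma0 + g * effect_scale * Delta` with
#'   `||Delta||_2 = 1`.
#' @param salient_fraction fraction of regions carrying the planted effect.
#' @param ar_coefficient lag-1 temporal autocorrelation in `[0,1)`.
#' @param seed master integer seed; every random draw in the generator flows
#'   from it through named substreams.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects, n_regions = 360L, n_timepoints = 1200L,
                          n_sessions = 4L, tr = 0.72,
                          family_size_probs = c("1" = 0.28, "2" = 0.38, "3+" = 0.34),
                          heritability = 0.5, n_confounds = 3L,
                          confound_r2 = 0.138, effect_scale = 0.22,
                          salient_fraction = 0.2, ar_coefficient = 0.3,
                          seed = 1L) {
  for (nm in c("n_subjects", "n_regions", "n_timepoints", "n_sessions", "n_confounds")) {
    stopifnot_scalar_count(get(nm), nm)
  }
  if (confound_r2 < 0 || confound_r2 >= 1) stop("`confound_r2` must be in [0, 1)")
  if (effect_scale < 0) stop("`effect_scale` must be nonnegative")
  if (ar_coefficient < 0 || ar_coefficient >= 1) stop("`ar_coefficient` must be in [0, 1)")
  if (heritability < 0 || heritability > 1) stop("`heritability` must be in [0, 1]")
  if (abs(sum(family_size_probs) - 1) > 1e-8 || any(family_size_probs < 0)) {
    stop("`family_size_probs` must be a probability vector")
  }
  if (salient_fraction <= 0 || salient_fraction > 1) {
    stop("`salient_fraction` must be in (0, 1]")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints), n_sessions = as.integer(n_sessions),
         tr = tr, family_size_probs = family_size_probs,
         heritability = heritability, n_confounds = as.integer(n_confounds),
         confound_r2 = confound_r2, effect_scale = effect_scale,
         salient_fraction = salient_fraction, ar_coefficient = ar_coefficient,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Base innovation correlation: convex mix of the identity and a normalized
# rank-q factor structure, so that diag(Sigma0) = 1 and lambda_min >= w.
base_covariance <- function(n_regions, seed, n_factors = 5L, w = 0.55) {
  B <- with_seed(substream_seed(seed, "sigma0"),
                 matrix(rnorm(n_regions * n_factors), n_regions, n_factors))
  A <- tcrossprod(B)
  d <- sqrt(diag(A))
  d[d == 0] <- 1
  C0 <- A / tcrossprod(d)
  w * diag(n_regions) + (1 - w) * C0
}

# Planted effect: symmetric Gaussian matrix supported on the salient block
# (positive diagonal so the trait also modulates innovation variances),
# normalized to unit spectral norm.
planted_delta <- function(n_regions, salient_idx, seed) {
  m <- length(salient_idx)
  Draw <- with_seed(substream_seed(seed, "delta"),
                    matrix(rnorm(m * m), m, m))
  Dsym <- (Draw + t(Draw)) / sqrt(2)
  diag(Dsym) <- abs(diag(Dsym)) + 0.5
  Delta <- matrix(0, n_regions, n_regions)
  Delta[salient_idx, salient_idx] <- Dsym
  Delta / max(abs(eigen(Delta, symmetric = TRUE, only.values = TRUE)$values))
}

#' Generate a synthetic cohort: subjects, families, trait, confounds, truth
#'
#' Draws family sizes, a latent trait g with a family-shared component, and
#' confounds constructed so that the population R-squared of g on the
#' confounds equals `confound_r2` exactly.  Also builds the ground-truth
#' spatial structures (`sigma0`, the planted `delta_matrix`, and the salient
#' region set) that [simulate_timeseries()] consumes.
#'
#' @param config a [cohort_config()].
#' @return A `cohort`: list with `subjects` (data.frame `subject_id`,
#'   `family_id`, `g`), `confounds` (n x k matrix), `truth` (list
#'   `salient_regions`, `delta_matrix`, `confound_coefficients`, `sigma0`,
#'   `region_ids`), and `config`.
#' @examples
#' coh <- make_cohort(cohort_config(n_subjects = 20, n_regions = 10, seed = 7))
#' head(coh$subjects)
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  # family sizes
  sizes <- with_seed(substream_seed(config$seed, "families"), {
    out <- integer(0)
    while (sum(out) < n) {
      cls <- sample(c(1L, 2L, 3L), 1L, prob = config$family_size_probs)
      sz <- if (cls == 3L) 3L + rbinom(1L, 1L, 0.3) else cls
      out <- c(out, sz)
    }
    out
  })
  extra <- sum(sizes) - n
  if (extra > 0) sizes[length(sizes)] <- sizes[length(sizes)] - extra
  sizes <- sizes[sizes > 0]
  family_id <- rep(sprintf("F%04d", seq_along(sizes)), times = sizes)

  h2 <- config$heritability
  g <- with_seed(substream_seed(config$seed, "g"), {
    fam_comp <- rnorm(length(sizes))
    sqrt(h2) * rep(fam_comp, times = sizes) + sqrt(1 - h2) * rnorm(n)
  })

  # confounds c_j = alpha * g + eps_j gives population multiple R^2 equal to
  # confound_r2 when k * alpha^2 = r2 / (1 - r2).
  k <- config$n_confounds
  alpha <- sqrt(config$confound_r2 / (k * (1 - config$confound_r2)))
  confounds <- with_seed(substream_seed(config$seed, "confounds"), {
    matrix(rnorm(n * k), n, k)
  }) + alpha * g
  colnames(confounds) <- paste0("confound_", seq_len(k))

  region_ids <- paste0("R", seq_len(config$n_regions))
  n_sal <- max(1L, round(config$salient_fraction * config$n_regions))
  salient_idx <- with_seed(substream_seed(config$seed, "salient"),
                           sort(sample.int(config$n_regions, n_sal)))
  truth <- list(
    salient_regions = region_ids[salient_idx],
    delta_matrix = planted_delta(config$n_regions, salient_idx, config$seed),
    confound_coefficients = rep(alpha, k),
    sigma0 = base_covariance(config$n_regions, config$seed),
    region_ids = region_ids
  )
  structure(
    list(subjects = data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                               family_id = family_id, g = g,
                               stringsAsFactors = FALSE),
         confounds = confounds, truth = truth, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects in %d families, %d regions (%d salient)\n",
              nrow(x$subjects), length(unique(x$subjects$family_id)),
              x$config$n_regions, length(x$truth$salient_regions)))
  invisible(x)
}

# Trait-modulated innovation covariance, with nearest-PSD projection (eigen
# clipping) when an extreme trait value pushes an eigenvalue below 1e-8.
trait_covariance <- function(g, truth, config, subject_id = "?") {
  S <- truth$sigma0 + g * config$effect_scale * truth$delta_matrix
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warning(sprintf("covariance for subject %s (g = %.2f) projected to nearest PSD",
                    subject_id, g))
    vals <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% (vals * t(ev$vectors))
  }
  S
}

#' Simulate one subject's sessions
#'
#' Each session is a stationary Gaussian series: spatially correlated
#' innovations with covariance `Sigma(g) = Sigma0 + g * effect_scale * Delta`
#' passed through a recursive AR(1) filter.  Sessions are independent given
#' the subject.
#'
#' @param subject one row of `cohort$subjects` (needs `subject_id` and `g`).
#' @param truth the cohort's `truth` element.
#' @param config the [cohort_config()].
#' @return List of `n_sessions` [region_ts] objects.
#' @export
simulate_timeseries <- function(subject, truth, config) {
  g <- subject$g
  S <- trait_covariance(g, truth, config, subject$subject_id)
  L <- t(chol(S))
  phi <- config$ar_coefficient
  Tn <- config$n_timepoints
  R <- config$n_regions
  lapply(seq_len(config$n_sessions), function(s) {
    X <- with_seed(substream_seed(config$seed, "session", subject$subject_id, index = s), {
      E <- matrix(rnorm(Tn * R), Tn, R) %*% t(L)
      X <- E
      if (phi > 0) {
        # stationary start, then recursive filtering
        X[1, ] <- E[1, ] / sqrt(1 - phi^2)
        for (t in 2:Tn) X[t, ] <- phi * X[t - 1, ] + E[t, ]
      }
      X
    })
    region_ts(X, tr = config$tr, region_ids = truth$region_ids)
  })
}

#' Generate a full dataset: cohort plus all sessions
#'
#' Convenience wrapper calling [make_cohort()] then [simulate_timeseries()]
#' for every subject.
#'
#' @inheritParams make_cohort
#' @return A `cohort` with an extra `sessions` element: a list (one per
#'   subject, named by subject id) of lists of [region_ts].
#' @export
generate_dataset <- function(config) {
  coh <- make_cohort(config)
  coh$sessions <- lapply(seq_len(nrow(coh$subjects)), function(i) {
    simulate_timeseries(coh$subjects[i, ], coh$truth, config)
  })
  names(coh$sessions) <- coh$subjects$subject_id
  coh
}

#' Write cohort artifacts as plain text
#'
#' Metadata goes to `metadata.tsv` (subject id, family id, g, confounds and
#' session file names), the partition to `partition.tsv` (region_id,
#' network_label), the ground truth to `truth.json`, and each session to a
#' delimited matrix under `sessions/`.
#'
#' @param cohort a `cohort` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param partition optional [make_partition()] result.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, partition = NULL) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$sessions))
  dir.create(file.path(dir, "sessions"), recursive = TRUE, showWarnings = FALSE)
  n_sessions <- cohort$config$n_sessions
  session_cols <- matrix("", nrow(cohort$subjects), n_sessions)
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    for (s in seq_len(n_sessions)) {
      fn <- file.path("sessions", sprintf("%s_ses%d.tsv", sid, s))
      write_session_tsv(cohort$sessions[[i]][[s]], file.path(dir, fn))
      session_cols[i, s] <- fn
    }
  }
  colnames(session_cols) <- paste0("session_", seq_len(n_sessions))
  meta <- cbind(cohort$subjects, as.data.frame(cohort$confounds),
                as.data.frame(session_cols, stringsAsFactors = FALSE))
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(partition)) {
    utils::write.table(
      data.frame(region_id = names(partition$assignment),
                 network_label = unname(partition$assignment)),
      file.path(dir, "partition.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  truth <- cohort$truth
  truth$delta_matrix <- unclass(truth$delta_matrix)
  truth$sigma0 <- unclass(truth$sigma0)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param path path to a `partition.tsv`-style file.
#' @export
read_partition_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character")
  sizes <- table(factor(tab$network_label, levels = unique(tab$network_label)))
  sizes_int <- as.integer(sizes)
  names(sizes_int) <- names(sizes)
  assignment <- stats::setNames(tab$network_label, tab$region_id)
  structure(
    list(region_ids = tab$region_id, assignment = assignment,
         n_networks = length(sizes_int), sizes = sizes_int),
    class = "network_partition"
  )
}
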