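# Small fixtures shared across test files; everything is generated in code
# under fixed seeds.

tiny_arch <- function(d = 4L, h = 3L) arch_spec(input_dim = d, hidden_dim = h)

# random small parameter set with non-degenerate biases/initial states
tiny_params <- function(d = 4L, h = 3L, seed = 7L) {
  p <- deeptrait:::init_params(tiny_arch(d, h), seed = seed)
  deeptrait:::with_seed(seed + 1L, rapply(p, function(x) x + rnorm(length(x)) * 0.1,
                                          how = "replace"))
}

random_session <- function(Tn = 30L, R = 4L, seed = 5L, tr = 0.72) {
  deeptrait:::with_seed(seed, region_ts(matrix(rnorm(Tn * R), Tn, R), tr = tr))
}

# small preprocessed cohort + trained cv_run, cached per test session
small_trained_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- cohort_config(n_subjects = 80, n_regions = 12, n_timepoints = 240,
                         n_sessions = 2, salient_fraction = 0.25, seed = 42)
    coh <- preprocess_cohort(generate_dataset(cfg))
    folds <- make_folds(coh$subjects, k = 4, seed = 2)
    tc <- training_config(epochs = 20, learning_rate = 3e-3, weight_decay = 0.2,
                          max_crop = 5, batch_size = 16, ensemble_size = 2,
                          init_gain = 2, forget_bias = 1, seed = 9)
    cv <- run_cv(coh, folds, arch_spec(12, 8), tc)
    cache <<- list(cohort = coh, cv = cv, folds = folds)
    cache
  }
})

# numerical gradient of a scalar function of a matrix
fd_grad <- function(f, X, eps = 1e-5) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + eps
    Xm <- X; Xm[i] <- X[i] - eps
    G[i] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  G
}
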