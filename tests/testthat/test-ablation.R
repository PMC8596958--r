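test_that("ablation zero-fills exactly the requested regions", {
  s <- standardize(random_session(Tn = 20, R = 4, seed = 1))
  out <- ablate_regions(s, c("R2", "R4"))
  expect_true(all(out$values[, c(2, 4)] == 0))
  expect_equal(out$values[, c(1, 3)], s$values[, c(1, 3)])
  expect_equal(ablate_regions(s, character(0))$values, s$values)
  all_gone <- ablate_regions(s, s$region_ids)
  expect_true(all(all_gone$values == 0))
  expect_error(ablate_regions(s, "nope"), "unknown region")
})

test_that("a model that provably ignores a region is unaffected by its ablation", {
  p <- tiny_params(d = 4, h = 3)
  p$l1f$W[, 2] <- 0
  p$l1b$W[, 2] <- 0
  s <- standardize(random_session(Tn = 20, R = 4, seed = 2))
  expect_equal(rnn_forward(p, ablate_regions(s, "R2")), rnn_forward(p, s))
})

test_that("empirical p-values use the add-one rule and extremes behave", {
  null <- structure(list(set_size = 3L, n_iter = 10L,
                         t_values = seq(-2, 2.5, length.out = 10), seed = 1L),
                    class = "null_distribution")
  expect_equal(empirical_p(99, null), 1 / 11)
  expect_equal(empirical_p(-99, null), 1)
  expect_equal(empirical_p(0.25, null), (1 + 5) / 11)
  expect_gte(empirical_p(99, null), 1 / (null$n_iter + 1))
})

test_that("FDR adjustment matches the hand-computed BH step-up and BY dominates BH", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  bh <- fdr_adjust(p, "BH")
  expect_true(all(bh <= 0.05))   # all four rejected at q = .05
  expect_equal(bh, c(0.04, 0.04, 0.04, 0.04))
  by <- fdr_adjust(p, "BY")
  expect_true(all(by >= bh))
  set.seed(2)
  p2 <- runif(20)
  expect_true(all(fdr_adjust(p2, "BY") >= fdr_adjust(p2, "BH")))
  expect_error(fdr_adjust(numeric(0)), "empty")
})

test_that("ablation test flags degenerate delta patterns", {
  fix <- small_trained_run()
  cache <- deeptrait:::ablation_cache(fix$cv, fix$cohort, "r2")
  res0 <- ablation_test(fix$cv, fix$cohort, character(0), cache = cache)
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$flag, "zero_delta")
  expect_true(all(res0$deltas == 0))

  res <- ablation_test(fix$cv, fix$cohort, fix$cohort$truth$salient_regions,
                       cache = cache)
  expect_true(is.finite(res$t_stat))
  expect_equal(res$per_fold_baseline - res$per_fold_ablated, res$deltas)
  # paired T cross-check against stats::t.test
  tt <- t.test(res$deltas)$statistic
  expect_equal(res$t_stat, unname(tt), tolerance = 1e-12)
})

test_that("resampling null is reproducible and single-subset edge case collapses", {
  fix <- small_trained_run()
  cache <- deeptrait:::ablation_cache(fix$cv, fix$cohort, "r2")
  n1 <- resample_null(fix$cv, fix$cohort, set_size = 3, n_iter = 8, seed = 5,
                      cache = cache)
  n2 <- resample_null(fix$cv, fix$cohort, set_size = 3, n_iter = 8, seed = 5,
                      cache = cache)
  expect_identical(n1$t_values, n2$t_values)
  expect_length(n1$t_values, 8)
  R <- length(fix$cohort$truth$region_ids)
  nfull <- resample_null(fix$cv, fix$cohort, set_size = R, n_iter = 4, seed = 1,
                         cache = cache)
  expect_equal(length(unique(round(nfull$t_values, 12))), 1)
})

test_that("ablating planted regions degrades more than a matched non-salient set", {
  fix <- small_trained_run()
  coh <- fix$cohort
  cache <- deeptrait:::ablation_cache(fix$cv, coh, "r2")
  sal <- coh$truth$salient_regions
  non_sal <- setdiff(coh$truth$region_ids, sal)[seq_along(sal)]
  d_sal <- mean(ablation_test(fix$cv, coh, sal, cache = cache)$deltas)
  d_non <- mean(ablation_test(fix$cv, coh, non_sal, cache = cache)$deltas)
  expect_gt(d_sal, d_non)
})

test_that("ablation_study assembles a coherent FDR-corrected table", {
  fix <- small_trained_run()
  part <- make_partition(12, 3, region_ids = fix$cohort$truth$region_ids)
  tab <- ablation_study(fix$cv, fix$cohort, partition_sets(part), n_iter = 10,
                        seed = 3)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p >= 1 / 11 & tab$p <= 1))
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_equal(tab$M, unname(vapply(partition_sets(part), length, integer(1))))
})

test_that("ablating a superset of the informative regions degrades at least as much", {
  # toy linear task: the target is the mean activity of region 1
  set.seed(55)
  mats <- lapply(1:60, function(i) matrix(rnorm(25 * 4), 25, 4))
  targets <- vapply(mats, function(m) mean(m[, 1]), numeric(1))
  cfg <- training_config(epochs = 50, learning_rate = 0.01, weight_decay = 1e-4,
                         max_crop = 2, batch_size = 16, ensemble_size = 1,
                         seed = 8)
  m <- train_member(tiny_arch(d = 4, h = 6), mats, targets, cfg)
  test_mats <- lapply(1:40, function(i) matrix(rnorm(25 * 4), 25, 4))
  test_y <- vapply(test_mats, function(x) mean(x[, 1]), numeric(1))
  r2_for <- function(drop) {
    preds <- vapply(test_mats, function(x) {
      x[, drop] <- 0
      rnn_forward(m, x)
    }, numeric(1))
    deeptrait:::metric_value(test_y, preds, "r2")
  }
  base <- r2_for(integer(0))
  d_sub <- base - r2_for(1L)
  d_super <- base - r2_for(c(1L, 2L))
  expect_gt(d_sub, 0.5)                 # region 1 carries the signal
  expect_gte(d_super, d_sub - 0.05)     # superset at least as damaging
})
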