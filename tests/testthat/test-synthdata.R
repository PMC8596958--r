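test_that("partition sizes are balanced or echo explicit sizes", {
  expect_equal(unname(make_partition(4, 2)$sizes), c(2, 2))
  expect_equal(unname(make_partition(5, 2)$sizes), c(3, 2))
  p <- make_partition(360, 14)
  expect_equal(sum(p$sizes), 360)
  expect_lte(diff(range(p$sizes)), 1)
  sizes <- c(a = 10, b = 3, c = 7)
  pe <- make_partition(20, 3, sizes = sizes)
  expect_equal(pe$sizes, sizes)
  expect_equal(unname(table(pe$assignment)[names(sizes)]),
               unname(sizes), ignore_attr = TRUE)
  expect_error(make_partition(3, 5), "exceed")
})

test_that("every region is assigned exactly once, random or contiguous", {
  for (method in c("contiguous", "random")) {
    p <- make_partition(17, 4, method = method, seed = 3)
    expect_setequal(names(p$assignment), p$region_ids)
    expect_equal(sum(p$sizes), 17)
    expect_gte(p$n_networks, 2)
  }
})

test_that("confound construction hits the target shared variance", {
  cfg <- cohort_config(n_subjects = 5000, n_regions = 4, confound_r2 = 0.138,
                       seed = 123)
  coh <- make_cohort(cfg)
  fit <- summary(lm(coh$subjects$g ~ coh$confounds))
  expect_lt(abs(fit$r.squared - 0.138), 0.02)

  cfg0 <- cohort_config(n_subjects = 2000, n_regions = 4, confound_r2 = 0,
                        seed = 5)
  coh0 <- make_cohort(cfg0)
  expect_lt(max(abs(cor(coh0$confounds, coh0$subjects$g))), 0.08)

  expect_error(cohort_config(n_subjects = 10, confound_r2 = 1), "\\[0, 1\\)")
})

test_that("family sizes follow the configured distribution", {
  cfg <- cohort_config(n_subjects = 50, n_regions = 4,
                       family_size_probs = c("1" = 1, "2" = 0, "3+" = 0),
                       seed = 8)
  coh <- make_cohort(cfg)
  expect_true(all(table(coh$subjects$family_id) == 1))
  # trait is standard-normal-ish with family structure
  cfg2 <- cohort_config(n_subjects = 4000, n_regions = 4, seed = 9)
  g <- make_cohort(cfg2)$subjects$g
  expect_lt(abs(mean(g)), 0.08)
  expect_lt(abs(sd(g) - 1), 0.08)
})

test_that("ground truth marks salient regions as the nonzero delta rows", {
  cfg <- cohort_config(n_subjects = 10, n_regions = 20, salient_fraction = 0.2,
                       seed = 4)
  coh <- make_cohort(cfg)
  D <- coh$truth$delta_matrix
  expect_equal(D, t(D))
  row_norm <- rowSums(abs(D))
  nonzero <- coh$truth$region_ids[row_norm > 0]
  expect_setequal(nonzero, coh$truth$salient_regions)
  # recovery AUC is 1 by construction
  lab <- coh$truth$region_ids %in% coh$truth$salient_regions
  expect_true(min(row_norm[lab]) > max(row_norm[!lab]))
})

test_that("long-series empirical correlation converges to the model correlation", {
  cfg <- cohort_config(n_subjects = 2, n_regions = 6, n_timepoints = 20000,
                       n_sessions = 1, effect_scale = 0, ar_coefficient = 0.3,
                       seed = 31)
  coh <- make_cohort(cfg)
  sess <- simulate_timeseries(coh$subjects[1, ], coh$truth, cfg)
  emp <- cor(sess[[1]]$values)
  Sigma <- coh$truth$sigma0
  target <- stats::cov2cor(Sigma)
  expect_lt(max(abs(emp - target)), 0.02)
})

test_that("ar_coefficient zero gives white series; positive gives matching lag-1 r", {
  cfg <- cohort_config(n_subjects = 1, n_regions = 4, n_timepoints = 8000,
                       n_sessions = 1, ar_coefficient = 0, seed = 13)
  coh <- make_cohort(cfg)
  x <- simulate_timeseries(coh$subjects[1, ], coh$truth, cfg)[[1]]$values
  lag1 <- sapply(seq_len(ncol(x)), function(j) cor(x[-1, j], x[-nrow(x), j]))
  expect_lt(max(abs(lag1)), 0.05)

  cfg2 <- cohort_config(n_subjects = 1, n_regions = 4, n_timepoints = 8000,
                        n_sessions = 1, ar_coefficient = 0.5, seed = 13)
  coh2 <- make_cohort(cfg2)
  x2 <- simulate_timeseries(coh2$subjects[1, ], coh2$truth, cfg2)[[1]]$values
  lag1b <- sapply(seq_len(ncol(x2)), function(j) cor(x2[-1, j], x2[-nrow(x2), j]))
  expect_lt(max(abs(lag1b - 0.5)), 0.06)
})

test_that("trait effect moves salient-pair covariance in the planted direction", {
  cfg <- cohort_config(n_subjects = 2, n_regions = 8, n_timepoints = 20000,
                       n_sessions = 1, salient_fraction = 0.5,
                       effect_scale = 0.22, seed = 77)
  coh <- make_cohort(cfg)
  subj_hi <- coh$subjects[1, ]; subj_hi$g <- 2
  subj_lo <- coh$subjects[1, ]; subj_lo$g <- -2; subj_lo$subject_id <- "S_lo"
  x_hi <- simulate_timeseries(subj_hi, coh$truth, cfg)[[1]]$values
  x_lo <- simulate_timeseries(subj_lo, coh$truth, cfg)[[1]]$values
  dcov <- cov(x_hi) - cov(x_lo)
  D <- coh$truth$delta_matrix
  sal <- which(coh$truth$region_ids %in% coh$truth$salient_regions)
  big <- abs(D[sal, sal]) > quantile(abs(D[sal, sal]), 0.5)
  agree <- sign(dcov[sal, sal][big]) == sign(D[sal, sal][big])
  expect_gt(mean(agree), 0.9)
})

test_that("regeneration with the same seed is byte-identical", {
  cfg <- cohort_config(n_subjects = 12, n_regions = 6, n_timepoints = 40,
                       n_sessions = 2, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
})

test_that("cohort artifacts round-trip through plain-text files", {
  cfg <- cohort_config(n_subjects = 4, n_regions = 5, n_timepoints = 20,
                       n_sessions = 2, seed = 3)
  coh <- generate_dataset(cfg)
  part <- make_partition(5, 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, partition = part)
  ts <- read_session_tsv(file.path(dir, "sessions", "S0001_ses1.tsv"))
  expect_equal(ts$values, coh$sessions[[1]][[1]]$values, ignore_attr = TRUE)
  expect_equal(ts$tr, coh$sessions[[1]][[1]]$tr)
  p2 <- read_partition_tsv(file.path(dir, "partition.tsv"))
  expect_equal(p2$assignment, part$assignment)
  expect_equal(p2$sizes, part$sizes)
})
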