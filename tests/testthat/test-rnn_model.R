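test_that("parameter accounting reproduces the architecture's printed counts", {
  pc <- count_parameters(arch_spec(360, 256))
  expect_identical(pc$per_direction_lstm_layer1, 632320)
  expect_identical(pc$per_direction_lstm_layer2, 525824)
  expect_identical(pc$affine, 257)
  expect_identical(pc$total, 2316545)
  expect_identical(pc$total, 2 * pc$per_direction_lstm_layer1 +
                     2 * pc$per_direction_lstm_layer2 + pc$affine)
})

test_that("parameter formula matches tiny hand-computed cases and the real leaves", {
  pc <- count_parameters(arch_spec(1, 1))
  expect_identical(pc$per_direction_lstm_layer1, 14)
  expect_identical(pc$total, 58)
  expect_identical(count_parameters(arch_spec(2, 3))$per_direction_lstm_layer1,
                   4 * 3 * 5 + 18)
  # counting actual allocated leaves agrees with the formula
  p <- tiny_params(d = 2, h = 3)
  n_l1 <- length(p$l1f$W) + length(p$l1f$U) + length(p$l1f$b) +
    length(p$l1f$h0) + length(p$l1f$c0)
  expect_equal(n_l1, count_parameters(arch_spec(2, 3))$per_direction_lstm_layer1)
  expect_equal(length(unlist(p)), count_parameters(arch_spec(2, 3))$total)
})

test_that("degenerate parameter settings give forced outputs", {
  p <- tiny_params()
  pz <- rapply(p, function(x) x * 0, how = "replace")
  X <- random_session(Tn = 12, R = 4)
  expect_equal(rnn_forward(pz, X), 0)
  pb <- pz; pb$head$b <- 3.25
  expect_equal(rnn_forward(pb, X), 3.25)
  ph <- p; ph$head$w[] <- 0; ph$head$b <- -1
  expect_equal(rnn_forward(ph, random_session(seed = 50)), -1)
})

test_that("forward gradient matches central finite differences", {
  p <- tiny_params()
  X <- random_session(Tn = 10, R = 4, seed = 33)$values
  bw <- deeptrait:::cpp_bilstm_backward(p, deeptrait:::sessions_to_cube(list(X)), 1)
  G <- t(bw$dX[, 1, ])
  fd <- fd_grad(function(M) rnn_forward(p, M), X)
  expect_lt(max(abs(G - fd)) / max(abs(fd)), 1e-4)
})

test_that("training is deterministic and fits a planted linear signal", {
  set.seed(17)
  n_subj <- 60
  mats <- lapply(seq_len(n_subj), function(i) matrix(rnorm(25 * 5), 25, 5))
  targets <- vapply(mats, function(m) mean(m[, 1]), numeric(1))
  spec <- tiny_arch(d = 5, h = 6)
  cfg <- training_config(epochs = 50, learning_rate = 0.01, weight_decay = 1e-4,
                         max_crop = 2, batch_size = 16, ensemble_size = 1,
                         seed = 4)
  m1 <- train_member(spec, mats, targets, cfg)
  m2 <- train_member(spec, mats, targets, cfg)
  expect_identical(unclass(m1)[names(m1)], unclass(m2)[names(m2)])

  preds <- vapply(mats, function(x) rnn_forward(m1, x), numeric(1))
  expect_gt(evaluate(targets, preds)$r2, 0.9)

  # loss trend is non-increasing (5-epoch moving average)
  lh <- attr(m1, "loss_history")
  ma <- stats::filter(lh, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(min(diff(ma)), 0)  # it actually moves
  expect_true(all(diff(ma) < 0.05 * max(lh)))
})

test_that("weight decay shrinks predictions on a constant-zero target", {
  set.seed(3)
  mats <- lapply(1:20, function(i) matrix(rnorm(15 * 3), 15, 3))
  cfg <- training_config(epochs = 30, learning_rate = 5e-3, weight_decay = 0.5,
                         max_crop = 0, batch_size = 10, ensemble_size = 1,
                         seed = 12)
  m <- train_member(tiny_arch(3, 3), mats, rep(0, 20), cfg)
  preds <- vapply(mats, function(x) rnn_forward(m, x), numeric(1))
  expect_lt(mean(abs(preds)), 0.1)
})

test_that("ensemble prediction is the flat mean over members and sessions", {
  p <- tiny_params()
  s1 <- random_session(seed = 1); s2 <- random_session(seed = 2)
  expect_equal(ensemble_predict(list(p), list(s1)), rnn_forward(p, s1))
  # members predicting constants {1, 3} average to 2
  pz <- rapply(p, function(x) x * 0, how = "replace")
  pa <- pz; pa$head$b <- 1
  pb <- pz; pb$head$b <- 3
  expect_equal(ensemble_predict(list(pa, pb), list(s1, s2)), 2)
})

test_that("ensemble squared error never exceeds mean member squared error", {
  members <- lapply(1:4, function(i) tiny_params(seed = i))
  sess <- lapply(1:6, function(i) random_session(seed = i + 10))
  y <- rnorm(1, 0.3)
  per_member <- vapply(members, function(p) mean(rnn_forward(p, sess)), numeric(1))
  ens <- ensemble_predict(members, sess)
  expect_lte((ens - y)^2, mean((per_member - y)^2) + 1e-12)
})

test_that("dimension mismatches are caught", {
  p <- tiny_params(d = 4)
  expect_error(rnn_forward(p, random_session(R = 5)), "regions")
  cfg <- training_config(epochs = 1, ensemble_size = 1, max_crop = 20)
  mats <- lapply(1:4, function(i) matrix(rnorm(30 * 4), 30, 4))
  expect_error(train_member(tiny_arch(4, 3), mats, rnorm(4), cfg),
               "max_crop")
})

test_that("model checkpoints round-trip through JSON with predictions intact", {
  p <- tiny_params(d = 4, h = 3, seed = 2)
  attr(p, "seed") <- 11L
  attr(p, "loss_history") <- c(1, 0.4, 0.2)
  class(p) <- c("rnn_params", "list")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(p, path)
  q <- read_model_json(path)
  expect_equal(unlist(p), unlist(q), tolerance = 1e-12)
  expect_identical(attr(q, "seed"), 11L)
  s <- random_session(Tn = 12, R = 4, seed = 3)
  expect_equal(rnn_forward(q, s), rnn_forward(p, s), tolerance = 1e-12)
})
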