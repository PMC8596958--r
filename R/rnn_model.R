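#' Architecture of the bidirectional recurrent regressor
#'
#' Two bidirectional LSTM layers whose forward- and backward-direction outputs
#' are combined by addition at each timestep, followed by temporal mean
#' pooling and an affine head producing one scalar.  Initial hidden and cell
#' states of every direction are learnable.
#'
#' @param input_dim number of input regions (default 360).
#' @param hidden_dim LSTM state size (default 256).
#' @return An `arch_spec` list.
#' @export
arch_spec <- function(input_dim = 360L, hidden_dim = 256L) {
  stopifnot_scalar_count(input_dim, "input_dim")
  stopifnot_scalar_count(hidden_dim, "hidden_dim")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_bilstm_layers = 2L, direction_combine = "additive",
                 pooling = "temporal_mean", head = "affine_scalar"),
            class = "arch_spec")
}

#' Exact learnable-parameter accounting
#'
#' One direction-LSTM with input size d and state size h holds
#' `4h(d + h)` weights, `4h` gate biases, and `2h` learnable initial
#' hidden/cell states; the affine head holds `h + 1`.  For the default
#' architecture (360 inputs, 256 hidden) this gives 632,320 per direction in
#' layer 1, 525,824 in layer 2, 257 in the head, and 2,316,545 in total.
#'
#' @param spec an [arch_spec()].
#' @return A list with `per_direction_lstm_layer1`, `per_direction_lstm_layer2`,
#'   `affine`, and `total` (`= 2 * layer1 + 2 * layer2 + affine`).
#' @examples
#' count_parameters(arch_spec())$total  # 2316545
#' @export
count_parameters <- function(spec = arch_spec()) {
  stopifnot(inherits(spec, "arch_spec"))
  d <- spec$input_dim; h <- spec$hidden_dim
  per_dir <- function(d, h) 4 * h * (d + h) + 6 * h
  l1 <- per_dir(d, h)
  l2 <- per_dir(h, h)
  affine <- h + 1
  list(per_direction_lstm_layer1 = l1, per_direction_lstm_layer2 = l2,
       affine = affine, total = 2 * l1 + 2 * l2 + affine)
}

#' Training configuration
#'
#' @param epochs passes over the training sessions (default 50).
#' @param learning_rate ADAM step size (default 0.0005).
#' @param weight_decay decoupled weight-decay constant applied to weight
#'   matrices (default 0.0005).
#' @param max_crop maximum number of timesteps randomly removed at each end
#'   of every batch (default 20).
#' @param batch_size sessions per update (default 32).
#' @param ensemble_size number of independently trained members (default 50).
#' @param decay_biases if `TRUE`, decay also applies to biases and initial
#'   states (default `FALSE`).
#' @param init_gain multiplier on the Glorot-uniform weight initialization
#'   (default 1).
#' @param forget_bias constant added to the forget-gate bias at
#'   initialization (default 0).
#' @param seed integer seed controlling initialization, shuffling and crops.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 50L, learning_rate = 5e-4,
                            weight_decay = 5e-4, max_crop = 20L,
                            batch_size = 32L, ensemble_size = 50L,
                            decay_biases = FALSE, init_gain = 1,
                            forget_bias = 0, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0,
            max_crop >= 0, batch_size >= 1, ensemble_size >= 1, init_gain > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, max_crop = as.integer(max_crop),
                 batch_size = as.integer(batch_size),
                 ensemble_size = as.integer(ensemble_size),
                 decay_biases = decay_biases, init_gain = init_gain,
                 forget_bias = forget_bias, seed = as.integer(seed)),
            class = "training_config")
}

# Glorot-uniform weights (scaled by `gain`), zero biases and initial states
# except an optional constant forget-gate bias.
init_direction <- function(d, h, gain = 1, forget_bias = 0) {
  glorot <- function(nr, nc) {
    lim <- gain * sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- forget_bias
  list(W = glorot(4 * h, d), U = glorot(4 * h, h),
       b = b, h0 = numeric(h), c0 = numeric(h))
}

init_params <- function(spec, seed = 1L, gain = 1, forget_bias = 0) {
  d <- spec$input_dim; h <- spec$hidden_dim
  with_seed(seed, {
    p <- list(l1f = init_direction(d, h, gain, forget_bias),
              l1b = init_direction(d, h, gain, forget_bias),
              l2f = init_direction(h, h, gain, forget_bias),
              l2b = init_direction(h, h, gain, forget_bias))
    lim <- sqrt(6 / (h + 1))
    p$head <- list(w = runif(h, -lim, lim), b = 0)
    p
  })
}

# Stack a list of standardized T x R session matrices into the (R, B, T)
# batch cube the C++ core expects, optionally restricted to timestep rows
# t0..t1.
sessions_to_cube <- function(mats, t0 = 1L, t1 = nrow(mats[[1]])) {
  Tn <- t1 - t0 + 1L
  d <- ncol(mats[[1]])
  B <- length(mats)
  X <- array(0, c(d, B, Tn))
  for (b in seq_len(B)) X[, b, ] <- t(mats[[b]][t0:t1, , drop = FALSE])
  X
}

as_session_matrix <- function(session) {
  if (inherits(session, "region_ts")) session$values else as.matrix(session)
}

#' Forward pass: scalar prediction for sessions
#'
#' @param params trained parameters (see [train_member()]).
#' @param sessions one standardized session ([region_ts] or T x R matrix) or a
#'   list of equally long sessions.
#' @return Numeric vector of one scalar per session: the affine readout of the
#'   temporal mean of the second BiLSTM layer's summed direction outputs.
#' @export
rnn_forward <- function(params, sessions) {
  if (!is.list(sessions) || inherits(sessions, "region_ts")) sessions <- list(sessions)
  mats <- lapply(sessions, as_session_matrix)
  if (ncol(mats[[1]]) != ncol(params$l1f$W)) {
    stop(sprintf("session has %d regions but the model expects %d",
                 ncol(mats[[1]]), ncol(params$l1f$W)))
  }
  as.numeric(cpp_bilstm_forward(params, sessions_to_cube(mats)))
}

zeros_like <- function(params) rapply(params, function(x) x * 0, how = "replace")

# Which leaves receive decoupled weight decay: weight matrices (W, U, head w)
# unless decay_biases is set.
decay_mask <- function(params, decay_biases) {
  mask_dir <- function() list(W = TRUE, U = TRUE, b = decay_biases,
                              h0 = decay_biases, c0 = decay_biases)
  list(l1f = mask_dir(), l1b = mask_dir(), l2f = mask_dir(), l2b = mask_dir(),
       head = list(w = TRUE, b = decay_biases))
}

#' Train one ensemble member
#'
#' Minimizes the mean squared error of per-session scalar predictions against
#' each session's subject-level adjusted trait, using ADAM with decoupled
#' weight decay and backpropagation through time.  Every batch independently
#' crops up to `max_crop` timesteps at the start and at the end of its
#' sequences (uniform integers), and sessions are reshuffled every epoch.
#' Fully deterministic given `config$seed`.
#'
#' @param spec an [arch_spec()] (its `input_dim` must match the sessions).
#' @param sessions list of standardized, equally long session matrices or
#'   [region_ts] objects; each session is an independent training sample.
#' @param targets numeric vector, one adjusted-trait value per session.
#' @param config a [training_config()].
#' @return A parameter list (classes `rnn_params`) with attributes
#'   `loss_history` (mean batch MSE per epoch) and `seed`.
#' @export
train_member <- function(spec, sessions, targets, config) {
  stopifnot(inherits(spec, "arch_spec"), inherits(config, "training_config"))
  mats <- lapply(sessions, as_session_matrix)
  if (length(mats) < 2) stop("need at least 2 training sessions")
  if (length(targets) != length(mats)) stop("one target per session required")
  Tn <- nrow(mats[[1]])
  if (2 * config$max_crop >= Tn) stop("2 * max_crop must be smaller than the sequence length")
  if (ncol(mats[[1]]) != spec$input_dim) {
    stop(sprintf("sessions have %d regions but `input_dim` is %d",
                 ncol(mats[[1]]), spec$input_dim))
  }

  params <- init_params(spec, substream_seed(config$seed, "init"),
                        gain = config$init_gain %||% 1,
                        forget_bias = config$forget_bias %||% 0)
  m <- zeros_like(params); v <- zeros_like(params)
  mask <- decay_mask(params, config$decay_biases)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay
  step <- 0L
  n <- length(mats)
  loss_history <- numeric(config$epochs)

  with_seed(substream_seed(config$seed, "trainloop"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (idx in batches) {
        crop0 <- sample.int(config$max_crop + 1L, 1L) - 1L
        crop1 <- sample.int(config$max_crop + 1L, 1L) - 1L
        X <- sessions_to_cube(mats[idx], t0 = 1L + crop0, t1 = Tn - crop1)
        bw <- cpp_bilstm_mse_grad(params, X, targets[idx])
        if (!is.finite(bw$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (seed %d)",
                       epoch, config$seed))
        }
        ep_loss <- ep_loss + bw$loss * length(idx)
        step <- step + 1L
        new <- adamw_update(params, bw$grads, m, v, step, lr, wd, b1, b2, eps, mask)
        params <- new$params; m <- new$m; v <- new$v
      }
      loss_history[epoch] <- ep_loss / n
    }
  })
  attr(params, "loss_history") <- loss_history
  attr(params, "seed") <- config$seed
  class(params) <- c("rnn_params", "list")
  params
}

adamw_update <- function(params, grads, m, v, step, lr, wd, b1, b2, eps, mask) {
  bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
  walk <- function(p, g, mm, vv, msk) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], mm[[i]], vv[[i]], msk[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      mm <- b1 * mm + (1 - b1) * g
      vv <- b2 * vv + (1 - b2) * g^2
      stepv <- lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
      if (isTRUE(msk)) stepv <- stepv + lr * wd * p
      list(p = p - stepv, m = mm, v = vv)
    }
  }
  r <- walk(params, grads, m, v, mask)
  list(params = r$p, m = r$m, v = r$v)
}

#' Train a full ensemble
#'
#' Trains `config$ensemble_size` members with member-specific seeds derived
#' from `config$seed`.
#'
#' @inheritParams train_member
#' @return List of `rnn_params`, in training order.
#' @export
train_ensemble <- function(spec, sessions, targets, config) {
  lapply(seq_len(config$ensemble_size), function(i) {
    cfg_i <- config
    cfg_i$seed <- substream_seed(config$seed, "member", index = i)
    train_member(spec, sessions, targets, cfg_i)
  })
}

#' Ensemble prediction for one subject
#'
#' The subject-level prediction is the flat mean over all members and all of
#' the subject's sessions of the per-session scalar outputs.
#'
#' @param members list of trained `rnn_params`.
#' @param sessions list of the subject's standardized sessions.
#' @return A single scalar.
#' @export
ensemble_predict <- function(members, sessions) {
  stopifnot(length(members) >= 1, length(sessions) >= 1)
  preds <- vapply(members, function(p) mean(rnn_forward(p, sessions)), numeric(1))
  mean(preds)
}

#' Save / load model parameters as JSON
#'
#' Checkpoints one trained member as a named-array JSON container embedding
#' the architecture dimensions and the training seed, so a model can be
#' re-loaded for prediction or saliency analysis without retraining.
#'
#' @param params trained `rnn_params` (see [train_member()]).
#' @param path file path.
#' @return `read_model_json` returns the `rnn_params`; `write_model_json`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(params, path) {
  h <- length(params$head$w)
  d <- ncol(params$l1f$W)
  payload <- list(
    arch = list(input_dim = d, hidden_dim = h),
    seed = attr(params, "seed"),
    loss_history = attr(params, "loss_history"),
    params = rapply(params, unclass, how = "replace")
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- payload$arch$input_dim; h <- payload$arch$hidden_dim
  as_num_matrix <- function(m, nr, nc) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    stopifnot(nrow(m) == nr, ncol(m) == nc)
    m
  }
  fix_dir <- function(p, din) {
    list(W = as_num_matrix(p$W, 4 * h, din),
         U = as_num_matrix(p$U, 4 * h, h),
         b = as.numeric(p$b), h0 = as.numeric(p$h0), c0 = as.numeric(p$c0))
  }
  params <- list(l1f = fix_dir(payload$params$l1f, d),
                 l1b = fix_dir(payload$params$l1b, d),
                 l2f = fix_dir(payload$params$l2f, h),
                 l2b = fix_dir(payload$params$l2b, h),
                 head = list(w = as.numeric(payload$params$head$w),
                             b = as.numeric(payload$params$head$b)))
  attr(params, "seed") <- payload$seed
  attr(params, "loss_history") <- payload$loss_history
  class(params) <- c("rnn_params", "list")
  params
}

# Batched per-member predictions for many subjects sharing session length:
# returns a matrix (n_members x n_sessions_total); used by the CV engine and
# the ablation machinery to avoid per-session overhead.
member_session_outputs <- function(members, mats) {
  X <- sessions_to_cube(mats)
  t(vapply(members, function(p) as.numeric(cpp_bilstm_forward(p, X)),
           numeric(length(mats))))
}
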