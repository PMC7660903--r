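# A small feed-forward network trained with Adam.
#
# Architecture: n_hidden fully connected ReLU layers of hidden_width units
# with inverted dropout between layers, and a softmax output over the
# classes. The loss is categorical cross-entropy with optional per-class
# weights (applied to training batches only, as in Keras). Training stops
# when the epoch-average training loss has not improved for
# `patience_epochs` consecutive epochs (or at `max_epochs`); the parameters
# returned are those of the epoch with the lowest validation loss.
#
# Written in base R matrix operations: no package in the declared dependency
# set offers a multi-hidden-layer perceptron with dropout and class-weighted
# loss, and the training loop (the early-stopping/selection rule in
# particular) is specific enough to own.

#' Network configuration
#'
#' @param n_features Input dimension.
#' @param n_classes Output dimension (>= 2).
#' @param hidden_width Units per hidden layer (default 200).
#' @param n_hidden Number of hidden layers (default 2).
#' @param dropout_p Dropout probability between layers (default 0.2).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience_epochs Epochs without training-loss improvement before
#'   stopping (default 10).
#' @param max_epochs Hard cap on epochs (default 200).
#' @param batch_size Minibatch size (default 256).
#' @param rng_seed Seed for initialization, shuffling and dropout.
#' @return Object of class `mlp_config`.
#' @export
mlp_config <- function(n_features, n_classes, hidden_width = 200,
                       n_hidden = 2, dropout_p = 0.2, learning_rate = 1e-3,
                       patience_epochs = 10, max_epochs = 200,
                       batch_size = 256, rng_seed = 1) {
  stopifnot(dropout_p >= 0, dropout_p < 1, hidden_width >= 1, n_classes >= 2,
            n_hidden >= 1, max_epochs >= 1, patience_epochs >= 1)
  structure(list(n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 hidden_width = as.integer(hidden_width),
                 n_hidden = as.integer(n_hidden), dropout_p = dropout_p,
                 learning_rate = learning_rate,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "mlp_config")
}

mlp_init_params <- function(config) {
  dims <- c(config$n_features,
            rep(config$hidden_width, config$n_hidden), config$n_classes)
  L <- length(dims) - 1
  W <- lapply(seq_len(L), function(l) {
    matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
           dims[l], dims[l + 1])
  })
  b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
  list(W = W, b = b)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

relu <- function(Z) { Z[Z < 0] <- 0; Z }

mlp_forward <- function(params, X, dropout_p = 0, training = FALSE) {
  L <- length(params$W)
  A <- X
  As <- vector("list", L - 1); Zs <- vector("list", L - 1)
  masks <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    Z <- sweep(A %*% params$W[[l]], 2, params$b[[l]], "+")
    A <- relu(Z)
    if (training && dropout_p > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout_p, nrow(A)) /
        (1 - dropout_p)
      A <- A * mask
      masks[[l]] <- mask
    }
    Zs[[l]] <- Z; As[[l]] <- A
  }
  Zo <- sweep(A %*% params$W[[L]], 2, params$b[[L]], "+")
  list(P = softmax_rows(Zo), As = As, Zs = Zs, masks = masks)
}

# mean over samples of w_i * cross-entropy_i
weighted_ce <- function(P, y_idx, w) {
  p <- P[cbind(seq_along(y_idx), y_idx)]
  mean(w * -log(pmax(p, 1e-12)))
}

mlp_gradients <- function(params, X, fwd, y_idx, w) {
  L <- length(params$W)
  n <- nrow(X)
  Y <- matrix(0, n, ncol(fwd$P))
  Y[cbind(seq_len(n), y_idx)] <- 1
  dZ <- (fwd$P - Y) * (w / n)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- if (l == 1) X else fwd$As[[l - 1]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- tcrossprod(dZ, params$W[[l]])
      if (!is.null(fwd$masks[[l - 1]])) dA <- dA * fwd$masks[[l - 1]]
      dZ <- dA * (fwd$Zs[[l - 1]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_state_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train one network
#'
#' @param x_train,x_val Numeric feature matrices (already standardized by the
#'   caller; see [train_fold()]).
#' @param y_train,y_val Integer class indices in `1..n_classes`.
#' @param config An [mlp_config()].
#' @param class_weights Optional positive per-class weights (length
#'   `n_classes`); applied to training loss only.
#' @return List with `params` (weights of the best-validation epoch),
#'   `training_log` (tibble `epoch`, `train_loss`, `val_loss`),
#'   `best_epoch`, `stopped_epoch`, `config`.
#' @export
mlp_train <- function(x_train, y_train, x_val, y_val, config,
                      class_weights = NULL) {
  stopifnot(ncol(x_train) == config$n_features,
            max(y_train) <= config$n_classes)
  if (is.null(class_weights)) class_weights <- rep(1, config$n_classes)
  stopifnot(all(class_weights > 0))
  set.seed(config$rng_seed)
  params <- mlp_init_params(config)
  state <- adam_state_init(params)
  n <- nrow(x_train)
  w_train <- class_weights[y_train]
  w_unit <- rep(1, length(y_val))

  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  best_train <- Inf; best_val <- Inf
  best_params <- params; best_epoch <- 0L
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    loss_sum <- 0
    for (s in starts) {
      batch <- idx[s:min(s + config$batch_size - 1, n)]
      Xb <- x_train[batch, , drop = FALSE]
      fwd <- mlp_forward(params, Xb, config$dropout_p, training = TRUE)
      loss_sum <- loss_sum +
        weighted_ce(fwd$P, y_train[batch], w_train[batch]) * length(batch)
      grads <- mlp_gradients(params, Xb, fwd, y_train[batch], w_train[batch])
      upd <- adam_update(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    # epoch training loss = average of the minibatch losses seen during the
    # forward passes (dropout active), the usual framework-reported quantity
    train_loss <- loss_sum / n
    val_loss <- weighted_ce(mlp_forward(params, x_val)$P, y_val, w_unit)
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop("non-finite loss at epoch ", epoch, " (train = ", train_loss,
           ", val = ", val_loss, ")")
    }
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, train_loss)
    log_val <- c(log_val, val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
    }
    if (train_loss < best_train - 1e-9) {
      best_train <- train_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience_epochs) break
    }
  }
  list(params = best_params,
       training_log = tibble::tibble(epoch = log_epoch,
                                     train_loss = log_train,
                                     val_loss = log_val),
       best_epoch = best_epoch, stopped_epoch = epoch, config = config)
}

#' Softmax predictions of a trained network
#'
#' @param model Result of [mlp_train()].
#' @param x Feature matrix on the same scale the model was trained on.
#' @return Matrix of class probabilities, rows summing to 1.
#' @export
mlp_predict <- function(model, x) {
  mlp_forward(model$params, x)$P
}
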