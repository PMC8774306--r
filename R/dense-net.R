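# Dense feed-forward binary classifier with explicit forward/backward
# passes. The default stack mirrors the diagnostic device's network:
# 64-relu, 64-sigmoid, dropout 0.4, 128-tanh, dropout 0.5, 2-softmax.

#' Specify a dense network architecture
#'
#' @param input_dim Length of the flattened spectrum feature vector
#'   (default 352 = 4 excitations x 88 emission channels).
#' @param hidden_units Integer vector of hidden layer widths.
#' @param hidden_activations Activation per hidden layer; one of `"relu"`,
#'   `"sigmoid"`, `"tanh"`.
#' @param dropout_rates Dropout rate applied after each hidden layer
#'   (0 disables); rates must lie in `[0, 1)`.
#' @param n_classes Number of softmax outputs (2: normal, cancer).
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_dim = 352,
                         hidden_units = c(64, 64, 128),
                         hidden_activations = c("relu", "sigmoid", "tanh"),
                         dropout_rates = c(0, 0.4, 0.5),
                         n_classes = 2) {
  stopifnot(
    input_dim > 0, n_classes >= 2,
    length(hidden_units) == length(hidden_activations),
    length(hidden_units) == length(dropout_rates),
    all(hidden_units > 0),
    all(hidden_activations %in% c("relu", "sigmoid", "tanh")),
    all(dropout_rates >= 0), all(dropout_rates < 1)
  )
  structure(
    list(input_dim = as.integer(input_dim),
         hidden_units = as.integer(hidden_units),
         hidden_activations = hidden_activations,
         dropout_rates = dropout_rates,
         n_classes = as.integer(n_classes)),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> input", x$input_dim, "\n")
  for (i in seq_along(x$hidden_units)) {
    cat(sprintf("  dense(%d, %s)", x$hidden_units[i], x$hidden_activations[i]))
    if (x$dropout_rates[i] > 0) cat(sprintf(" + dropout(%g)", x$dropout_rates[i]))
    cat("\n")
  }
  cat(sprintf("  dense(%d, softmax)\n", x$n_classes))
  invisible(x)
}

layer_dims <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_units, spec$n_classes)
  list(fan_in = dims[-length(dims)], fan_out = dims[-1])
}

#' Number of trainable parameters in a network
#'
#' @param spec A [network_spec()].
#' @return Integer: sum over dense layers of `in * out + out`.
#' @export
n_parameters <- function(spec) {
  d <- layer_dims(spec)
  sum(d$fan_in * d$fan_out + d$fan_out)
}

#' Initialise network parameters
#'
#' Glorot-uniform weights (`U(-l, l)`, `l = sqrt(6 / (fan_in + fan_out))`)
#' and zero biases.
#'
#' @param spec A [network_spec()].
#' @param seed Optional integer seed; `NULL` draws from the current stream.
#' @return A `dense_net_params` object: the spec plus one `(W, b)` pair per
#'   dense layer.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  d <- layer_dims(spec)
  layers <- purrr::map(seq_along(d$fan_in), function(i) {
    fi <- d$fan_in[i]; fo <- d$fan_out[i]
    lim <- sqrt(6 / (fi + fo))
    list(W = matrix(stats::runif(fi * fo, -lim, lim), nrow = fi),
         b = rep(0, fo))
  })
  structure(list(spec = spec, layers = layers), class = "dense_net_params")
}

activate <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z))
}

activate_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through the network
#'
#' In `"train"` mode each dropout layer zeroes activations with its
#' configured probability and rescales survivors by `1 / (1 - rate)`
#' (inverted dropout); in `"eval"` mode dropout is the identity and the
#' pass is deterministic.
#'
#' @param params A `dense_net_params` object from [build_network()].
#' @param x Numeric matrix, one row per sample, `input_dim` columns.
#' @param mode `"eval"` or `"train"`.
#' @param masks Optional list of pre-drawn dropout masks (train mode), as
#'   returned in `$masks`; used to replay a pass exactly.
#' @param keep_cache Return intermediate activations for [nn_backward()].
#' @return If `keep_cache` is `FALSE`, the class-probability matrix
#'   (rows sum to 1). Otherwise a list with `probs`, `cache` and `masks`.
#' @export
nn_forward <- function(params, x, mode = c("eval", "train"),
                       masks = NULL, keep_cache = FALSE) {
  stopifnot(inherits(params, "dense_net_params"))
  mode <- match.arg(mode)
  x <- as.matrix(x)
  spec <- params$spec
  if (ncol(x) != spec$input_dim) {
    abort(sprintf("Input has %d columns; network expects %d.",
                  ncol(x), spec$input_dim),
          class = "fluordx_shape_error")
  }
  n_hidden <- length(spec$hidden_units)
  a <- x
  cache <- vector("list", n_hidden + 1)
  masks_out <- vector("list", n_hidden)
  for (i in seq_len(n_hidden)) {
    ly <- params$layers[[i]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    h <- activate(z, spec$hidden_activations[i])
    m <- NULL
    if (spec$dropout_rates[i] > 0 && mode == "train") {
      r <- spec$dropout_rates[i]
      m <- masks[[i]] %||%
        (matrix(stats::runif(length(h)) >= r, nrow = nrow(h)) / (1 - r))
      h_dropped <- h * m
    } else {
      h_dropped <- h
    }
    cache[[i]] <- list(a_in = a, z = z, a = h, mask = m)
    masks_out[[i]] <- m
    a <- h_dropped
  }
  ly <- params$layers[[n_hidden + 1]]
  z_out <- sweep(a %*% ly$W, 2, ly$b, "+")
  probs <- softmax_rows(z_out)
  cache[[n_hidden + 1]] <- list(a_in = a, z = z_out, a = probs, mask = NULL)
  if (!keep_cache) return(probs)
  list(probs = probs, cache = cache, masks = masks_out)
}

#' Mean categorical cross-entropy
#'
#' `-mean over samples of sum(y * log(clip(p, 1e-7, 1 - 1e-7)))`.
#'
#' @param probs Probability matrix, rows summing to 1.
#' @param onehot One-hot label matrix of the same shape.
#' @return Scalar loss.
#' @export
categorical_cross_entropy <- function(probs, onehot) {
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  -mean(rowSums(onehot * log(p)))
}

nn_accuracy <- function(probs, onehot) {
  mean(max.col(probs, ties.method = "first") ==
         max.col(onehot, ties.method = "first"))
}

#' Backward pass: gradients of the batch cross-entropy loss
#'
#' Uses the softmax + cross-entropy identity: the gradient at the output
#' pre-activation is `(p - y) / batch_size`. Dropout masks recorded by the
#' paired forward pass gate the hidden-layer gradients.
#'
#' @param params A `dense_net_params` object.
#' @param cache The `cache` element returned by
#'   `nn_forward(..., mode = "train", keep_cache = TRUE)`.
#' @param onehot One-hot label matrix for the batch.
#' @return A list with one `(W, b)` gradient pair per dense layer.
#' @export
nn_backward <- function(params, cache, onehot) {
  spec <- params$spec
  n_hidden <- length(spec$hidden_units)
  n <- nrow(onehot)
  grads <- vector("list", n_hidden + 1)

  out <- cache[[n_hidden + 1]]
  dz <- (out$a - onehot) / n
  grads[[n_hidden + 1]] <- list(W = crossprod(out$a_in, dz), b = colSums(dz))
  grad_a <- tcrossprod(dz, params$layers[[n_hidden + 1]]$W)

  for (i in rev(seq_len(n_hidden))) {
    cc <- cache[[i]]
    if (!is.null(cc$mask)) grad_a <- grad_a * cc$mask
    dz <- grad_a * activate_grad(cc$z, cc$a, spec$hidden_activations[i])
    grads[[i]] <- list(W = crossprod(cc$a_in, dz), b = colSums(dz))
    if (i > 1) grad_a <- tcrossprod(dz, params$layers[[i]]$W)
  }
  grads
}

#' Training hyperparameters
#'
#' Two profiles are provided. `"published"` is the published regimen:
#' learning rate 1e-6 with inverse-time decay constant 1e-6 per update,
#' momentum 0.9 with Nesterov acceleration, batch size 32, up to 15,000
#' epochs with early-stopping patience 5000. `"fast"` keeps the optimiser
#' but rescales the schedule (learning rate 1e-3, 300 epochs, patience 50)
#' so a full cross-validation finishes in minutes.
#'
#' @param profile `"published"` or `"fast"`.
#' @param learning_rate,lr_decay,momentum,nesterov,max_epochs,batch_size,patience
#'   Override any single setting of the chosen profile.
#' @param checkpoint Monitor-set quantity that selects the checkpointed
#'   model: `"loss"` (default) or `"accuracy"`.
#' @param seed Optional seed applied at the start of training.
#' @return A `train_config` object.
#' @export
train_config <- function(profile = c("published", "fast"),
                         learning_rate = NULL, lr_decay = NULL,
                         momentum = NULL, nesterov = NULL,
                         max_epochs = NULL, batch_size = NULL,
                         patience = NULL,
                         checkpoint = c("loss", "accuracy"),
                         seed = NULL) {
  profile <- match.arg(profile)
  checkpoint <- match.arg(checkpoint)
  defaults <- switch(profile,
    published = list(learning_rate = 1e-6, lr_decay = 1e-6, momentum = 0.9,
                 nesterov = TRUE, max_epochs = 15000L, batch_size = 32L,
                 patience = 5000L),
    fast = list(learning_rate = 1e-3, lr_decay = 1e-6, momentum = 0.9,
                nesterov = TRUE, max_epochs = 300L, batch_size = 32L,
                patience = 50L)
  )
  cfg <- list(
    profile = profile,
    learning_rate = learning_rate %||% defaults$learning_rate,
    lr_decay = lr_decay %||% defaults$lr_decay,
    momentum = momentum %||% defaults$momentum,
    nesterov = nesterov %||% defaults$nesterov,
    max_epochs = as.integer(max_epochs %||% defaults$max_epochs),
    batch_size = as.integer(batch_size %||% defaults$batch_size),
    patience = as.integer(patience %||% defaults$patience),
    checkpoint = checkpoint,
    seed = seed
  )
  stopifnot(cfg$learning_rate > 0, cfg$lr_decay >= 0,
            cfg$momentum >= 0, cfg$momentum < 1,
            cfg$max_epochs >= 1, cfg$batch_size >= 1, cfg$patience >= 0)
  structure(cfg, class = "train_config")
}

new_sgd_state <- function(params) {
  list(velocity = purrr::map(params$layers, function(ly) {
    list(W = ly$W * 0, b = ly$b * 0)
  }), t = 0L)
}

#' One SGD update with momentum, Nesterov acceleration and decay
#'
#' The effective learning rate follows the inverse-time schedule
#' `lr_t = lr0 / (1 + decay * t)` with `t` the number of updates already
#' taken. Velocity update: `v <- mu * v - lr_t * g`; the parameter step is
#' `mu * v - lr_t * g` under Nesterov, `v` otherwise.
#'
#' @param params,grads Parameters and matching gradients.
#' @param state Optimiser state from a previous call (or `NULL` to start).
#' @param config A [train_config()].
#' @return List with updated `params` and `state`.
#' @export
nn_sgd_step <- function(params, grads, state = NULL, config = train_config()) {
  state <- state %||% new_sgd_state(params)
  lr <- config$learning_rate / (1 + config$lr_decay * state$t)
  mu <- config$momentum
  for (i in seq_along(params$layers)) {
    vW <- mu * state$velocity[[i]]$W - lr * grads[[i]]$W
    vb <- mu * state$velocity[[i]]$b - lr * grads[[i]]$b
    if (config$nesterov) {
      params$layers[[i]]$W <- params$layers[[i]]$W + mu * vW - lr * grads[[i]]$W
      params$layers[[i]]$b <- params$layers[[i]]$b + mu * vb - lr * grads[[i]]$b
    } else {
      params$layers[[i]]$W <- params$layers[[i]]$W + vW
      params$layers[[i]]$b <- params$layers[[i]]$b + vb
    }
    state$velocity[[i]]$W <- vW
    state$velocity[[i]]$b <- vb
  }
  state$t <- state$t + 1L
  list(params = params, state = state)
}

labels_to_onehot <- function(labels) {
  lv <- match(labels, c("normal", "cancer"))
  if (anyNA(lv)) {
    abort("Labels must be 'normal' or 'cancer'.",
          class = "fluordx_value_error")
  }
  y <- matrix(0, nrow = length(lv), ncol = 2)
  y[cbind(seq_along(lv), lv)] <- 1
  y
}

#' Train the dense network with early stopping and checkpointing
#'
#' Shuffles the training spectra each epoch, performs mini-batch SGD, and
#' after every epoch evaluates loss and accuracy on both sets in eval mode.
#' The parameters achieving the best monitor loss (or accuracy, see
#' [train_config()]) are checkpointed; training stops once `patience`
#' epochs pass without strict improvement, or at `max_epochs`.
#'
#' @param train A spectra tibble used for gradient updates.
#' @param monitor A spectra tibble monitored for early stopping (the
#'   protocol's "test" set); never used for gradients.
#' @param spec A [network_spec()]; `NULL` derives `input_dim` from the data.
#' @param config A [train_config()].
#' @return A `dense_net_fit`: checkpointed `params`, `history` tibble
#'   (epoch, train/monitor loss and accuracy), `best_epoch`,
#'   `stopped_epoch`, plus the spec and config.
#' @export
fit_dense_net <- function(train, monitor, spec = NULL,
                          config = train_config("fast")) {
  tr <- feature_matrix(train)
  mo <- feature_matrix(monitor)
  if (nrow(tr$x) == 0 || nrow(mo$x) == 0) {
    abort("Training and monitor sets must be non-empty.",
          class = "fluordx_value_error")
  }
  fit_dense_net_xy(tr$x, labels_to_onehot(tr$meta$label),
                   mo$x, labels_to_onehot(mo$meta$label),
                   spec = spec, config = config)
}

# Matrix-level training loop (also used directly in tests on toy data).
fit_dense_net_xy <- function(x_train, y_train, x_monitor, y_monitor,
                             spec = NULL, config = train_config("fast")) {
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- spec %||% network_spec(input_dim = ncol(x_train))
  stopifnot(inherits(spec, "network_spec"),
            ncol(x_train) == spec$input_dim,
            ncol(x_monitor) == spec$input_dim)
  n <- nrow(x_train)
  params <- build_network(spec)
  state <- new_sgd_state(params)

  best_metric <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  ep_tl <- ep_ta <- ep_ml <- ep_ma <- numeric(config$max_epochs)
  stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + config$batch_size - 1, n)]
      fw <- nn_forward(params, x_train[rows, , drop = FALSE],
                       mode = "train", keep_cache = TRUE)
      grads <- nn_backward(params, fw$cache, y_train[rows, , drop = FALSE])
      upd <- nn_sgd_step(params, grads, state, config)
      params <- upd$params
      state <- upd$state
    }
    p_tr <- nn_forward(params, x_train, mode = "eval")
    p_mo <- nn_forward(params, x_monitor, mode = "eval")
    ep_tl[epoch] <- categorical_cross_entropy(p_tr, y_train)
    ep_ta[epoch] <- nn_accuracy(p_tr, y_train)
    ep_ml[epoch] <- categorical_cross_entropy(p_mo, y_monitor)
    ep_ma[epoch] <- nn_accuracy(p_mo, y_monitor)
    if (!is.finite(ep_tl[epoch]) || !is.finite(ep_ml[epoch])) {
      abort(sprintf(
        "Training aborted: non-finite loss at epoch %d (train %g, monitor %g).",
        epoch, ep_tl[epoch], ep_ml[epoch]),
        class = "fluordx_training_error")
    }
    metric <- if (config$checkpoint == "loss") ep_ml[epoch] else -ep_ma[epoch]
    if (metric < best_metric) {
      best_metric <- metric
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) {
        stopped <- epoch
        break
      }
    }
  }
  keep <- seq_len(stopped)
  history <- tibble(
    epoch = keep,
    train_loss = ep_tl[keep], train_accuracy = ep_ta[keep],
    monitor_loss = ep_ml[keep], monitor_accuracy = ep_ma[keep]
  )
  structure(
    list(params = best_params, final_params = params, history = history,
         best_epoch = best_epoch, stopped_epoch = stopped,
         spec = spec, config = config),
    class = "dense_net_fit"
  )
}

#' @export
print.dense_net_fit <- function(x, ...) {
  cat("<dense_net_fit>\n")
  cat("  parameters:", n_parameters(x$spec), "\n")
  cat("  best epoch:", x$best_epoch, "of", x$stopped_epoch, "run\n")
  cat(sprintf("  best monitor loss: %.6f\n",
              x$history$monitor_loss[x$best_epoch]))
  invisible(x)
}

#' Per-spectrum cancer probability
#'
#' The softmax output of the second ("cancer") neuron, evaluated
#' deterministically (no dropout).
#'
#' @param params A `dense_net_params` or `dense_net_fit`.
#' @param x Feature matrix, one flattened spectrum per row.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_cancer_probability <- function(params, x) {
  if (inherits(params, "dense_net_fit")) params <- params$params
  nn_forward(params, x, mode = "eval")[, 2]
}

#' Predict cancer probabilities for a spectra table
#'
#' @param object A `dense_net_fit`.
#' @param newdata A spectra tibble.
#' @param threshold Decision threshold for the hard label (inclusive:
#'   probability equal to the threshold is called cancer).
#' @param ... Unused.
#' @return A tibble with one row per spectrum: `case_id`, `replicate`,
#'   `label`, `p_cancer`, `pred_label`.
#' @export
predict.dense_net_fit <- function(object, newdata, threshold = 0.5, ...) {
  fm <- feature_matrix(newdata)
  p <- predict_cancer_probability(object$params, fm$x)
  mutate(fm$meta, p_cancer = p,
         pred_label = classify_spectrum(p, threshold))
}
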