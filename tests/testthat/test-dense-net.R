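test_that("network construction gives the published shapes and counts", {
  spec <- network_spec()
  params <- build_network(spec, seed = 1)
  dims <- vapply(params$layers, function(l) dim(l$W), integer(2))
  expect_equal(dims, matrix(c(352, 64, 64, 64, 64, 128, 128, 2), nrow = 2))
  expect_equal(n_parameters(spec), 35330)
  expect_identical(build_network(spec, seed = 5), build_network(spec, seed = 5))
  # Glorot bound respected, biases zero
  lim1 <- sqrt(6 / (352 + 64))
  expect_true(all(abs(params$layers[[1]]$W) <= lim1))
  expect_true(all(vapply(params$layers, function(l) all(l$b == 0), logical(1))))
})

test_that("forward pass produces normalised, deterministic probabilities", {
  spec <- tiny_net_spec()
  params <- build_network(spec, seed = 2)
  set.seed(3)
  x <- matrix(rnorm(7 * 24), nrow = 7)
  p <- nn_forward(params, x, mode = "eval")
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_identical(p, nn_forward(params, x, mode = "eval"))

  zero <- params
  for (i in seq_along(zero$layers)) {
    zero$layers[[i]]$W[] <- 0
    zero$layers[[i]]$b[] <- 0
  }
  expect_equal(nn_forward(zero, x, mode = "eval"),
               matrix(0.5, nrow = 7, ncol = 2))
  expect_equal(predict_cancer_probability(zero, x), rep(0.5, 7))

  expect_error(nn_forward(params, x[, 1:5]), class = "fluordx_shape_error")
})

test_that("cross-entropy matches hand arithmetic", {
  expect_equal(categorical_cross_entropy(matrix(c(0.5, 0.5), 1),
                                         matrix(c(1, 0), 1)),
               log(2), tolerance = 1e-12)
  expect_equal(categorical_cross_entropy(matrix(c(0, 1), 1),
                                         matrix(c(0, 1), 1)),
               -log(1 - 1e-7), tolerance = 1e-12)
  probs <- rbind(c(0.5, 0.5), c(0, 1))
  y <- rbind(c(1, 0), c(0, 1))
  expect_equal(categorical_cross_entropy(probs, y),
               (log(2) - log(1 - 1e-7)) / 2, tolerance = 1e-9)
  expect_equal(round(categorical_cross_entropy(probs, y), 6), 0.346574)
})

test_that("backward pass matches central finite differences on every layer", {
  spec <- tiny_net_spec()
  set.seed(11)
  x <- matrix(rnorm(5 * 24), nrow = 5)
  y <- fluordx:::labels_to_onehot(sample(c("normal", "cancer"), 5,
                                         replace = TRUE))
  params <- build_network(spec, seed = 12)

  # without dropout (eval path)
  fw <- nn_forward(params, x, mode = "eval", keep_cache = TRUE)
  grads <- nn_backward(params, fw$cache, y)
  num <- numeric_gradients(params, x, y, masks = NULL)
  expect_lt(max_rel_err(grads, num), 1e-5)

  # with dropout masks replayed through the finite differences
  set.seed(13)
  fw2 <- nn_forward(params, x, mode = "train", keep_cache = TRUE)
  grads2 <- nn_backward(params, fw2$cache, y)
  num2 <- numeric_gradients(params, x, y, masks = fw2$masks)
  expect_lt(max_rel_err(grads2, num2), 1e-5)
})

test_that("output-layer gradients obey the softmax cross-entropy identity", {
  spec <- tiny_net_spec()
  params <- build_network(spec, seed = 4)
  set.seed(5)
  x <- matrix(rnorm(6 * 24), nrow = 6)
  y <- fluordx:::labels_to_onehot(rep(c("normal", "cancer"), 3))
  fw <- nn_forward(params, x, mode = "eval", keep_cache = TRUE)
  grads <- nn_backward(params, fw$cache, y)
  # d(loss)/d(output bias) = column sums of (p - y)/n
  expect_equal(grads[[4]]$b, colSums(fw$probs - y) / 6, tolerance = 1e-12)
})

test_that("units silenced by dropout receive zero gradient", {
  spec <- tiny_net_spec()
  params <- build_network(spec, seed = 6)
  set.seed(7)
  x <- matrix(rnorm(5 * 24), nrow = 5)
  y <- fluordx:::labels_to_onehot(rep("cancer", 5))
  masks <- list(
    NULL,
    matrix(1 / (1 - 0.4), nrow = 5, ncol = 8),
    matrix(1 / (1 - 0.5), nrow = 5, ncol = 12)
  )
  masks[[2]][, 3] <- 0  # silence unit 3 of the second hidden layer
  fw <- nn_forward(params, x, mode = "train", masks = masks,
                   keep_cache = TRUE)
  grads <- nn_backward(params, fw$cache, y)
  expect_equal(grads[[2]]$W[, 3], rep(0, 8))
  expect_equal(grads[[2]]$b[3], 0)
  # downstream weights fed by the silenced unit also see zero gradient
  expect_equal(grads[[3]]$W[3, ], rep(0, 12))
})

test_that("SGD updates follow momentum, Nesterov and inverse-time decay", {
  fake_params <- function(theta) {
    structure(list(spec = NULL,
                   layers = list(list(W = matrix(theta), b = 0))),
              class = "dense_net_params")
  }
  grad_of <- function(theta) list(list(W = matrix(theta), b = 0))

  # plain gradient step when momentum and decay vanish
  cfg <- train_config("fast", learning_rate = 0.1, lr_decay = 0,
                      momentum = 0, nesterov = FALSE)
  st <- nn_sgd_step(fake_params(2), grad_of(2), NULL, cfg)
  expect_equal(st$params$layers[[1]]$W[1], 2 - 0.1 * 2)

  # inverse-time decay: per-step decrement is lr0 / (1 + decay * t)
  cfg_d <- train_config("fast", learning_rate = 0.1, lr_decay = 0.5,
                        momentum = 0, nesterov = FALSE)
  p <- fake_params(0); s <- NULL
  decs <- numeric(3)
  for (t in 0:2) {
    before <- p$layers[[1]]$W[1]
    up <- nn_sgd_step(p, grad_of(1), s, cfg_d)
    p <- up$params; s <- up$state
    decs[t + 1] <- before - p$layers[[1]]$W[1]
  }
  expect_equal(decs, 0.1 / (1 + 0.5 * 0:2), tolerance = 1e-12)

  # published constants: after 1e6 updates the rate is halved
  s_far <- nn_sgd_step(fake_params(1), grad_of(1), NULL,
                       train_config("published", momentum = 0,
                                    nesterov = FALSE))$state
  s_far$t <- 1000000L
  up <- nn_sgd_step(fake_params(1), grad_of(1), s_far,
                    train_config("published", momentum = 0, nesterov = FALSE))
  expect_equal(1 - up$params$layers[[1]]$W[1], 5e-7, tolerance = 1e-9)

  # two Nesterov steps on the quadratic loss theta^2 / 2 match a
  # hand-unrolled scalar oracle
  cfg_n <- train_config("fast", learning_rate = 0.1, lr_decay = 0.01,
                        momentum = 0.9, nesterov = TRUE)
  theta0 <- 1.5
  # oracle, unrolled by hand: g = theta; lr_t = lr0 / (1 + decay * t)
  lr0 <- 0.1; mu <- 0.9; dec <- 0.01
  g0 <- theta0
  v1 <- mu * 0 - lr0 * g0
  theta1 <- theta0 + mu * v1 - lr0 * g0
  lr1 <- lr0 / (1 + dec * 1)
  g1 <- theta1
  v2 <- mu * v1 - lr1 * g1
  theta2 <- theta1 + mu * v2 - lr1 * g1

  p <- fake_params(theta0); s <- NULL
  for (i in 1:2) {
    up <- nn_sgd_step(p, grad_of(p$layers[[1]]$W[1]), s, cfg_n)
    p <- up$params; s <- up$state
  }
  expect_equal(p$layers[[1]]$W[1], theta2, tolerance = 1e-14)
})

test_that("early stopping waits out the patience and keeps the best weights", {
  d <- generate_cohort(tiny_strong_config(seed = 31))
  parts <- split_cases(d, 12, 4, 4, seed = 32)
  tr <- d[d$case_id %in% parts$case_id[parts$part == "train"], ]
  mo <- d[d$case_id %in% parts$case_id[parts$part == "test"], ]

  # a vanishing learning rate leaves the monitor loss bit-identical, so no
  # epoch after the first strictly improves: stop at 1 + patience
  frozen <- train_config("fast", learning_rate = 1e-30, max_epochs = 50,
                         patience = 4, seed = 33)
  fit <- fit_dense_net(tr, mo, spec = tiny_net_spec(), config = frozen)
  expect_equal(fit$best_epoch, 1)
  expect_equal(fit$stopped_epoch, 5)

  # checkpoint property on a real run: the returned parameters achieve the
  # minimum monitor loss recorded in history
  fit2 <- fit_dense_net(tr, mo, spec = tiny_net_spec(),
                        config = tiny_train_config(seed = 34))
  expect_lte(fit2$stopped_epoch, 30)
  expect_equal(fit2$history$monitor_loss[fit2$best_epoch],
               min(fit2$history$monitor_loss))
  fm <- fluordx:::feature_matrix(mo)
  re_loss <- categorical_cross_entropy(
    nn_forward(fit2$params, fm$x, mode = "eval"),
    fluordx:::labels_to_onehot(fm$meta$label))
  expect_equal(re_loss, min(fit2$history$monitor_loss), tolerance = 1e-12)

  expect_error(fit_dense_net(tr[0, ], mo, config = tiny_train_config()),
               class = "fluordx_value_error")
})

test_that("training is reproducible under fixed seeds", {
  d <- generate_cohort(tiny_strong_config(n_cancer = 5, n_normal = 5,
                                          seed = 41))
  parts <- split_cases(d, 6, 2, 2, seed = 42)
  tr <- d[d$case_id %in% parts$case_id[parts$part == "train"], ]
  mo <- d[d$case_id %in% parts$case_id[parts$part == "test"], ]
  cfg <- tiny_train_config(max_epochs = 10, seed = 43)
  f1 <- fit_dense_net(tr, mo, spec = tiny_net_spec(), config = cfg)
  f2 <- fit_dense_net(tr, mo, spec = tiny_net_spec(), config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("full-batch descent decreases the loss at a small learning rate", {
  blobs <- toy_blobs(n_per_class = 30, seed = 51)
  spec <- network_spec(input_dim = 4, hidden_units = c(8, 8, 12),
                       hidden_activations = c("relu", "sigmoid", "tanh"),
                       dropout_rates = c(0, 0, 0))
  cfg <- train_config("fast", learning_rate = 1e-4, momentum = 0,
                      nesterov = FALSE, batch_size = nrow(blobs$x),
                      max_epochs = 10, patience = 10, seed = 52)
  fit <- fluordx:::fit_dense_net_xy(blobs$x, blobs$y, blobs$x, blobs$y,
                                    spec = spec, config = cfg)
  expect_true(all(diff(fit$history$train_loss) <= 1e-12))
})

test_that("the network learns a separable toy problem", {
  blobs <- toy_blobs(n_per_class = 100, seed = 61)
  spec <- network_spec(input_dim = 4, hidden_units = c(8, 8, 12),
                       hidden_activations = c("relu", "sigmoid", "tanh"),
                       dropout_rates = c(0, 0.4, 0.5))
  cfg <- train_config("fast", learning_rate = 1e-3, max_epochs = 200,
                      patience = 200, seed = 62)
  fit <- fluordx:::fit_dense_net_xy(blobs$x, blobs$y, blobs$x, blobs$y,
                                    spec = spec, config = cfg)
  expect_lte(nrow(fit$history), 200)
  expect_gt(fit$history$train_accuracy[fit$stopped_epoch], 0.95)
  p <- predict_cancer_probability(fit$params, blobs$x)
  expect_true(all(p >= 0 & p <= 1))
  gap <- mean(p[blobs$labels == "cancer"]) - mean(p[blobs$labels == "normal"])
  expect_gt(gap, 0.5)
})
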