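# Small fixtures built in code: a reduced cohort geometry (2 excitations,
# 12 channels -> 24 features) and a narrow network so unit tests stay fast.

tiny_cohort_config <- function(n_cancer = 4, n_normal = 4, replicates = 3,
                               seed = NULL, ...) {
  cohort_config(
    n_cancer_cases = n_cancer, n_normal_cases = n_normal,
    replicates_per_case = replicates,
    excitations = c(365, 450), n_channels = 12,
    seed = seed, ...
  )
}

tiny_strong_config <- function(n_cancer = 10, n_normal = 10, replicates = 3,
                               seed = NULL) {
  fl <- default_fluorophores()
  fl$cancer_multiplier <- 0.3
  tiny_cohort_config(n_cancer, n_normal, replicates, seed = seed,
                     fluorophores = fl, noise_sd = 0.05)
}

tiny_net_spec <- function(input_dim = 24) {
  network_spec(input_dim = input_dim,
               hidden_units = c(8, 8, 12),
               hidden_activations = c("relu", "sigmoid", "tanh"),
               dropout_rates = c(0, 0.4, 0.5))
}

tiny_train_config <- function(max_epochs = 30, patience = 10, ...) {
  train_config("fast", max_epochs = max_epochs, patience = patience, ...)
}

# Central finite-difference gradients of the batch loss, replaying the
# given dropout masks; independent oracle for nn_backward().
numeric_gradients <- function(params, x, y, masks = NULL, eps = 1e-5) {
  loss_at <- function(p) {
    probs <- if (is.null(masks)) {
      fluordx::nn_forward(p, x, mode = "eval")
    } else {
      fluordx::nn_forward(p, x, mode = "train", masks = masks)
    }
    fluordx::categorical_cross_entropy(probs, y)
  }
  lapply(seq_along(params$layers), function(l) {
    gW <- params$layers[[l]]$W * 0
    for (i in seq_along(gW)) {
      up <- params; up$layers[[l]]$W[i] <- up$layers[[l]]$W[i] + eps
      dn <- params; dn$layers[[l]]$W[i] <- dn$layers[[l]]$W[i] - eps
      gW[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    gb <- params$layers[[l]]$b * 0
    for (i in seq_along(gb)) {
      up <- params; up$layers[[l]]$b[i] <- up$layers[[l]]$b[i] + eps
      dn <- params; dn$layers[[l]]$b[i] <- dn$layers[[l]]$b[i] - eps
      gb[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    list(W = gW, b = gb)
  })
}

max_rel_err <- function(analytic, numeric) {
  errs <- unlist(lapply(seq_along(analytic), function(l) {
    c(abs(analytic[[l]]$W - numeric[[l]]$W) /
        pmax(abs(analytic[[l]]$W) + abs(numeric[[l]]$W), 1e-4),
      abs(analytic[[l]]$b - numeric[[l]]$b) /
        pmax(abs(analytic[[l]]$b) + abs(numeric[[l]]$b), 1e-4))
  }))
  max(errs)
}

# Exhaustive Mann-Whitney pair-counting AUC (ties count one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == "cancer"]
  neg <- scores[labels == "normal"]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# Textbook order statistics, coded independently of summarize_runs().
stats_oracle <- function(v) {
  n <- length(v)
  s <- sort(v)
  m <- sum(v) / n
  qlin <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  list(
    n = n, min = s[1], max = s[n], mean = m,
    median = qlin(0.5),
    sd = sqrt(sum((v - m)^2) / (n - 1)),
    p25 = qlin(0.25), p75 = qlin(0.75)
  )
}

# Two-Gaussian linearly separable toy classes in a low dimension.
toy_blobs <- function(n_per_class = 100, dim = 4, sep = 1.5, sd = 0.3,
                      seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * dim, mean = -sep, sd = sd), ncol = dim),
    matrix(rnorm(n_per_class * dim, mean = sep, sd = sd), ncol = dim)
  )
  labels <- rep(c("normal", "cancer"), each = n_per_class)
  y <- matrix(0, nrow = 2 * n_per_class, ncol = 2)
  y[cbind(seq_len(2 * n_per_class), ifelse(labels == "cancer", 2, 1))] <- 1
  list(x = x, y = y, labels = labels)
}
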