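#' DCGAN training configuration
#'
#' Hyperparameters of the per-class adversarial augmenter: 5000 training
#' epochs at batch size 32, Adam with learning rate 0.001 and momentum
#' (beta1) 0.5, a 100-dimensional uniform \[-1, 1\] noise input, 64 filters of
#' length 5 in the first convolutional layer and a 1024-unit fully connected
#' layer in both generator and discriminator. Because the data here are
#' 12-dimensional feature vectors rather than images, the convolutions are
#' the 1-D analog of the usual image-domain layout (kernel length 5, 64
#' filters).
#'
#' @param epochs training epochs (default 5000).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param adam_momentum Adam beta1 (default 0.5).
#' @param noise_dim latent dimension, components uniform on \[-1, 1\].
#' @param filters first convolutional layer width (default 64).
#' @param kernel convolution kernel length (default 5).
#' @param fc_units fully connected layer width (default 1024).
#' @param lr_decay linearly decay the (variable) learning rate to ~0 over
#'   training (default `TRUE`).
#' @param seed RNG seed for reproducible training.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(epochs = 5000, batch_size = 32, learning_rate = 0.001,
                       adam_momentum = 0.5, noise_dim = 100, filters = 64,
                       kernel = 5, fc_units = 1024, lr_decay = TRUE, seed = 1) {
  vals <- c(epochs, batch_size, learning_rate, adam_momentum, noise_dim,
            filters, kernel, fc_units)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_config("all gan_config values must be positive")
  }
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, adam_momentum = adam_momentum,
      noise_dim = as.integer(noise_dim), filters = as.integer(filters),
      kernel = as.integer(kernel), fc_units = as.integer(fc_units),
      lr_decay = isTRUE(lr_decay), seed = as.integer(seed)
    ),
    class = "gan_config"
  )
}

#' Min-max feature scaler to \[-1, 1\]
#'
#' Fitted on real training vectors only; maps each feature linearly from its
#' observed \[min, max\] to \[-1, 1\] (the generator's bounded tanh output
#' range). Constant features map to 0 and de-scale back to the constant.
#'
#' @param features numeric data frame / matrix of feature vectors.
#' @return An object of class `feature_scaler`.
#' @export
feature_scaler <- function(features) {
  X <- as.matrix(as_tibble(features)[feature_cols_of(features)])
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  structure(list(min = lo, max = hi, features = colnames(X)),
            class = "feature_scaler")
}

feature_cols_of <- function(x) {
  x <- as_tibble(x)
  nm <- names(x)[vapply(x, is.numeric, logical(1))]
  setdiff(nm, "phase_id")
}

scale_features <- function(scaler, features) {
  X <- as.matrix(as_tibble(features)[scaler$features])
  rng <- scaler$max - scaler$min
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(X, 2, scaler$min), 2, rng, "/") * 2 - 1
  out[, const] <- 0 # constant features sit at the range centre
  out
}

unscale_features <- function(scaler, X) {
  rng <- scaler$max - scaler$min
  out <- sweep(sweep((X + 1) / 2, 2, rng, "*"), 2, scaler$min, "+")
  colnames(out) <- scaler$features
  out
}

# hard contracts of the classifier features: percentages, counts, bin index
integer_features <- c("saccade_number", "fixation_number", "aps_modal_bin")
feature_hard_bounds <- function(name) {
  if (name %in% c("fixdis_below_75", "sacamp_above_2.5", "aps_trial",
                  "aps_sac", "aps_fix", "aps_cf55")) {
    c(0, 100)
  } else if (name == "aps_modal_bin") {
    c(1, 20)
  } else if (name %in% c("phase_duration_s", "saccade_duration_s",
                         "saccade_number", "fixation_number",
                         "mean_sacamp_deg")) {
    c(0, Inf)
  } else {
    c(-Inf, Inf) # unknown features carry no hard contract
  }
}

gan_init_params <- function(cfg, n_feat) {
  f <- cfg$filters; u <- cfg$fc_units; k <- cfg$kernel; z <- cfg$noise_dim
  # kernels stored as k x filters matrices; the slab forwards expand them
  list(
    g = list(
      W0 = gaussian_init(z, u), b0 = rep(0, u),
      W1 = gaussian_init(u, n_feat * f), b1 = rep(0, n_feat * f),
      K = gaussian_init(k, f), bK = 0
    ),
    d = list(
      K = gaussian_init(k, f), bK = rep(0, f),
      W1 = gaussian_init(n_feat * f, u), b1 = rep(0, u),
      W2 = gaussian_init(u, 1), b2 = 0
    )
  )
}

gen_forward <- function(g, z, n_feat, f) {
  pre0 <- sweep(z %*% g$W0, 2, g$b0, "+")
  h0 <- relu(pre0)
  pre1 <- sweep(h0 %*% g$W1, 2, g$b1, "+")
  h1 <- relu(pre1)
  h1a <- array(h1, c(nrow(z), n_feat, f))
  o <- conv1d_forward(h1a, array(g$K, c(nrow(g$K), f, 1)), g$bK)
  x <- tanh(o[, , 1])
  if (is.null(dim(x))) x <- matrix(x, nrow = nrow(z))
  list(z = z, pre0 = pre0, h0 = h0, pre1 = pre1, h1a = h1a, o = o, x = x)
}

gen_backward <- function(g, cache, dx, n_feat, f) {
  B <- nrow(dx)
  do <- array(dx * (1 - tanh(cache$o[, , 1])^2), c(B, n_feat, 1))
  cb <- conv1d_backward(cache$h1a, array(g$K, c(nrow(g$K), f, 1)), do)
  dh1 <- matrix(cb$dx, B, n_feat * f) * d_relu(matrix(cache$pre1, B, n_feat * f))
  dW1 <- crossprod(cache$h0, dh1)
  db1 <- colSums(dh1)
  dh0 <- (dh1 %*% t(g$W1)) * d_relu(cache$pre0)
  dW0 <- crossprod(cache$z, dh0)
  db0 <- colSums(dh0)
  list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1, K = cb$dK, bK = sum(cb$db))
}

disc_forward <- function(d, x, n_feat, f) {
  B <- nrow(x)
  xa <- array(x, c(B, n_feat, 1))
  c1 <- conv1d_forward(xa, array(d$K, c(nrow(d$K), 1, f)), d$bK)
  a1 <- leaky_relu(c1)
  af <- matrix(a1, B, n_feat * f)
  pre_h <- sweep(af %*% d$W1, 2, d$b1, "+")
  h <- leaky_relu(pre_h)
  logit <- sweep(h %*% d$W2, 2, d$b2, "+")
  list(xa = xa, c1 = c1, af = af, pre_h = pre_h, h = h, logit = logit)
}

disc_backward <- function(d, cache, dlogit, n_feat, f, need_dx = FALSE) {
  B <- nrow(dlogit)
  dW2 <- crossprod(cache$h, dlogit)
  db2 <- sum(dlogit)
  dh <- (dlogit %*% t(d$W2)) * d_leaky_relu(cache$pre_h)
  dW1 <- crossprod(cache$af, dh)
  db1 <- colSums(dh)
  daf <- dh %*% t(d$W1)
  da1 <- array(daf, c(B, n_feat, f)) * d_leaky_relu(cache$c1)
  cb <- conv1d_backward(cache$xa, array(d$K, c(nrow(d$K), 1, f)), da1)
  grads <- list(K = cb$dK, bK = cb$db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  dx <- if (need_dx) matrix(cb$dx, B, n_feat) else NULL
  list(grads = grads, dx = dx)
}

bce_with_logits <- function(logit, y) {
  # numerically stable binary cross-entropy
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

#' Train a per-class DCGAN-style augmenter on feature vectors
#'
#' Adversarial training of a generator that maps 100-dimensional uniform
#' noise to a 12-dimensional feature vector of one class, against a 1-D
#' convolutional discriminator. Features are min-max scaled to \[-1, 1\]
#' (scaler fitted on the training vectors); the generator's tanh output lives
#' in the same range. One generator/discriminator update pair per minibatch,
#' binary cross-entropy losses, Adam with the configured momentum. Training
#' is deterministic given `cfg$seed`.
#'
#' @param features tibble of real feature vectors of one class (numeric
#'   feature columns; optional `phase_id`/`label`/`origin` columns). Needs at
#'   least one full batch of rows.
#' @param cfg a [gan_config()].
#' @return An object of class `mnl_dcgan`: generator/discriminator weights,
#'   the fitted [feature_scaler()], per-epoch losses, class label and the
#'   provenance (`train_uids`) of the training rows.
#' @export
train_dcgan <- function(features, cfg = gan_config()) {
  features <- as_tibble(features)
  lab <- if ("label" %in% names(features)) {
    u <- unique(as.character(features$label))
    if (length(u) != 1) stop_contract("train_dcgan expects vectors of a single class")
    u
  } else {
    NA_character_
  }
  feat_names <- feature_cols_of(features)
  n_feat <- length(feat_names)
  n <- nrow(features)
  if (n < cfg$batch_size) {
    stop_insufficient(sprintf(
      "need at least one full batch (%d) of real vectors, got %d",
      cfg$batch_size, n
    ))
  }
  set.seed(cfg$seed)
  scaler <- feature_scaler(features)
  X <- scale_features(scaler, features)
  p <- gan_init_params(cfg, n_feat)
  fit <- dcgan_train_cpp(
    X, p, cfg$epochs, cfg$batch_size, cfg$learning_rate,
    cfg$adam_momentum, cfg$noise_dim, cfg$filters, cfg$kernel,
    cfg$lr_decay
  )
  p$g <- lapply(fit$g, drop_dims)
  p$d <- lapply(fit$d, drop_dims)
  d_loss <- as.numeric(fit$d_loss)
  g_loss <- as.numeric(fit$g_loss)
  structure(
    list(
      generator = p$g, discriminator = p$d, scaler = scaler,
      feature_names = feat_names, label = lab, cfg = cfg,
      losses = tibble(epoch = seq_len(cfg$epochs), d_loss = d_loss, g_loss = g_loss),
      train_uids = if ("phase_id" %in% names(features)) features$phase_id else NULL
    ),
    class = "mnl_dcgan"
  )
}

#' @export
print.mnl_dcgan <- function(x, ...) {
  cat(sprintf(
    "<mnl_dcgan> class %s, %d features, %d epochs (final D loss %.3f, G loss %.3f)\n",
    x$label, length(x$feature_names), x$cfg$epochs,
    tail(x$losses$d_loss, 1), tail(x$losses$g_loss, 1)
  ))
  invisible(x)
}

#' Draw synthetic feature vectors from a trained augmenter
#'
#' Samples latent noise, maps it through the generator and de-scales back to
#' the original feature units. Integer features (event counts, the modal APS
#' bin) are rounded and all features are clipped to their hard bounds
#' (percentages to \[0, 100\], counts to >= 0, bin index to \[1, 20\]). The
#' class label is inherited from the generator's training class.
#'
#' @param gan a trained [train_dcgan()] model.
#' @param n number of vectors to draw (> 0).
#' @param seed RNG seed.
#' @return A tibble with `phase_id`, `label`, `origin = "synthetic"` and the
#'   feature columns.
#' @export
sample_synthetic <- function(gan, n, seed = 1) {
  stopifnot(inherits(gan, "mnl_dcgan"))
  if (n <= 0) stop_contract("n must be positive")
  set.seed(as.integer(seed %% 2147483647))
  cfg <- gan$cfg
  n_feat <- length(gan$feature_names)
  z <- matrix(runif(n * cfg$noise_dim, -1, 1), n)
  x <- gen_forward(gan$generator, z, n_feat, cfg$filters)$x
  out <- unscale_features(gan$scaler, x)
  out <- as_tibble(out)
  for (nm in names(out)) {
    b <- feature_hard_bounds(nm)
    v <- pmin(pmax(out[[nm]], b[1]), b[2])
    if (nm %in% integer_features) v <- round(v)
    out[[nm]] <- v
  }
  dplyr::bind_cols(
    tibble(
      phase_id = sprintf("synth_%s_%d", gan$label, seq_len(n)),
      label = factor(gan$label, levels = phase_labels),
      origin = "synthetic"
    ),
    out
  )
}

#' Real-vs-synthetic overlap in a 2-D embedding
#'
#' Embeds real and synthetic feature vectors jointly with t-SNE (fixed
#' perplexity and seed) and quantifies how separable the two sets are in the
#' embedding: a 5-fold cross-validated logistic discriminator's balanced
#' accuracy, floored at 0.5. A score near 0.5 means the synthetic points
#' overlap the real ones (the desired outcome of augmentation); a score near
#' 1 means they form their own cluster.
#'
#' @param real,synthetic tibbles of feature vectors (>= 10 rows each).
#' @param seed RNG seed for the embedding and CV folds.
#' @param perplexity t-SNE perplexity (reduced automatically for small sets).
#' @param max_points larger sets are subsampled to this size before
#'   embedding (exact t-SNE is quadratic in the point count).
#' @return An object of class `overlap_report`: `embedding` (tibble with
#'   `dim1`, `dim2`, `set`) and `separability` in \[0.5, 1\].
#' @export
embedding_overlap <- function(real, synthetic, seed = 1, perplexity = 30,
                              max_points = 600) {
  real <- as_tibble(real)
  synthetic <- as_tibble(synthetic)
  feats <- intersect(feature_cols_of(real), feature_cols_of(synthetic))
  if (nrow(real) < 10 || nrow(synthetic) < 10) {
    stop_insufficient("embedding_overlap needs at least 10 points per set")
  }
  set.seed(as.integer(seed %% 2147483647))
  sub <- function(x) {
    if (nrow(x) > max_points / 2) x[sample.int(nrow(x), max_points / 2), ] else x
  }
  real <- sub(real); synthetic <- sub(synthetic)
  X <- rbind(as.matrix(real[feats]), as.matrix(synthetic[feats]))
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  Y <- tsne_embed(Xs, perplexity = perplexity, seed = seed + 1)
  set_lab <- c(rep("real", nrow(real)), rep("synthetic", nrow(synthetic)))
  emb <- tibble(dim1 = Y[, 1], dim2 = Y[, 2], set = set_lab)
  score <- cv_separability(Y, set_lab == "synthetic", seed = seed + 2)
  structure(
    list(embedding = emb, separability = score),
    class = "overlap_report"
  )
}

cv_separability <- function(Y, is_synth, k = 5, seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  n <- length(is_synth)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- logical(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    df <- data.frame(y = is_synth[tr], d1 = Y[tr, 1], d2 = Y[tr, 2])
    fit <- suppressWarnings(stats::glm(y ~ d1 + d2, family = stats::binomial(), data = df))
    ph <- predict(fit, newdata = data.frame(d1 = Y[!tr, 1], d2 = Y[!tr, 2]),
                  type = "response")
    pred[!tr] <- ph > 0.5
  }
  acc_synth <- mean(pred[is_synth])
  acc_real <- mean(!pred[!is_synth])
  max(0.5, (acc_synth + acc_real) / 2)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> %d embedded points, separability %.3f (0.5 = full overlap)\n",
    nrow(x$embedding), x$separability
  ))
  invisible(x)
}

#' @export
tidy.mnl_dcgan <- function(x, ...) x$losses

#' @export
glance.mnl_dcgan <- function(x, ...) {
  tibble(
    label = x$label,
    epochs = x$cfg$epochs,
    n_train = if (!is.null(x$train_uids)) length(x$train_uids) else NA_integer_,
    final_d_loss = tail(x$losses$d_loss, 1),
    final_g_loss = tail(x$losses$g_loss, 1)
  )
}
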