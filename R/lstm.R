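#' LSTM classifier configuration
#'
#' The MNL/non-MNL classifier: a single-layer LSTM with 32 units consuming
#' one feature vector per time step (time step = 1, so one gated recurrent
#' cell application per phase), a 2-node softmax output, categorical
#' cross-entropy loss and RMSProp optimization. 1000 training epochs at batch
#' size 32; recurrent and input weights initialized orthogonally, biases at
#' zero.
#'
#' @param epochs training epochs (default 1000).
#' @param batch_size minibatch size (default 32).
#' @param units LSTM units per layer (default 32).
#' @param n_layers number of stacked LSTM layers (default 1).
#' @param learning_rate RMSProp learning rate (default 0.001).
#' @param rms_decay RMSProp decay constant (default 0.9).
#' @param seed RNG seed.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(epochs = 1000, batch_size = 32, units = 32,
                        n_layers = 1, learning_rate = 0.001, rms_decay = 0.9,
                        seed = 1) {
  vals <- c(epochs, batch_size, units, n_layers, learning_rate, rms_decay)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_config("all lstm_config values must be positive")
  }
  if (n_layers != 1) {
    stop_config("only a single LSTM layer is implemented (n_layers = 1)")
  }
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      units = as.integer(units), n_layers = as.integer(n_layers),
      learning_rate = learning_rate, rms_decay = rms_decay,
      seed = as.integer(seed)
    ),
    class = "lstm_config"
  )
}

lstm_init_params <- function(n_feat, units) {
  # gate order: input, forget, cell, output; W maps features, U the (zero)
  # initial hidden state — kept so the cell is the full gated unit
  list(
    W = orthogonal_init(n_feat, 4 * units),
    U = orthogonal_init(units, 4 * units),
    b = rep(0, 4 * units),
    Wy = orthogonal_init(units, 2),
    by = rep(0, 2)
  )
}

lstm_forward <- function(p, X) {
  B <- nrow(X)
  u <- ncol(p$U) / 4
  # h0 = c0 = 0, single time step
  zg <- sweep(X %*% p$W, 2, p$b, "+")
  gi <- sigmoid(zg[, 1:u, drop = FALSE])
  gf <- sigmoid(zg[, (u + 1):(2 * u), drop = FALSE])
  gc <- tanh(zg[, (2 * u + 1):(3 * u), drop = FALSE])
  go <- sigmoid(zg[, (3 * u + 1):(4 * u), drop = FALSE])
  cell <- gi * gc # f * c0 vanishes with c0 = 0
  tc <- tanh(cell)
  h <- go * tc
  logits <- sweep(h %*% p$Wy, 2, p$by, "+")
  m <- apply(logits, 1, max)
  el <- exp(logits - m)
  probs <- el / rowSums(el)
  list(X = X, gi = gi, gf = gf, gc = gc, go = go, cell = cell, tc = tc,
       h = h, logits = logits, probs = probs)
}

lstm_backward <- function(p, cache, Yonehot) {
  B <- nrow(Yonehot)
  u <- ncol(p$U) / 4
  dlogits <- (cache$probs - Yonehot) / B
  dWy <- crossprod(cache$h, dlogits)
  dby <- colSums(dlogits)
  dh <- dlogits %*% t(p$Wy)
  dgo <- dh * cache$tc * cache$go * (1 - cache$go)
  dcell <- dh * cache$go * (1 - cache$tc^2)
  dgi <- dcell * cache$gc * cache$gi * (1 - cache$gi)
  dgc <- dcell * cache$gi * (1 - cache$gc^2)
  dgf <- matrix(0, B, u) # forget gate sees c0 = 0: no gradient
  dz <- cbind(dgi, dgf, dgc, dgo)
  dW <- crossprod(cache$X, dz)
  db <- colSums(dz)
  list(W = dW, b = db, Wy = dWy, by = dby,
       U = p$U * 0) # h0 = 0: recurrent weights receive no gradient at t = 1
}

#' Train the LSTM classifier
#'
#' Trains on labelled feature vectors. Features are z-scored using statistics
#' of the *real* training rows only (synthetic and test vectors are
#' standardized with the same statistics). Per-epoch cross-entropy loss is
#' logged; training is deterministic given `cfg$seed`.
#'
#' @param train tibble with `label` (both classes present), the feature
#'   columns, and optionally `origin` (`"real"`/`"synthetic"`; all rows are
#'   treated as real when absent).
#' @param cfg an [lstm_config()].
#' @return An object of class `mnl_lstm`.
#' @export
train_lstm <- function(train, cfg = lstm_config()) {
  train <- as_tibble(train)
  if (!"label" %in% names(train)) stop_contract("training data needs a 'label' column")
  lab <- as.character(train$label)
  if (length(unique(lab)) < 2) {
    stop_contract("training set must contain both classes")
  }
  feats <- feature_cols_of(train)
  X <- as.matrix(train[feats])
  if (any(!is.finite(X))) stop_contract("training features must be finite")
  origin <- if ("origin" %in% names(train)) train$origin else rep("real", nrow(train))
  real_rows <- origin == "real"
  if (!any(real_rows)) real_rows <- rep(TRUE, nrow(train))
  mu <- colMeans(X[real_rows, , drop = FALSE])
  sg <- apply(X[real_rows, , drop = FALSE], 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  # positive class: non-MNL (column 2 of the softmax)
  y <- as.integer(lab == "non-MNL")
  Y <- cbind(1 - y, y)
  set.seed(cfg$seed)
  p <- lstm_init_params(ncol(Xs), cfg$units)
  fit <- lstm_train_cpp(
    Xs, y, p, cfg$epochs, cfg$batch_size, cfg$units,
    cfg$learning_rate, cfg$rms_decay
  )
  p <- list(
    W = fit$W, U = fit$U, b = drop_dims(fit$b),
    Wy = fit$Wy, by = drop_dims(fit$by)
  )
  loss <- as.numeric(fit$loss)
  structure(
    list(
      params = p, cfg = cfg, feature_names = feats,
      center = mu, scale = sg,
      losses = tibble(epoch = seq_len(cfg$epochs), loss = loss)
    ),
    class = "mnl_lstm"
  )
}

#' @export
print.mnl_lstm <- function(x, ...) {
  cat(sprintf(
    "<mnl_lstm> %d units, %d features, %d epochs (final loss %.4f)\n",
    x$cfg$units, length(x$feature_names), x$cfg$epochs, tail(x$losses$loss, 1)
  ))
  invisible(x)
}

#' @export
predict.mnl_lstm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as_tibble(newdata)
  X <- as.matrix(newdata[object$feature_names])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  probs <- lstm_forward(object$params, Xs)$probs
  colnames(probs) <- c("MNL", "non-MNL")
  if (type == "prob") {
    return(as_tibble(probs))
  }
  factor(ifelse(probs[, 2] > 0.5, "non-MNL", "MNL"), levels = phase_labels)
}

#' Confusion-count classification metrics
#'
#' Builds accuracy, sensitivity and specificity (percent) from confusion
#' counts, with **non-MNL as the positive class**: sensitivity is the
#' true-positive rate on non-MNL phases, specificity the true-negative rate
#' on MNL phases.
#'
#' @param tp,fn true positives / false negatives (non-MNL phases called
#'   non-MNL / MNL).
#' @param tn,fp true negatives / false positives (MNL phases called MNL /
#'   non-MNL).
#' @param roc optional tibble of ROC points (`fpr`, `tpr`, `threshold`).
#' @return An object of class `classification_metrics`.
#' @examples
#' m <- classification_metrics(tp = 40, fn = 4, tn = 16, fp = 1)
#' m$accuracy # 91.80
#' @export
classification_metrics <- function(tp, fn, tn, fp, roc = NULL) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_contract("confusion counts must be non-negative integers")
  }
  structure(
    list(
      tp = tp, fn = fn, tn = tn, fp = fp,
      accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
      roc = roc
    ),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "<classification_metrics> accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%% (tp %d, fn %d, tn %d, fp %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$tp, x$fn, x$tn, x$fp
  ))
  invisible(x)
}

#' @export
tidy.classification_metrics <- function(x, ...) {
  tibble(
    metric = c("accuracy", "sensitivity", "specificity"),
    percent = c(x$accuracy, x$sensitivity, x$specificity)
  )
}

#' @export
glance.classification_metrics <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity,
    tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp
  )
}

# ROC over the softmax-score sweep, positive class non-MNL
roc_points <- function(score_pos, is_pos) {
  ord <- order(score_pos, decreasing = TRUE)
  sc <- score_pos[ord]
  yp <- is_pos[ord]
  tp <- cumsum(yp)
  fp <- cumsum(!yp)
  keep <- c(diff(sc) != 0, TRUE) # one point per distinct threshold
  tibble(
    threshold = c(Inf, sc[keep]),
    tpr = c(0, tp[keep] / sum(is_pos)),
    fpr = c(0, fp[keep] / sum(!is_pos))
  )
}

#' Evaluate a classifier on a labelled test set
#'
#' @param model a trained [train_lstm()] model.
#' @param test tibble with `label` (both classes present) and the feature
#'   columns.
#' @return A [classification_metrics()] with the ROC curve attached.
#' @export
evaluate_classifier <- function(model, test) {
  test <- as_tibble(test)
  if (!"label" %in% names(test)) stop_contract("test data needs a 'label' column")
  lab <- as.character(test$label)
  if (nrow(test) == 0 || length(unique(lab)) < 2) {
    stop_contract("test set must be non-empty with both classes present")
  }
  probs <- predict(model, test, type = "prob")
  is_pos <- lab == "non-MNL"
  called_pos <- probs[["non-MNL"]] > 0.5
  classification_metrics(
    tp = sum(is_pos & called_pos),
    fn = sum(is_pos & !called_pos),
    tn = sum(!is_pos & !called_pos),
    fp = sum(!is_pos & called_pos),
    roc = roc_points(probs[["non-MNL"]], is_pos)
  )
}

#' Run the data-feeding experiment
#'
#' Reproduces the augmentation protocol: for each synthetic-sample size `s`
#' in `synth_sizes`, the training set is the real vectors plus `s` synthetic
#' vectors per class drawn from per-class generators trained on the real
#' training portion only; one LSTM is trained per strategy and all
#' strategies are evaluated on the identical held-out test set. Generators
#' whose training provenance overlaps the test set are rejected.
#'
#' @param real_train labelled real training feature tibble (both classes).
#' @param test labelled test feature tibble; never touched by the GANs.
#' @param gan_mnl,gan_non trained per-class [train_dcgan()] generators; when
#'   `NULL` they are trained here with `gan_cfg`.
#' @param synth_sizes synthetic vectors per class to append
#'   (default `c(0, 200, 1000, 1600, 2000)`).
#' @param gan_cfg a [gan_config()] used when generators are trained here.
#' @param lstm_cfg an [lstm_config()].
#' @param seed master seed; per-strategy seeds derive from it.
#' @return A tibble of class `feeding_result`: one row per strategy with the
#'   train composition, metrics, and the `classification_metrics` objects in
#'   a list column.
#' @export
feeding_experiment <- function(real_train, test,
                               gan_mnl = NULL, gan_non = NULL,
                               synth_sizes = c(0, 200, 1000, 1600, 2000),
                               gan_cfg = gan_config(),
                               lstm_cfg = lstm_config(),
                               seed = 1) {
  real_train <- as_tibble(real_train)
  test <- as_tibble(test)
  if ("phase_id" %in% names(real_train)) {
    real_train$phase_id <- as.character(real_train$phase_id)
  }
  if ("phase_id" %in% names(test)) test$phase_id <- as.character(test$phase_id)
  lab <- as.character(real_train$label)
  if (!all(phase_labels %in% lab)) {
    stop_contract("real_train must contain both classes")
  }
  if (!"origin" %in% names(real_train)) real_train$origin <- "real"
  if (is.null(gan_mnl)) {
    gan_mnl <- train_dcgan(
      filter(real_train, .data$label == "MNL"),
      utils::modifyList(gan_cfg, list(seed = derive_seed(seed, "gan_mnl")))
    )
  }
  if (is.null(gan_non)) {
    gan_non <- train_dcgan(
      filter(real_train, .data$label == "non-MNL"),
      utils::modifyList(gan_cfg, list(seed = derive_seed(seed, "gan_non")))
    )
  }
  if ("phase_id" %in% names(test)) {
    leaked <- intersect(
      c(gan_mnl$train_uids, gan_non$train_uids), test$phase_id
    )
    if (length(leaked) > 0) {
      stop_contract(sprintf(
        "generator was trained on %d test phase(s): data leakage", length(leaked)
      ))
    }
  }
  purrr::map_dfr(synth_sizes, function(s) {
    train <- real_train
    if (s > 0) {
      train <- bind_rows(
        train,
        sample_synthetic(gan_mnl, s, seed = derive_seed(seed, paste0("synth_mnl_", s))),
        sample_synthetic(gan_non, s, seed = derive_seed(seed, paste0("synth_non_", s)))
      )
    }
    cfg_s <- lstm_cfg
    cfg_s$seed <- derive_seed(seed, paste0("lstm_", s))
    model <- train_lstm(train, cfg_s)
    m <- evaluate_classifier(model, test)
    tibble(
      strategy = if (s == 0) "R" else sprintf("R+%dS", s),
      n_real = nrow(real_train),
      n_synth_per_class = s,
      accuracy = m$accuracy,
      sensitivity = m$sensitivity,
      specificity = m$specificity,
      metrics = list(m)
    )
  })
}
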