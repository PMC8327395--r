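# Compact exact t-SNE (no Barnes-Hut): adequate for the few hundred feature
# vectors whose real-vs-synthetic overlap is being inspected. Standard
# recipe: per-point bandwidths from a binary search on perplexity, symmetric
# affinities, early exaggeration, momentum gradient descent.

tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sump) + beta * sum(di * p) / sump
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_embed <- function(X, perplexity = 30, n_iter = 300, seed = 1) {
  n <- nrow(X)
  if (n < 8) stop_insufficient("t-SNE embedding needs at least 8 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(as.integer(seed %% 2147483647))
  P <- tsne_affinities(X, perplexity)
  Y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  eta <- 200
  exag_until <- min(100, n_iter %/% 3)
  P4 <- P * 4
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= exag_until) P4 else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    if (iter == 120) momentum <- 0.8
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
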