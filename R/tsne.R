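# Compact t-SNE on a precomputed distance matrix. Used only to lay out the
# variant similarity network for display; nothing downstream depends on the
# coordinates. Deterministic given the seed.
tsne_embed <- function(D, perplexity = 30, seed = 7L, max_iter = 300L,
                       eta = 100) {
  n <- nrow(D)
  set.seed(seed)
  if (n == 1L) return(matrix(0, 1L, 2L))
  if (n <= 4L) {
    y <- stats::cmdscale(stats::as.dist(D), k = min(2L, n - 1L))
    if (ncol(y) < 2L) y <- cbind(y, 0)
    return(y + 1e-4 * matrix(rnorm(2L * n), n, 2L))
  }
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- D^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { beta_hi <- beta; beta <- (beta_lo + beta) / 2; next }
      p <- w / sw
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {  # entropy too high -> sharpen
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    P[i, -i] <- exp(-di * beta) / max(sum(exp(-di * beta)), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- 1e-4 * matrix(rnorm(2L * n), n, 2L)
  G <- matrix(0, n, 2L)  # momentum term
  for (iter in seq_len(max_iter)) {
    Pi <- if (iter <= 50L) 4 * P else P  # early exaggeration
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- 4 * (Pi - Q) * num
    grad <- (diag(rowSums(W)) - W) %*% Y
    mom <- if (iter <= 20L) 0.5 else 0.8
    G <- mom * G - eta * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
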