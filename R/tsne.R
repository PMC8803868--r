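# Exact t-SNE (no tree approximation) for small feature tables. The
# cohorts embedded here hold on the order of 100 maps, so the O(n^2)
# gradient is computed in full at every iteration.

# per-point conditional probabilities at the requested perplexity,
# calibrated by bisection on the Gaussian precision
.tsne_p <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- D2[i, -i]
    for (iter in seq_len(60)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne <- function(X, dims = 2, perplexity = 10, n_iter = 500,
                  learning_rate = 100, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_p(D2, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  gain <- matrix(1, n, dims); inc <- matrix(0, n, dims)
  momentum <- 0.5
  P_run <- P * 4   # early exaggeration
  for (it in seq_len(n_iter)) {
    if (it == 101) P_run <- P
    if (it == 251) momentum <- 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - learning_rate * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
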