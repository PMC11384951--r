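## Exact (O(n^2)) t-distributed stochastic neighbor embedding. Suitable for
## the cohort sizes this package works with (a few thousand state vectors);
## no tree approximation is attempted.

## per-point conditional affinities calibrated to the target perplexity
tsneAffinities <- function(d2, perplexity) {
  n <- nrow(d2)
  targetH <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { p <- rep(1 / length(di), length(di)); break }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - targetH) < 1e-5) break
      if (H > targetH) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Exact t-SNE embedding
#'
#' Gradient descent with momentum and early exaggeration on the
#' Kullback-Leibler divergence between Gaussian input affinities (calibrated
#' per point to `perplexity`) and Student-t output affinities. Deterministic
#' given `seed`.
#'
#' @param x numeric matrix (observations as rows).
#' @param dims output dimensionality (default 2).
#' @param perplexity affinity calibration target; reduced automatically when
#'   the sample is too small for the requested value.
#' @param max_iter gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @return numeric matrix of embedding coordinates.
#' @export
tsneEmbed <- function(x, dims = 2L, perplexity = 30, max_iter = 300L,
                      seed = 1L) {
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 observations for t-SNE")
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2
  P <- tsneAffinities(d2, perplexity)
  withSeed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  })
  dY <- matrix(0, n, dims); gains <- matrix(1, n, dims)
  eta <- 200; momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100L) 4 else 1
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
    if (iter == 20L) momentum <- 0.8
  }
  Y
}
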