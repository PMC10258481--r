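# 2-D visualization of sequence libraries by t-distributed stochastic
# neighbour embedding over one-hot encodings with the L1 metric. For one-hot
# vectors the L1 distance between two sequences is exactly twice their
# Hamming distance, so the embedding approximately preserves mutational
# distance. Exact (non-tree) t-SNE: adequate for desk-scale libraries.

# per-point conditional distributions at a target perplexity (binary search
# over the Gaussian bandwidth), from squared distances
tsne_p_matrix <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; pj <- rep(0, length(di)) }
      else {
        pj <- w / sw
        H <- log(sw) + beta * sum(di * w) / sw
      }
      hdiff <- H - logU
      if (abs(hdiff) < tol) break
      if (hdiff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- pj
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed sequence feature vectors in 2-D with t-SNE
#'
#' Exact t-SNE with the L1 metric (distances squared, as in common library
#' implementations for non-Euclidean metrics) and PCA initialisation, with
#' early exaggeration and momentum gradient descent. Intended for one-hot
#' encoded libraries, where L1 distance is twice the Hamming distance.
#'
#' @param X Numeric matrix of feature vectors (e.g. [onehot_encode()]
#'   output), one row per sequence.
#' @param perplexity t-SNE perplexity; must be below the number of rows
#'   (500 at full library scale; use smaller values for small inputs).
#' @param learning_rate Gradient-descent learning rate.
#' @param n_iter Number of gradient iterations.
#' @param seed Integer seed (gradient jitter at initialisation).
#' @return Numeric matrix `n x 2` of embedding coordinates.
#' @export
embed_2d <- function(X, perplexity = 30, learning_rate = 200, n_iter = 500L,
                     seed = 1L) {
  n <- nrow(X)
  if (n < 2L) stop_scfv("embedding needs at least 2 sequences", class = "invalid_config")
  if (perplexity >= n) {
    stop_scfv("perplexity (", perplexity, ") must be below the number of sequences (",
              n, ")", class = "invalid_config")
  }
  D2 <- as.matrix(stats::dist(X, method = "manhattan"))^2
  P <- tsne_p_matrix(D2, perplexity)

  with_seed(seed, {
    pca <- stats::prcomp(X, rank. = 2L)
    Y <- pca$x[, 1:2, drop = FALSE]
    if (ncol(Y) < 2L) Y <- cbind(Y, 0)
    Y <- scale(Y, scale = FALSE)
    Y <- Y / max(stats::sd(Y), 1e-12) * 1e-4
    Y <- Y + matrix(stats::rnorm(2L * n, sd = 1e-6), n, 2L)

    gains <- matrix(1, n, 2L)
    inc <- matrix(0, n, 2L)
    exag <- 12
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= 100L) P * exag else P
      # low-dimensional affinities (Student-t kernel)
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (it <= 250L) 0.5 else 0.8
      gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8), 0.01)
      inc <- momentum * inc - learning_rate * gains * grad
      Y <- Y + inc
      Y <- scale(Y, scale = FALSE)
    }
    dimnames(Y) <- list(rownames(X), c("tsne1", "tsne2"))
    Y
  })
}
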