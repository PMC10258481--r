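# Sequence-to-affinity surrogate models with uncertainty quantification:
# a multi-member regression ensemble (encoder x loss x missing-data policy)
# and a PCA + Gaussian-process model. Both expose predict() returning a
# predictive mean and standard deviation per sequence.

# ---- linear members -------------------------------------------------------

# Ridge regression (squared loss). Uses the primal normal equations when
# p <= n and the kernel (dual) form otherwise.
fit_ridge <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  if (p <= n) {
    beta <- solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, yc))
  } else {
    alpha <- solve(tcrossprod(Xc) + lambda * diag(n), yc)
    beta <- crossprod(Xc, alpha)
  }
  list(beta = drop(beta), intercept = ym - sum(xm * drop(beta)))
}

# L1 (MAE) loss via iteratively reweighted least squares with a small ridge
# stabiliser; weights w_i = 1 / max(|r_i|, delta). Deterministic.
fit_l1 <- function(X, y, lambda, iters = 8L, delta = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  w <- rep(1, n)
  beta <- NULL
  use_dual <- p > n
  K <- if (use_dual) tcrossprod(Xc) else NULL
  for (it in seq_len(iters)) {
    if (use_dual) {
      # weighted dual: beta = Xc' D (D K D + lambda I)^-1 D yc, D = diag(sqrt(w))
      s <- sqrt(w)
      S <- K * tcrossprod(s) + lambda * diag(n)
      alpha <- s * solve(S, s * yc)
      beta <- drop(crossprod(Xc, alpha))
    } else {
      XtW <- t(Xc * w)
      beta <- drop(solve(XtW %*% Xc + lambda * diag(p), XtW %*% yc))
    }
    r <- yc - drop(Xc %*% beta)
    w <- 1 / pmax(abs(r), delta)
  }
  list(beta = beta, intercept = ym - sum(xm * beta))
}

predict_member <- function(member, X) {
  drop(X %*% member$fit$beta) + member$fit$intercept
}

# ---- ensemble -------------------------------------------------------------

#' Train the sequence-to-affinity regression ensemble
#'
#' Fits one regression member per (encoder, loss, preprocessing policy)
#' combination: losses are squared error (ridge) and absolute error (IRLS-L1),
#' policies are drop-missing and median-impute. With the three built-in
#' encoders this yields 12 members (a fourth, user-supplied encoder family
#' restores the 16-member configuration). The ensemble's prediction is the
#' mean of the member outputs and its uncertainty the population standard
#' deviation across members.
#'
#' @param data An [affinity_dataset()].
#' @param space A [design_space()].
#' @param encoders Named list of encoders (default [default_encoders()]).
#' @param lambda Ridge penalty applied to every member.
#' @return Object of class `ensemble_model`.
#' @export
train_ensemble <- function(data, space, encoders = default_encoders(space),
                           lambda = 1e-2) {
  stopifnot(length(encoders) >= 1L)
  if (length(data) < 20L) {
    stop_scfv("need at least 20 training records", class = "insufficient_data")
  }
  tabs <- list(drop = preprocess(data, "drop"),
               impute = preprocess(data, "impute"))
  members <- list()
  for (ei in seq_along(encoders)) {
    enc <- encoders[[ei]]
    for (policy in names(tabs)) {
      tab <- tabs[[policy]]
      if (stats::var(tab$target) == 0) {
        warning("degenerate (zero-variance) targets under policy '", policy, "'")
      }
      X <- encode(enc, tab$sequence)
      for (loss in c("mse", "mae")) {
        fit <- if (loss == "mse") fit_ridge(X, tab$target, lambda) else
          fit_l1(X, tab$target, lambda)
        members[[length(members) + 1L]] <- list(
          encoder_index = ei, loss = loss, policy = policy, fit = fit)
      }
    }
  }
  structure(list(members = members, encoders = encoders, space = space,
                 lambda = lambda),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Affinity ensemble: ", length(x$members), " members (",
      length(x$encoders), " encoders x 2 losses x 2 policies)\n", sep = "")
  invisible(x)
}

#' Predict affinity with uncertainty
#'
#' @param object A fitted `ensemble_model`.
#' @param seqs Character vector of sequences.
#' @param ... Unused.
#' @return Data frame with columns `mean` (predicted log-affinity) and `sd`
#'   (population standard deviation across ensemble members).
#' @export
predict.ensemble_model <- function(object, seqs, ...) {
  n <- length(seqs)
  if (n == 0L) return(data.frame(mean = numeric(), sd = numeric()))
  enc_X <- lapply(object$encoders, encode, seqs = seqs)
  P <- vapply(object$members, function(m) {
    predict_member(m, enc_X[[m$encoder_index]])
  }, numeric(n))
  if (n == 1L) P <- matrix(P, nrow = 1L)
  mu <- rowMeans(P)
  s <- sqrt(pmax(rowMeans(P * P) - mu * mu, 0))
  data.frame(mean = mu, sd = s)
}

# ---- Gaussian process -----------------------------------------------------

gp_nll <- function(logpar, D2, y) {
  l2 <- exp(2 * logpar[1]); sf2 <- exp(2 * logpar[2]); sn2 <- exp(2 * logpar[3])
  n <- length(y)
  K <- sf2 * exp(-D2 / (2 * l2)) + diag(sn2 + 1e-8, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' Train the PCA + Gaussian-process affinity model
#'
#' Encodes training sequences, reduces the representation with principal
#' component analysis, and fits an exact Gaussian-process regressor with a
#' radial-basis-function kernel plus observation noise. Kernel length-scale,
#' signal variance and noise variance are optimised by maximising the log
#' marginal likelihood. Missing replicates are median-imputed upstream, as in
#' the reference preprocessing for this model family. Because exact GP
#' inference is cubic in the training size, training sets larger than
#' `max_train` are randomly subsampled (seeded).
#'
#' @param data An [affinity_dataset()].
#' @param space A [design_space()].
#' @param encoder Sequence encoder (default one-hot).
#' @param pca_dim Number of principal components to keep (capped at the
#'   available rank).
#' @param max_train Training subsample cap.
#' @param seed Integer seed for the subsample.
#' @return Object of class `gp_model`.
#' @export
train_gp <- function(data, space, encoder = encoder_onehot(space),
                     pca_dim = 128L, max_train = 1000L, seed = NULL) {
  if (pca_dim < 1L) stop_scfv("pca_dim must be >= 1", class = "invalid_config")
  tab <- preprocess(data, "impute")
  with_seed(seed, {
    if (nrow(tab) > max_train) {
      tab <- tab[sort(sample.int(nrow(tab), max_train)), , drop = FALSE]
    }
    X <- encode(encoder, tab$sequence)
    rank_cap <- min(pca_dim, nrow(X) - 1L, ncol(X))
    pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = rank_cap)
    Z <- pca$x
    y <- tab$target
    ym <- mean(y)
    yc <- y - ym
    D2 <- as.matrix(stats::dist(Z))^2
    med <- stats::median(D2[upper.tri(D2)])
    l0 <- 0.5 * log(max(med, 1e-6))
    sy <- log(max(stats::sd(y), 1e-3))
    # marginal-likelihood surfaces are multimodal (a noise-only mode competes
    # with the signal mode); optimise from several starts and keep the best
    starts <- list(c(l0, sy, sy - 2), c(l0 + 1.5, sy, sy - 1),
                   c(l0 - 1, sy, sy - 2), c(l0 + 0.7, sy + 0.5, sy - 3))
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        stats::optim(st, gp_nll, D2 = D2, y = yc, method = "L-BFGS-B",
                     lower = st - 8, upper = st + 8),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    l2 <- exp(2 * best$par[1]); sf2 <- exp(2 * best$par[2]); sn2 <- exp(2 * best$par[3])
    K <- sf2 * exp(-D2 / (2 * l2)) + diag(sn2 + 1e-8, nrow(Z))
    ch <- chol(K)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    structure(list(encoder = encoder, pca = pca, Z = Z, chol = ch,
                   alpha = alpha, ymean = ym, l2 = l2, sf2 = sf2, sn2 = sn2,
                   space = space, pca_dim = rank_cap),
              class = "gp_model")
  })
}

#' @export
print.gp_model <- function(x, ...) {
  cat("GP affinity model: ", nrow(x$Z), " inducing points, ", x$pca_dim,
      " principal components, lengthscale ", signif(sqrt(x$l2), 3), "\n", sep = "")
  invisible(x)
}

#' Predict affinity with the GP posterior
#'
#' @param object A fitted `gp_model`.
#' @param seqs Character vector of sequences.
#' @param ... Unused.
#' @return Data frame with columns `mean` (posterior mean) and `sd` (latent
#'   posterior standard deviation).
#' @export
predict.gp_model <- function(object, seqs, ...) {
  n <- length(seqs)
  if (n == 0L) return(data.frame(mean = numeric(), sd = numeric()))
  X <- encode(object$encoder, seqs)
  Z <- stats::predict(object$pca, X)[, seq_len(object$pca_dim), drop = FALSE]
  # squared distances to the training points
  d2 <- outer(rowSums(Z^2), rowSums(object$Z^2), "+") - 2 * tcrossprod(Z, object$Z)
  Ks <- object$sf2 * exp(-pmax(d2, 0) / (2 * object$l2))
  mu <- drop(Ks %*% object$alpha) + object$ymean
  v <- forwardsolve(t(object$chol), t(Ks))
  var <- pmax(object$sf2 - colSums(v^2), 1e-12)
  data.frame(mean = mu, sd = sqrt(var))
}

# ---- evaluation -----------------------------------------------------------

#' Evaluate a surrogate model against held-out measurements
#'
#' Computes the Spearman rank correlation between predicted means and the
#' averaged non-missing measurements, the overall mean absolute error, and
#' the MAE binned by mutational (Hamming) distance to a reference sequence
#' with per-bin standard errors. Records with every replicate missing are
#' excluded; empty distance bins are omitted.
#'
#' @param model A fitted `ensemble_model` or `gp_model`.
#' @param test An [affinity_dataset()].
#' @param reference Reference sequence for distance binning (typically the
#'   candidate/template).
#' @return List with `spearman`, `mae_overall` and data frame
#'   `mae_by_distance` (`distance`, `mae`, `sem`, `n`).
#' @export
evaluate_model <- function(model, test, reference) {
  keep <- !is.na(test$avg)
  if (!any(keep)) stop_scfv("no measured records to evaluate", class = "invalid_dataset")
  seqs <- test$sequence[keep]
  y <- test$avg[keep]
  pred <- stats::predict(model, seqs)$mean
  abs_err <- abs(pred - y)
  dist <- hamming_to(reference, seqs)
  bins <- sort(unique(dist))
  by_d <- do.call(rbind, lapply(bins, function(d) {
    e <- abs_err[dist == d]
    data.frame(distance = d, mae = mean(e),
               sem = stats::sd(e) / sqrt(length(e)), n = length(e))
  }))
  list(spearman = stats::cor(pred, y, method = "spearman"),
       mae_overall = mean(abs_err),
       mae_by_distance = by_d)
}
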