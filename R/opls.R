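# Multivariate models for spectral cohorts: PCA (backed by prcomp) and
# OPLS-DA with one predictive component, orthogonal-variation deflation,
# leave-one-out Q2 and label-permutation validation.

#' PCA scores of a sample-by-variable matrix
#'
#' Mean-centred principal component decomposition (no variance scaling by
#' default, the convention for spectral data).
#'
#' @param x sample-by-variable numeric matrix (>= 2 samples).
#' @param n_components number of components to return; must not exceed the
#'   rank bound `min(nrow - 1, ncol)`.
#' @param scale. logical; divide variables by their s.d. first.
#' @return list with `scores`, `loadings` (orthonormal columns),
#'   `explained_variance` (proportions, non-increasing) and `sdev`.
#' @export
pca_scores <- function(x, n_components = 2L, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 1L) stop("need >= 2 samples and >= 1 variable")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax)
    stop("n_components exceeds the rank bound (", kmax, ")")
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- seq_len(n_components)
  list(scores = p$x[, k, drop = FALSE],
       loadings = p$rotation[, k, drop = FALSE],
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[k],
       sdev = p$sdev[k])
}

# single O-PLS fit: one predictive component after n_orth orthogonal
# deflations. X rows = samples. y numeric (centred internally).
opls_fit <- function(X, y, n_orth = 1L) {
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xf <- sweep(X, 2, x_mean); yc <- y - y_mean
  W_o <- P_o <- vector("list", n_orth)
  used <- 0L
  for (j in seq_len(n_orth)) {
    w <- drop(crossprod(Xf, yc)); w <- w / sqrt(sum(w^2))
    t_ <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t_)) / sum(t_^2)
    w_o <- p - sum(w * p) * w
    nrm <- sqrt(sum(w_o^2))
    if (!is.finite(nrm) || nrm < 1e-10) break
    w_o <- w_o / nrm
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o[[j]] <- w_o; P_o[[j]] <- p_o; used <- j
  }
  w <- drop(crossprod(Xf, yc)); w <- w / sqrt(sum(w^2))
  t_p <- drop(Xf %*% w)
  q <- sum(yc * t_p) / sum(t_p^2)
  list(x_mean = x_mean, y_mean = y_mean,
       W_o = W_o[seq_len(used)], P_o = P_o[seq_len(used)],
       w = w, q = q, scores = t_p)
}

opls_predict <- function(fit, Xnew) {
  Xc <- sweep(rbind(Xnew), 2, fit$x_mean)
  for (j in seq_along(fit$W_o)) {
    t_o <- drop(Xc %*% fit$W_o[[j]])
    Xc <- Xc - tcrossprod(t_o, fit$P_o[[j]])
  }
  fit$y_mean + fit$q * drop(Xc %*% fit$w)
}

# leave-one-out Q2 = 1 - PRESS / TSS
opls_q2 <- function(X, y, n_orth) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    f <- opls_fit(X[-i, , drop = FALSE], y[-i], n_orth)
    press <- press + (y[i] - opls_predict(f, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' OPLS-DA with permutation validation
#'
#' Fits an orthogonal projections to latent structures discriminant model
#' with one predictive component and `n_orthogonal` orthogonal components
#' (NIPALS-style deflation), scores the model by leave-one-out
#' cross-validated Q2, and validates it by label permutation:
#' `p = (1 + #[permuted Q2 >= observed Q2]) / (1 + n_permutations)`.
#'
#' @param x sample-by-variable matrix.
#' @param labels two-class factor/character/logical vector, >= 3 samples per
#'   class.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list of class `oplsda`: `scores` (predictive), `loadings`
#'   (predictive weight vector, unit norm), `orthogonal` (per-component
#'   weights), `q2`, `permutation_p`, `permuted_q2`, `classes`, `fit`.
#' @export
oplsda_fit_and_permute <- function(x, labels, n_orthogonal = 1L,
                                   n_permutations = 1000L, seed = 1L) {
  x <- as.matrix(x)
  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("OPLS-DA requires exactly two classes")
  if (any(table(as.character(labels)) < 3L)) stop("each class needs >= 3 samples")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  y <- ifelse(as.character(labels) == lev[2], 1, -1)
  fit <- opls_fit(x, y, n_orthogonal)
  q2_obs <- opls_q2(x, y, n_orthogonal)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      opls_q2(x, sample(y), n_orthogonal)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= q2_obs)) / (1 + n_permutations)
  structure(list(scores = fit$scores, loadings = fit$w,
                 orthogonal = fit$W_o, q2 = q2_obs,
                 permutation_p = p, permuted_q2 = perm,
                 classes = stats::setNames(c(-1, 1), lev), fit = fit),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("<oplsda> 1 predictive + %d orthogonal component(s); Q2 = %.3f, permutation p = %.4g (%d permutations)\n",
              length(x$orthogonal), x$q2, x$permutation_p, length(x$permuted_q2)))
  invisible(x)
}
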