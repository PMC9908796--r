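# Independent oracles, written directly from the model definitions and kept
# free of the package's implementation paths.

# Mixed-model-equation BLUP with known variance components: the conditional
# mean of mu + sum_k u_k at every cell given the observed ones, computed by
# direct dense linear algebra on V = sum_k s2_k K_k[obs, obs] + s2e I.
oracle_mme_predict <- function(y_obs, obs_idx, kernels, sigma2, sigma2_eps) {
  n <- length(y_obs)
  V <- diag(sigma2_eps, n)
  for (k in names(kernels)) {
    V <- V + sigma2[[k]] * kernels[[k]][obs_idx, obs_idx]
  }
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop((t(one) %*% Vi %*% y_obs) / (t(one) %*% Vi %*% one))
  alpha <- Vi %*% (y_obs - mu)
  n_all <- nrow(kernels[[1L]])
  pred <- rep(mu, n_all)
  for (k in names(kernels)) {
    pred <- pred + sigma2[[k]] * drop(kernels[[k]][, obs_idx] %*% alpha)
  }
  pred
}

# Brute-force restricted likelihood for the one-way random model
# y = Xb + Zu + e, evaluated on a dense grid of the variance ratio.
oracle_reml_grid <- function(y, X, Z, lambdas) {
  n <- length(y)
  p <- qr(X)$rank
  vals <- vapply(lambdas, function(lam) {
    H <- tcrossprod(Z) + diag(lam, n)
    Hi <- solve(H)
    XtHiX <- t(X) %*% Hi %*% X
    b <- solve(XtHiX, t(X) %*% Hi %*% y)
    r <- y - X %*% b
    s2g <- drop(t(r) %*% Hi %*% r) / (n - p)
    -0.5 * ((n - p) * (1 + log(s2g)) +
              determinant(H, logarithm = TRUE)$modulus[1L] +
              determinant(XtHiX, logarithm = TRUE)$modulus[1L])
  }, numeric(1L))
  lam <- lambdas[which.max(vals)]
  H <- tcrossprod(Z) + diag(lam, n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  b <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% b
  s2g <- drop(t(r) %*% Hi %*% r) / (n - p)
  list(lambda = lam, sigma2_g = s2g, sigma2_e = lam * s2g,
       loglik = max(vals))
}
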