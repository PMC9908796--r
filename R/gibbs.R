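#' MCMC settings for the multi-kernel sampler
#'
#' Defaults follow common practice for these models: 25,000 iterations, a
#' burn-in of 5,000 and thinning of 10, with scaled-inverse-chi-squared
#' variance priors of 5 degrees of freedom.
#'
#' @param n_iter Total iterations.
#' @param burn_in Discarded initial iterations (`< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in sample (`>= 1`).
#' @param seed Integer RNG seed; recorded in the fit.
#' @param prior_df Prior degrees of freedom for every variance component.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 25000L, burn_in = 5000L, thin = 10L,
                          seed = 1L, prior_df = 5) {
  stopifnot(n_iter > burn_in, thin >= 1L, prior_df > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df),
            class = "mcmc_settings")
}

# Eigen-factorize a PSD kernel, truncating numerically null directions.
# Returns B with K ~= B %*% t(B), columns scaled by sqrt(eigenvalue).
.kernel_factor <- function(K, name, tol = 1e-8) {
  eg <- eigen(K, symmetric = TRUE)
  lmax <- max(eg$values, 1)
  if (min(eg$values) < -1e-6 * lmax) {
    stop("kernel '", name, "' is not positive semi-definite (min eigenvalue ",
         format(min(eg$values)), ")")
  }
  keep <- eg$values > tol * lmax
  if (!any(keep)) stop("kernel '", name, "' is numerically null")
  eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep))
}

# Effective sample size by the initial-positive-sequence autocorrelation rule.
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos) > 0L) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Fit a multi-kernel Bayesian GBLUP model by Gibbs sampling
#'
#' Fits `y = mu + sum_k u_k + eps` over the observed cells of the grid, with
#' `u_k ~ N(0, sigma2_k K_k)` for each supplied kernel and
#' `eps ~ N(0, sigma2_eps I)`. Each kernel is eigendecomposed once
#' (eigenvalues below `1e-8` of the largest truncated) and its effect
#' sampled in the eigenbasis; a second orthogonal rotation diagonalizes the
#' observed-cell Gram matrix so every coefficient block is updated in a
#' single vectorized draw. All variances carry scaled-inverse-chi-squared
#' priors whose modes split the phenotypic variance equally between the
#' terms and the residual.
#'
#' Masked cells are predicted as the posterior mean of `mu + sum_k u_k`,
#' with `u_k` sampled over all cells conditionally on the observed ones.
#'
#' @param grid An `obs_grid` with at least 10 observed cells.
#' @param kernels Named list of cell x cell PSD kernels from
#'   [build_kernels()].
#' @param settings An [mcmc_settings()] object.
#' @param fix_variances Optional named numeric vector (one entry per kernel
#'   plus `residual`) that freezes the variance components at known values;
#'   the sampler then draws only the effects, and the posterior mean
#'   prediction converges to the closed-form mixed-model BLUP at those
#'   variances.
#' @return An object of class `gp_fit`: list with `varcomp` (data.frame:
#'   term, post_mean, post_sd, ess), `mu`, `predictions` and
#'   `prediction_sd` (length `n_cells`), `term_effects` (cells x terms
#'   posterior means), `h2_g` (when a `g` term is present), `model_terms`,
#'   `settings`, `grid`.
#' @export
gibbs_fit <- function(grid, kernels, settings = mcmc_settings(),
                      fix_variances = NULL) {
  stopifnot(inherits(grid, "obs_grid"), length(kernels) >= 1L,
            inherits(settings, "mcmc_settings"))
  if (!is.null(fix_variances)) {
    need <- c(names(kernels), "residual")
    if (!all(need %in% names(fix_variances))) {
      stop("fix_variances must name every kernel term and 'residual'")
    }
  }
  obs <- which(grid$observed)
  n <- length(obs)
  if (n < 10L) stop("need at least 10 observed cells")
  y <- grid$y[obs]
  K <- length(kernels)
  terms <- names(kernels)

  # per-kernel factors and rotations (one-time cost)
  Mx <- Pfull <- list()
  Dk <- list()
  for (k in seq_len(K)) {
    B <- .kernel_factor(kernels[[k]], terms[k])
    Bobs <- B[obs, , drop = FALSE]
    eg <- eigen(crossprod(Bobs), symmetric = TRUE)
    Q <- eg$vectors
    Dk[[k]] <- pmax(eg$values, 0)
    Mx[[k]] <- Bobs %*% Q
    Pfull[[k]] <- B %*% Q
  }
  r_k <- vapply(Mx, ncol, integer(1L))

  vy <- max(stats::var(y), 1e-8)
  df0 <- settings$prior_df
  mode_share <- vy / (K + 1)
  S0 <- mode_share * (df0 + 2) / df0   # prior scale: mode = share
  S0e <- S0

  set.seed(settings$seed)
  fixed <- !is.null(fix_variances)
  mu <- mean(y)
  s2 <- if (fixed) unname(fix_variances[terms]) else rep(vy / (K + 1), K)
  s2e <- if (fixed) unname(fix_variances[["residual"]]) else vy / (K + 1)
  beta <- lapply(r_k, function(r) numeric(r))
  u_obs <- lapply(seq_len(K), function(k) numeric(n))
  resid <- y - mu

  keep_it <- seq(settings$burn_in + settings$thin, settings$n_iter,
                 by = settings$thin)
  n_keep <- length(keep_it)
  chain_s2 <- matrix(NA_real_, n_keep, K, dimnames = list(NULL, terms))
  chain_s2e <- numeric(n_keep)
  chain_mu <- numeric(n_keep)
  pred_sum <- pred_sq <- numeric(grid$n_cells)
  eff_sum <- matrix(0, grid$n_cells, K, dimnames = list(NULL, terms))
  stored <- 0L

  for (it in seq_len(settings$n_iter)) {
    for (k in seq_len(K)) {
      ek <- resid + u_obs[[k]]
      prec <- Dk[[k]] / s2e + 1 / s2[k]
      m <- (crossprod(Mx[[k]], ek) / s2e) / prec
      beta[[k]] <- drop(m) + stats::rnorm(r_k[k]) / sqrt(prec)
      u_new <- drop(Mx[[k]] %*% beta[[k]])
      resid <- ek - u_new
      u_obs[[k]] <- u_new
      if (!fixed) {
        s2[k] <- (df0 * S0 + sum(beta[[k]]^2)) /
          stats::rchisq(1L, df0 + r_k[k])
      }
    }
    em <- resid + mu
    mu <- mean(em) + stats::rnorm(1L) * sqrt(s2e / n)
    resid <- em - mu
    if (!fixed) {
      s2e <- (df0 * S0e + sum(resid^2)) / stats::rchisq(1L, df0 + n)
    }

    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0L) {
      stored <- stored + 1L
      chain_s2[stored, ] <- s2
      chain_s2e[stored] <- s2e
      chain_mu[stored] <- mu
      pred <- rep(mu, grid$n_cells)
      for (k in seq_len(K)) {
        uf <- drop(Pfull[[k]] %*% beta[[k]])
        eff_sum[, k] <- eff_sum[, k] + uf
        pred <- pred + uf
      }
      pred_sum <- pred_sum + pred
      pred_sq <- pred_sq + pred^2
    }
  }

  predictions <- pred_sum / stored
  prediction_sd <- sqrt(pmax(0, pred_sq / stored - predictions^2))
  ess_all <- c(apply(chain_s2, 2L, .ess), .ess(chain_s2e))
  varcomp <- data.frame(
    term = c(terms, "residual"),
    post_mean = c(colMeans(chain_s2), mean(chain_s2e)),
    post_sd = c(apply(chain_s2, 2L, stats::sd), stats::sd(chain_s2e)),
    ess = ess_all,
    stringsAsFactors = FALSE
  )
  if (any(ess_all < 50)) {
    warning("low effective sample size (< 50) for variance component(s): ",
            paste(varcomp$term[ess_all < 50], collapse = ", "),
            "; consider more iterations")
  }
  fit <- list(
    varcomp = varcomp,
    mu = mean(chain_mu),
    predictions = predictions,
    prediction_sd = prediction_sd,
    term_effects = eff_sum / stored,
    model_terms = terms,
    h2_g = if ("g" %in% terms) {
      s2g <- varcomp$post_mean[varcomp$term == "g"]
      s2r <- varcomp$post_mean[varcomp$term == "residual"]
      s2g / (s2g + s2r)
    } else NA_real_,
    settings = settings,
    grid = grid
  )
  class(fit) <- "gp_fit"
  fit
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Multi-kernel GBLUP fit (", paste(x$model_terms, collapse = " + "),
      ")\n", sep = "")
  print(x$varcomp, row.names = FALSE, digits = 4)
  if (!is.na(x$h2_g)) cat(sprintf("Genomic heritability h2_g = %.3f\n", x$h2_g))
  invisible(x)
}

#' Genomic heritability from a fit
#'
#' `h2_g = sigma2_g / (sigma2_g + sigma2_eps)` from the posterior means of
#' the genomic and residual variances.
#'
#' @param fit A `gp_fit` containing a `g` term.
#' @return Numeric in \[0, 1\].
#' @export
genomic_h2 <- function(fit) {
  stopifnot(inherits(fit, "gp_fit"))
  if (!"g" %in% fit$model_terms) stop("fit has no genomic (g) term")
  s2g <- fit$varcomp$post_mean[fit$varcomp$term == "g"]
  s2r <- fit$varcomp$post_mean[fit$varcomp$term == "residual"]
  s2g / (s2g + s2r)
}

#' Predictions for a fully untested environment
#'
#' Extracts the fitted cell predictions for a target environment that has no
#' observed cells in the fit's grid. Information reaches such an environment
#' only through kernels that link it to training cells: the genomic kernel
#' always, and the covariate kernels via `Omega`; the environment-identity
#' kernel and the `ge` interaction contribute exactly zero.
#'
#' @param fit A `gp_fit`.
#' @param env_id Target environment present in the fit's grid.
#' @return Named numeric vector of predictions (names = line ids).
#' @export
predict_new_environment <- function(fit, env_id) {
  stopifnot(inherits(fit, "gp_fit"))
  grid <- fit$grid
  idx <- which(grid$cells$env_id == env_id)
  if (length(idx) == 0L) stop("environment '", env_id, "' not in fit grid")
  if (any(grid$observed[idx])) {
    stop("environment '", env_id, "' has observed cells; not an untested ",
         "environment")
  }
  stats::setNames(fit$predictions[idx], grid$cells$line_id[idx])
}

#' Deterministic multi-kernel BLUP with known variance components
#'
#' Closed-form mixed-model prediction `mu + sum_k sigma2_k K_k[, obs] V^{-1}
#' (y - mu)` with `V = sum_k sigma2_k K_k[obs, obs] + sigma2_eps I` and `mu`
#' the generalized-least-squares intercept. Useful for fast structural
#' analyses when variance components are fixed rather than sampled.
#'
#' @param grid An `obs_grid`.
#' @param kernels Named list of cell x cell kernels.
#' @param sigma2 Named numeric vector of variance components, one per kernel.
#' @param sigma2_eps Residual variance (> 0).
#' @return List with `mu`, `predictions` (all cells), `term_effects`
#'   (cells x terms matrix).
#' @export
kernel_blup <- function(grid, kernels, sigma2, sigma2_eps) {
  stopifnot(inherits(grid, "obs_grid"), sigma2_eps > 0,
            all(names(kernels) %in% names(sigma2)))
  obs <- which(grid$observed)
  y <- grid$y[obs]
  n <- length(obs)
  V <- diag(sigma2_eps, n)
  for (k in names(kernels)) {
    V <- V + sigma2[[k]] * kernels[[k]][obs, obs]
  }
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  alpha <- Vi %*% (y - mu)
  eff <- matrix(0, grid$n_cells, length(kernels),
                dimnames = list(NULL, names(kernels)))
  pred <- rep(mu, grid$n_cells)
  for (k in names(kernels)) {
    eff[, k] <- sigma2[[k]] * drop(kernels[[k]][, obs] %*% alpha)
    pred <- pred + eff[, k]
  }
  list(mu = mu, predictions = pred, term_effects = eff)
}
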