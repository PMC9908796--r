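#' Stage-1 single-trial mixed model
#'
#' Fits the base trial model `y = Xb + Zu + e` with replicate as a fixed
#' effect, genotype as a random effect `u ~ N(0, sigma2_g I)` and i.i.d.
#' residuals, by restricted maximum likelihood. The restricted likelihood is
#' profiled over the variance ratio `lambda = sigma2_e / sigma2_g`: a coarse
#' log-spaced grid locates the optimum, which is then refined with
#' [stats::optimize()]. Genotype BLUPs (conditional means of the random
#' effects) are returned as adjusted phenotypes for stage-2 genomic models.
#'
#' For an unreplicated trial (every line observed once) the two variance
#' components are not separable; the raw phenotypes, centered on the trial
#' mean, are passed through as the adjusted values and `H2` is `NA`.
#'
#' @param plots A data.frame with columns `line_id`, `replicate`, `value`
#'   (one trait). `replicate` may be omitted for unreplicated designs.
#' @return An object of class `trial_fit`: list with `sigma2_g`, `sigma2_e`,
#'   `H2`, `blups` (named per-line deviations), `mu`, `unreplicated`.
#' @export
fit_trial_model <- function(plots) {
  stopifnot(is.data.frame(plots), all(c("line_id", "value") %in% names(plots)))
  y <- plots$value
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  line <- factor(plots$line_id)
  if (nlevels(line) < 2L) stop("need at least 2 lines")
  if (stats::var(y) < .Machine$double.eps) {
    stop("all phenotype values identical: zero variance")
  }
  rep_f <- if ("replicate" %in% names(plots)) factor(plots$replicate)
           else factor(rep(1L, length(y)))
  unreplicated <- all(table(line) == 1L)
  if (unreplicated) {
    blups <- c(tapply(y, line, mean)) - mean(y)
    out <- list(sigma2_g = NA_real_, sigma2_e = NA_real_, H2 = NA_real_,
                blups = blups, mu = mean(y), unreplicated = TRUE)
    class(out) <- "trial_fit"
    return(out)
  }

  X <- stats::model.matrix(~rep_f)
  Z <- stats::model.matrix(~ line - 1L)
  n <- length(y)
  p <- qr(X)$rank
  ZZt <- tcrossprod(Z)

  # minus restricted log-likelihood profiled over lambda = s2e / s2g
  nrll <- function(log_lambda) {
    lam <- exp(log_lambda)
    H <- ZZt + diag(lam, n)
    ch <- chol(H)
    Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtHiX <- crossprod(X, Hi_X)
    b <- solve(XtHiX, crossprod(Hi_X, y))
    r <- y - X %*% b
    # y'Py reduces to (y - Xb)' H^{-1} (y - Xb) at the GLS solution
    Hi_r <- backsolve(ch, forwardsolve(t(ch), r))
    yPy <- sum(r * Hi_r)
    s2g <- yPy / (n - p)
    0.5 * ((n - p) * (1 + log(s2g)) + 2 * sum(log(diag(ch))) +
             determinant(XtHiX, logarithm = TRUE)$modulus[1L])
  }

  grid <- seq(log(1e-6), log(1e6), length.out = 41L)
  vals <- vapply(grid, nrll, numeric(1L))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(nrll, c(lo, hi))
  lam <- exp(opt$minimum)

  H <- ZZt + diag(lam, n)
  ch <- chol(H)
  Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
  b <- solve(crossprod(X, Hi_X), crossprod(Hi_X, y))
  r <- y - X %*% b
  Hi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2g <- sum(r * Hi_r) / (n - p)
  s2e <- lam * s2g
  blups <- drop(crossprod(Z, Hi_r))  # s2g * Z' V^{-1} r with V = s2g * H
  names(blups) <- levels(line)
  out <- list(sigma2_g = s2g, sigma2_e = s2e,
              H2 = broad_sense_h2(s2g, s2e),
              blups = blups, mu = mean(X %*% b), unreplicated = FALSE)
  class(out) <- "trial_fit"
  out
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("Single-trial mixed model fit\n")
  if (x$unreplicated) {
    cat("  unreplicated design: raw values passed through, H2 undefined\n")
  } else {
    cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, H2 = %.3f\n",
                x$sigma2_g, x$sigma2_e, x$H2))
  }
  cat("  lines:", length(x$blups), "\n")
  invisible(x)
}

#' Broad-sense heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e)` from single-trial variance
#' components.
#'
#' @param sigma2_g Genotypic variance (>= 0).
#' @param sigma2_e Residual variance (>= 0); not both zero.
#' @return Heritability in \[0, 1\].
#' @export
broad_sense_h2 <- function(sigma2_g, sigma2_e) {
  if (sigma2_g < 0 || sigma2_e < 0) stop("variance components must be >= 0")
  if (sigma2_g + sigma2_e == 0) stop("both variance components are zero")
  sigma2_g / (sigma2_g + sigma2_e)
}
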