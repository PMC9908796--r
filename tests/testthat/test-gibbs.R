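# Shared small instance: 10 lines x 2 environments = 20 cells, 2 masked.
small_instance <- function(seed = 101L) {
  set.seed(seed)
  n <- 10L
  G <- compute_grm(impute_and_standardize(
    simulate_genotypes(sim_config(n_lines = n, n_markers = 100L, seed = seed))))
  long <- expand.grid(line_id = rownames(G), env_id = c("e1", "e2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- drop(chol(G + diag(1e-6, n)) %*% rnorm(n))
  long$value <- g[match(long$line_id, rownames(G))] +
    rep(c(-1, 1), each = n) + rnorm(2L * n, 0, 0.5)
  long <- long[-c(3L, 15L), ]
  grid <- build_observation_grid(assemble_pheno_grid(long, trait = "t"))
  Om <- matrix(c(1, 0.3, 0.3, 1), 2L,
               dimnames = list(c("e1", "e2"), c("e1", "e2")))
  list(grid = grid, G = G, Om = Om)
}

test_that("with fixed variances the sampler reproduces the MME BLUP", {
  inst <- small_instance()
  kernels <- build_kernels(inst$grid, inst$G, inst$Om, "GEW")
  s2 <- c(g = 1, e = 1, w = 0.5)
  oracle <- oracle_mme_predict(inst$grid$y[inst$grid$observed],
                               which(inst$grid$observed),
                               kernels, s2, sigma2_eps = 0.25)
  preds <- sapply(1:3, function(s) {
    st <- mcmc_settings(n_iter = 4000L, burn_in = 1000L, thin = 2L, seed = s)
    gibbs_fit(inst$grid, kernels, st,
              fix_variances = c(s2, residual = 0.25))$predictions
  })
  expect_lt(max(abs(rowMeans(preds) - oracle)), 0.02)
})

test_that("kernel_blup agrees with the independent oracle formula", {
  inst <- small_instance(103L)
  kernels <- build_kernels(inst$grid, inst$G, inst$Om, "GE-GxE")
  s2 <- c(g = 0.8, e = 1.2, ge = 0.4)
  mine <- kernel_blup(inst$grid, kernels, s2, sigma2_eps = 0.3)
  oracle <- oracle_mme_predict(inst$grid$y[inst$grid$observed],
                               which(inst$grid$observed),
                               kernels, s2, sigma2_eps = 0.3)
  expect_equal(unname(mine$predictions), unname(oracle), tolerance = 1e-10)
})

test_that("identity-kernel fit partitions the variance of standardized data", {
  set.seed(111)
  n <- 80L
  long <- data.frame(line_id = sprintf("L%02d", 1:n), env_id = "e1",
                     value = as.numeric(scale(rnorm(n))))
  grid <- build_observation_grid(assemble_pheno_grid(long, trait = "t"))
  K <- diag(n)
  dimnames(K) <- NULL
  fit <- gibbs_fit(grid, list(g = K), fast_mcmc(5L))
  tot <- sum(fit$varcomp$post_mean)
  expect_lt(abs(tot - 1), 0.15)
})

test_that("single-kernel genomic fit is equivalent to ridge regression", {
  set.seed(121)
  cfg <- sim_config(n_lines = 30L, n_markers = 200L, seed = 121L)
  M <- simulate_genotypes(cfg)
  X <- impute_and_standardize(M)
  G <- compute_grm(X)
  y <- drop(X %*% rnorm(ncol(X), 0, 0.1)) + rnorm(30L, 0, 0.5)
  long <- data.frame(line_id = rownames(X), env_id = "e1", value = y)
  grid <- build_observation_grid(assemble_pheno_grid(long, trait = "t"))
  s2g <- 0.9; s2e <- 0.4
  # ridge regression in marker space: u = X (X'X + p*lambda I)^-1 X' yc
  p <- ncol(X)
  yc <- y - mean(y)
  u_ridge <- drop(X %*% solve(crossprod(X) + diag(p * s2e / s2g, p),
                              crossprod(X, yc)))
  st <- mcmc_settings(n_iter = 6000L, burn_in = 1000L, thin = 2L, seed = 9L)
  fit <- gibbs_fit(grid, build_kernels(grid, G, model = "G"), st,
                   fix_variances = c(g = s2g, residual = s2e))
  # compare centered genetic predictions; mu handling differs only by
  # the GLS vs simple mean, both near mean(y) here
  expect_lt(max(abs((fit$predictions - mean(fit$predictions)) -
                      (u_ridge - mean(u_ridge)))), 0.03)
})

test_that("degenerate constant phenotypes are fitted as constants", {
  n <- 15L
  long <- data.frame(line_id = sprintf("L%02d", 1:n), env_id = "e1",
                     value = 7)
  grid <- build_observation_grid(assemble_pheno_grid(long, trait = "t"))
  K <- diag(n)
  fit <- suppressWarnings(gibbs_fit(grid, list(g = K), fast_mcmc(3L)))
  expect_lt(max(abs(fit$predictions - 7)), 0.01)
  expect_lt(max(fit$varcomp$post_mean), 1e-4)
})

test_that("variance recovery in the genotype-plus-environment regime", {
  # Data generated under g + e + noise and fitted with the matching GE
  # model: every component is identified and should land near its target.
  targets <- c(g = 1, e = 3, eps = 0.5)
  est <- sapply(c(201L, 202L), function(seed) {
    sim <- small_sim(seed = seed, n_envs = 10L, ec_noise = 1,
                     n_lines = 80L, n_markers = 300L,
                     variances = c(g = 1, e = 3, w = 0, ge = 0, gw = 0,
                                   eps = 0.5))
    grid <- build_observation_grid(sim$data$pheno)
    kk <- build_kernels(grid, sim$data$G, sim$data$Omega, "GE")
    fit <- suppressWarnings(gibbs_fit(grid, kk, fast_mcmc(seed)))
    setNames(fit$varcomp$post_mean,
             sub("residual", "eps", fit$varcomp$term))[names(targets)]
  })
  rel_err <- abs(rowMeans(est) - targets) / targets
  expect_lt(max(rel_err), 0.30)
})

test_that("genomic and residual variances recover under the full GEW model", {
  # The environment-level split between the e and w kernels is only weakly
  # identified with few environments (both act on the same environment
  # space), but the genomic and residual components stay well determined.
  sim <- small_sim(seed = 205L, n_envs = 10L, n_ecs = 8L, ec_noise = 1,
                   n_lines = 80L, n_markers = 300L,
                   variances = c(g = 1, e = 2, w = 1, ge = 0, gw = 0,
                                 eps = 0.5))
  grid <- build_observation_grid(sim$data$pheno)
  kk <- build_kernels(grid, sim$data$G, sim$data$Omega, "GEW")
  fit <- suppressWarnings(gibbs_fit(grid, kk, fast_mcmc(205L)))
  est <- setNames(fit$varcomp$post_mean, fit$varcomp$term)
  expect_lt(abs(est[["g"]] - 1), 0.30)
  expect_lt(abs(est[["residual"]] - 0.5) / 0.5, 0.30)
})

test_that("chain-length doubling barely moves the posterior predictions", {
  inst <- small_instance(131L)
  kernels <- build_kernels(inst$grid, inst$G, inst$Om, "GE")
  st1 <- mcmc_settings(n_iter = 6000L, burn_in = 1000L, thin = 2L, seed = 3L)
  st2 <- mcmc_settings(n_iter = 12000L, burn_in = 1000L, thin = 2L, seed = 4L)
  f1 <- gibbs_fit(inst$grid, kernels, st1)
  f2 <- gibbs_fit(inst$grid, kernels, st2)
  expect_lt(max(abs(f1$predictions - f2$predictions)), 0.05)
})

test_that("genomic heritability is the posterior variance ratio", {
  inst <- small_instance(141L)
  kernels <- build_kernels(inst$grid, inst$G, model = "G")
  fit <- gibbs_fit(inst$grid, kernels, fast_mcmc(7L))
  s2g <- fit$varcomp$post_mean[fit$varcomp$term == "g"]
  s2r <- fit$varcomp$post_mean[fit$varcomp$term == "residual"]
  expect_equal(genomic_h2(fit), s2g / (s2g + s2r), tolerance = 1e-12)
  expect_equal(genomic_h2(fit), fit$h2_g, tolerance = 1e-12)
  expect_true(fit$h2_g >= 0 && fit$h2_g <= 1)

  fit_e <- gibbs_fit(inst$grid,
                     build_kernels(inst$grid, inst$G, inst$Om, "GE")["e"],
                     fast_mcmc(8L))
  expect_error(genomic_h2(fit_e), "no genomic")
})

test_that("non-PSD kernels are refused", {
  inst <- small_instance(151L)
  bad <- diag(inst$grid$n_cells)
  bad[1L, 2L] <- bad[2L, 1L] <- 2
  expect_error(gibbs_fit(inst$grid, list(g = bad), fast_mcmc()),
               "not positive semi-definite")
})
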