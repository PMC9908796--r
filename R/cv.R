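#' Bundle the inputs of a multi-environment genomic prediction analysis
#'
#' @param pheno A `pheno_grid` of adjusted phenotypes.
#' @param G Genomic relationship matrix covering the grid's lines.
#' @param W Standardized EC matrix (environments x covariates); optional,
#'   needed for covariate models and the covariate-selected CV design.
#' @param Omega Environmental kernel; computed as [build_omega()] of `W`
#'   when `W` is given and `Omega` is not.
#' @return A list of class `gp_data`.
#' @export
gp_data <- function(pheno, G, W = NULL, Omega = NULL) {
  stopifnot(inherits(pheno, "pheno_grid"))
  missing_lines <- setdiff(pheno$line_ids, rownames(G))
  if (length(missing_lines) > 0L) {
    stop("line(s) missing from G: ",
         paste(utils::head(missing_lines, 3L), collapse = ", "))
  }
  if (is.null(Omega) && !is.null(W)) Omega <- build_omega(W)
  structure(list(pheno = pheno, G = G, W = W, Omega = Omega),
            class = "gp_data")
}

#' Predictive ability
#'
#' Pearson correlation between predicted values and adjusted phenotypes in a
#' validation set. Sign is preserved; negative abilities are meaningful and
#' reported as such.
#'
#' @param predicted,observed Paired numeric vectors (>= 3 pairs).
#' @return Correlation in \[-1, 1\], or `NA` with a warning if either vector
#'   is constant.
#' @export
predictive_ability <- function(predicted, observed) {
  ok <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[ok]
  observed <- observed[ok]
  if (length(predicted) < 3L) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant vector: predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(predicted, observed)
}

# Predictive ability that degrades to NA (with warning) instead of
# erroring when an assembled validation set is too small.
.safe_pa <- function(predicted, observed) {
  ok <- is.finite(predicted) & is.finite(observed)
  if (sum(ok) < 3L) {
    warning("fewer than 3 validation pairs: predictive ability undefined")
    return(NA_real_)
  }
  predictive_ability(predicted, observed)
}

# Deterministic per-run seed from a master seed and run indices (< 2^31).
.derive_seed <- function(master, i, j = 0L) {
  as.integer((as.numeric(master) * 1009 + i * 7919 + j * 104729) %% 2147483629)
}

# Fit one model on training environments and predict a masked target.
.fit_predict_env <- function(data, model, train_envs, target_env, settings) {
  grid <- build_observation_grid(data$pheno)
  sub <- subset_grid(grid, envs = c(train_envs, target_env),
                     mask_envs = target_env)
  kernels <- build_kernels(sub, data$G, data$Omega, model)
  fit <- gibbs_fit(sub, kernels, settings)
  preds <- predict_new_environment(fit, target_env)
  truth_col <- data$pheno$values[, target_env]
  truth <- truth_col[data$pheno$mask[, target_env]]
  list(r = predictive_ability(preds[names(truth)], truth), fit = fit,
       predictions = preds)
}

.cv_row <- function(data, scheme, model, target, replicate, r, train_envs) {
  data.frame(trait = data$pheno$trait, scheme = scheme, model = model,
             target = target, replicate = replicate, r = r,
             training_envs = paste(train_envs, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Cross-validation with random training environments
#'
#' For every target environment, repeatedly (default 50 replicates) samples
#' `n_train` training environments (default 4) uniformly without replacement
#' from the remaining ones, fits each model on the training cells only, and
#' computes the predictive ability in the fully masked target environment.
#' Replicate-level seeds are derived deterministically from `seed` so each
#' run is independently reproducible.
#'
#' @param data A `gp_data` bundle.
#' @param models Character vector of model labels (see [model_terms()]).
#' @param n_train Training-set size (default 4).
#' @param n_rep Number of replicates per target (default 50).
#' @param settings Sampler settings template ([mcmc_settings()]); the seed
#'   field is overridden per replicate.
#' @param seed Master seed for the environment sampling and sampler seeds.
#' @return data.frame with one row per trait x model x target x replicate:
#'   `trait`, `scheme`, `model`, `target`, `replicate`, `r`,
#'   `training_envs`.
#' @export
run_cv_ran <- function(data, models, n_train = 4L, n_rep = 50L,
                       settings = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(data, "gp_data"))
  envs <- data$pheno$env_ids
  if (length(envs) < n_train + 1L) {
    stop("need at least ", n_train + 1L, " environments for CV with ",
         n_train, " training environments")
  }
  out <- list()
  for (ti in seq_along(envs)) {
    target <- envs[ti]
    others <- setdiff(envs, target)
    for (rep_i in seq_len(n_rep)) {
      rs <- .derive_seed(seed, ti, rep_i)
      set.seed(rs)
      train <- sort(sample(others, n_train))
      for (model in models) {
        st <- settings
        st$seed <- rs
        res <- .fit_predict_env(data, model, train, target, st)
        out[[length(out) + 1L]] <-
          .cv_row(data, "CV-RAN", model, target, rep_i, res$r, train)
      }
    }
  }
  do.call(rbind, out)
}

#' Cross-validation with covariate-selected training environments
#'
#' For every target environment, the training set is the `k` environments
#' nearest in standardized EC space ([select_training_envs()]); the
#' prediction is performed once per target.
#'
#' @inheritParams run_cv_ran
#' @param k Training-set size (default 4).
#' @param W EC matrix used for the distance; defaults to the bundle's `W`,
#'   restricted to whole-season (`_WS`) columns when present.
#' @return data.frame as in [run_cv_ran()] with `scheme = "CV-SEL"`.
#' @export
run_cv_sel <- function(data, models, k = 4L, W = NULL,
                       settings = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(data, "gp_data"))
  if (is.null(W)) W <- data$W
  if (is.null(W)) stop("EC matrix W required for covariate-selected CV")
  ws <- grep("_WS$", colnames(W))
  if (length(ws) > 0L) W <- W[, ws, drop = FALSE]
  envs <- data$pheno$env_ids
  out <- list()
  for (ti in seq_along(envs)) {
    target <- envs[ti]
    train <- select_training_envs(target, W, k)
    for (model in models) {
      st <- settings
      st$seed <- .derive_seed(seed, ti)
      res <- .fit_predict_env(data, model, train, target, st)
      out[[length(out) + 1L]] <-
        .cv_row(data, "CV-SEL", model, target, 1L, res$r, train)
    }
  }
  do.call(rbind, out)
}

#' Leave-one-environment-out cross-validation
#'
#' Each environment is predicted from the cells of all remaining
#' environments.
#'
#' @inheritParams run_cv_ran
#' @return data.frame as in [run_cv_ran()] with `scheme = "CV-LOEO"`.
#' @export
run_cv_loeo <- function(data, models, settings = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(data, "gp_data"))
  envs <- data$pheno$env_ids
  if (length(envs) < 3L) stop("need at least 3 environments")
  out <- list()
  for (ti in seq_along(envs)) {
    target <- envs[ti]
    train <- setdiff(envs, target)
    for (model in models) {
      st <- settings
      st$seed <- .derive_seed(seed, ti)
      res <- .fit_predict_env(data, model, train, target, st)
      out[[length(out) + 1L]] <-
        .cv_row(data, "CV-LOEO", model, target, 1L, res$r, train)
    }
  }
  do.call(rbind, out)
}

#' Leave-one-line-out cross-validation for untested lines
#'
#' Each eligible line (observed in every environment) is masked everywhere
#' in turn; models are trained on all remaining cells and the line is
#' predicted across environments. Predictive ability is reported at the
#' line level (per line, across environments) and at the environment level
#' (per environment, across the assembled left-out predictions of all
#' lines).
#'
#' @inheritParams run_cv_ran
#' @param lines Lines to sweep (default: all lines observed everywhere);
#'   lines not fully observed are excluded with a warning.
#' @return List with `line_level` and `env_level` data.frames (`trait`,
#'   `scheme`, `model`, `target`, `r`) and `predictions` (long data.frame of
#'   left-out predictions).
#' @export
run_cv_lines <- function(data, models, lines = NULL,
                         settings = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(data, "gp_data"))
  eligible <- common_lines(data$pheno)
  if (is.null(lines)) lines <- eligible
  bad <- setdiff(lines, eligible)
  if (length(bad) > 0L) {
    warning("excluding line(s) not observed in all environments: ",
            paste(utils::head(bad, 5L), collapse = ", "))
    lines <- intersect(lines, eligible)
  }
  if (length(lines) < 1L) stop("no eligible lines")
  grid <- build_observation_grid(data$pheno)
  preds <- list()
  for (li in seq_along(lines)) {
    line <- lines[li]
    sub <- subset_grid(grid, mask_lines = line)
    for (model in models) {
      st <- settings
      st$seed <- .derive_seed(seed, li)
      kernels <- build_kernels(sub, data$G, data$Omega, model)
      fit <- gibbs_fit(sub, kernels, st)
      idx <- which(sub$cells$line_id == line)
      preds[[length(preds) + 1L]] <- data.frame(
        model = model, line_id = line, env_id = sub$cells$env_id[idx],
        predicted = fit$predictions[idx],
        observed = data$pheno$values[line, sub$cells$env_id[idx]],
        stringsAsFactors = FALSE
      )
    }
  }
  preds <- do.call(rbind, preds)
  line_level <- env_level <- list()
  for (model in models) {
    pm <- preds[preds$model == model, , drop = FALSE]
    for (line in lines) {
      p <- pm[pm$line_id == line, , drop = FALSE]
      line_level[[length(line_level) + 1L]] <-
        .cv_row(data, "LOO-LINES", model, line, 1L,
                .safe_pa(p$predicted, p$observed), character(0))
    }
    for (env in data$pheno$env_ids) {
      p <- pm[pm$env_id == env, , drop = FALSE]
      env_level[[length(env_level) + 1L]] <-
        .cv_row(data, "LOO-LINES", model, env, 1L,
                .safe_pa(p$predicted, p$observed), character(0))
    }
  }
  list(line_level = do.call(rbind, line_level),
       env_level = do.call(rbind, env_level),
       predictions = preds)
}
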