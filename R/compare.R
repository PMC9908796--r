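#' Fisher z-transformation of a correlation
#'
#' `Z = 0.5 * (log(1 + r) - log(1 - r))`, the variance-stabilizing
#' transform used to compare predictive abilities across models; the
#' inverse is the hyperbolic tangent. Correlations at or beyond +-1 are
#' clamped to `+-(1 - 1e-6)` with a warning.
#'
#' @param r Correlation(s) in \[-1, 1\].
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clamped to 1 - 1e-6 before z-transform")
    r <- pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6)
  }
  0.5 * (log(1 + r) - log(1 - r))
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

# Compact letter display from a logical "significantly different" matrix
# (insert-and-absorb): start from one all-model group, split on each
# significant pair, drop subset groups, assign letters by group mean.
.letter_display <- function(sig, means) {
  models <- rownames(sig)
  groups <- list(models)
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (j <= i || !isTRUE(sig[i, j])) next
      new_groups <- list()
      for (g in groups) {
        if (all(c(models[i], models[j]) %in% g)) {
          new_groups <- c(new_groups, list(setdiff(g, models[i])),
                          list(setdiff(g, models[j])))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a != b && keep[b] &&
              all(new_groups[[a]] %in% new_groups[[b]]) &&
              (length(new_groups[[a]]) < length(new_groups[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      groups <- new_groups[keep]
    }
  }
  ord <- order(vapply(groups, function(g) -max(means[g]), numeric(1L)))
  groups <- groups[ord]
  letters_out <- stats::setNames(rep("", length(models)), models)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) {
      letters_out[m] <- paste0(letters_out[m], letters[gi])
    }
  }
  letters_out
}

#' Compare models by ANOVA and Tukey tests on z-transformed abilities
#'
#' For one target environment and trait with replicated cross-validation
#' results, z-transforms the per-replicate predictive abilities, runs a
#' one-way ANOVA with model as the factor, Tukey honest-significant-
#' difference pairwise tests at `alpha`, and summarizes the grouping as a
#' compact letter display (models sharing a letter are not significantly
#' different). Model means are back-transformed to the correlation scale.
#'
#' @param cv data.frame of CV results (as returned by [run_cv_ran()]) for a
#'   single target and trait, with >= 2 models and >= 2 replicates each.
#' @param alpha Significance level (default 0.05).
#' @return List with `summary` (data.frame: model, n, mean_z, mean_r,
#'   letters), `anova` (F statistic, df, p value) and `tukey` (pairwise
#'   table from [stats::TukeyHSD()]).
#' @export
compare_models <- function(cv, alpha = 0.05) {
  stopifnot(is.data.frame(cv), all(c("model", "r") %in% names(cv)))
  if (length(unique(cv$target)) > 1L || length(unique(cv$trait)) > 1L) {
    stop("compare_models expects a single target environment and trait; ",
         "split the results first")
  }
  if (length(unique(cv$model)) < 2L) stop("need at least 2 models")
  if (min(table(cv$model)) < 2L) {
    stop("need at least 2 replicates per model for a within-group variance")
  }
  z <- fisher_z(cv$r)
  model <- factor(cv$model)
  fit <- stats::aov(z ~ model, data = data.frame(z = z, model = model))
  at <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  mods <- levels(model)
  sig <- matrix(FALSE, length(mods), length(mods),
                dimnames = list(mods, mods))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (pi in seq_along(pairs)) {
    a <- pairs[[pi]][1L]
    b <- pairs[[pi]][2L]
    sig[a, b] <- sig[b, a] <- tk[pi, "p adj"] < alpha
  }
  mean_z <- tapply(z, model, mean)
  lett <- .letter_display(sig, mean_z)
  summary_df <- data.frame(
    model = mods,
    n = as.integer(table(model)),
    mean_z = as.numeric(mean_z),
    mean_r = fisher_z_inv(as.numeric(mean_z)),
    letters = lett[mods],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(summary = summary_df[order(-summary_df$mean_z), ],
       anova = list(f = at[["F value"]][1L], df = at[["Df"]],
                    p = at[["Pr(>F)"]][1L]),
       tukey = tk)
}
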