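#' Assemble a line x environment phenotype grid
#'
#' Binds per-trial adjusted phenotypes (stage-1 BLUPs, or raw values for
#' unreplicated trials) into a sparse line x environment grid for one trait.
#' An environment is a location x year x season combination; cells without an
#' observation are masked and later serve as prediction slots.
#'
#' @param long A data.frame with columns `line_id`, `env_id`, `value`, and
#'   optionally `trait` (a single trait).
#' @param trait Trait label to attach (taken from `long$trait` if present).
#' @return An object of class `pheno_grid`: list with `values` (lines x
#'   environments numeric matrix, `NA` where masked), `mask` (logical matrix,
#'   `TRUE` = observed), `line_ids`, `env_ids`, `trait`.
#' @export
assemble_pheno_grid <- function(long, trait = NULL) {
  stopifnot(is.data.frame(long),
            all(c("line_id", "env_id", "value") %in% names(long)))
  if (is.null(trait)) {
    trait <- if ("trait" %in% names(long)) {
      tr <- unique(long$trait)
      if (length(tr) > 1L) stop("multiple traits in input; subset first")
      tr
    } else "trait"
  }
  key <- paste(long$line_id, long$env_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (line, environment) record: ", d$line_id, " / ", d$env_id)
  }
  line_ids <- sort(unique(as.character(long$line_id)))
  env_ids <- sort(unique(as.character(long$env_id)))
  values <- matrix(NA_real_, length(line_ids), length(env_ids),
                   dimnames = list(line_ids, env_ids))
  values[cbind(match(long$line_id, line_ids),
               match(long$env_id, env_ids))] <- long$value
  mask <- !is.na(values)
  if (any(colSums(mask) == 0L)) stop("environment with zero observations")
  structure(list(values = values, mask = mask, line_ids = line_ids,
                 env_ids = env_ids, trait = trait),
            class = "pheno_grid")
}

#' @export
print.pheno_grid <- function(x, ...) {
  cat(sprintf("Phenotype grid [%s]: %d lines x %d environments, %d/%d cells observed\n",
              x$trait, length(x$line_ids), length(x$env_ids),
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Convert a phenotype grid to long format
#'
#' @param grid A `pheno_grid`.
#' @param observed_only Drop masked cells (default `TRUE`).
#' @return data.frame with `line_id`, `env_id`, `trait`, `value`.
#' @export
pheno_grid_to_long <- function(grid, observed_only = TRUE) {
  stopifnot(inherits(grid, "pheno_grid"))
  df <- expand.grid(line_id = grid$line_ids, env_id = grid$env_ids,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$trait <- grid$trait
  df$value <- as.vector(grid$values)
  if (observed_only) df <- df[as.vector(grid$mask), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Lines observed in every environment
#'
#' @param grid A `pheno_grid`.
#' @return Character vector of line ids with no masked cell.
#' @export
common_lines <- function(grid) {
  stopifnot(inherits(grid, "pheno_grid"))
  grid$line_ids[rowSums(grid$mask) == length(grid$env_ids)]
}

#' Between-environment phenotypic correlations
#'
#' Pairwise-complete Pearson correlations between environment columns of the
#' grid. Pairs sharing fewer than `min_overlap` lines are reported as `NA`
#' (undefined) since a correlation on a handful of shared lines is not
#' interpretable.
#'
#' @param grid A `pheno_grid`.
#' @param min_overlap Minimum number of shared observed lines per pair
#'   (>= 3; default 10).
#' @return List with `r` (environment x environment correlation matrix, unit
#'   diagonal), `n_overlap` (shared-line counts), `env_ids`.
#' @export
env_correlation <- function(grid, min_overlap = 10L) {
  stopifnot(inherits(grid, "pheno_grid"))
  if (min_overlap < 3L) stop("min_overlap must be >= 3")
  V <- grid$values
  n_overlap <- crossprod(grid$mask * 1L)
  r <- suppressWarnings(stats::cor(V, use = "pairwise.complete.obs"))
  r[n_overlap < min_overlap] <- NA_real_
  diag(r) <- 1
  list(r = r, n_overlap = n_overlap, env_ids = grid$env_ids)
}

#' Summarize between-environment correlations
#'
#' Off-diagonal summary used to characterize the consistency of a trait
#' across environments: number of environment pairs, fraction of defined
#' pairwise correlations above a threshold, and the range.
#'
#' @param ec Result of [env_correlation()].
#' @param threshold Correlation threshold for the exceedance fraction.
#' @return List with `n_pairs`, `n_defined`, `fraction_above`, `min`, `max`.
#' @export
summarize_env_correlation <- function(ec, threshold = 0.5) {
  r <- ec$r[upper.tri(ec$r)]
  def <- r[!is.na(r)]
  list(n_pairs = length(r), n_defined = length(def),
       fraction_above = mean(def > threshold),
       min = min(def), max = max(def))
}

#' Two-way genotype x environment analysis of variance
#'
#' Standard two-way ANOVA decomposition of phenotypes into genotype,
#' environment and interaction effects, on plot-level (replicated) or
#' cell-level data restricted to lines observed in all environments. With a
#' single observation per cell the interaction is confounded with the
#' residual, so its F test is unavailable and flagged.
#'
#' @param long data.frame with `line_id`, `env_id`, `value` (one or more
#'   observations per line x environment cell).
#' @return List with `table` (data.frame: term, df, sum_sq, mean_sq,
#'   f_value, p_value) and `interaction_testable`.
#' @export
gxe_anova <- function(long) {
  stopifnot(is.data.frame(long),
            all(c("line_id", "env_id", "value") %in% names(long)))
  g <- factor(long$line_id)
  e <- factor(long$env_id)
  if (nlevels(g) < 2L || nlevels(e) < 2L) {
    stop("need at least 2 genotypes and 2 environments")
  }
  cells <- table(g, e)
  if (any(cells == 0L)) {
    stop("empty line x environment cells; subset to lines observed in all ",
         "environments (see common_lines)")
  }
  replicated <- any(cells > 1L)
  if (replicated) {
    fit <- stats::aov(value ~ g * e, data = data.frame(value = long$value, g, e))
    tab <- summary(fit)[[1L]]
    terms <- c("genotype", "environment", "genotype:environment", "residual")
  } else {
    fit <- stats::aov(value ~ g + e, data = data.frame(value = long$value, g, e))
    tab <- summary(fit)[[1L]]
    terms <- c("genotype", "environment", "genotype:environment")
    # one observation per cell: residual row IS the interaction
  }
  out <- data.frame(
    term = terms,
    df = tab[["Df"]],
    sum_sq = tab[["Sum Sq"]],
    mean_sq = tab[["Mean Sq"]],
    f_value = tab[["F value"]],
    p_value = tab[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  if (!replicated) {
    out$f_value[out$term == "genotype:environment"] <- NA_real_
    out$p_value[out$term == "genotype:environment"] <- NA_real_
  }
  list(table = out, interaction_testable = replicated)
}

#' Cluster environments by phenotypic correlation
#'
#' Agglomerative hierarchical clustering of environments with distance
#' `d = 1 - r` on the between-environment correlation matrix and average
#' linkage. Leaf order is made deterministic by labeling order.
#'
#' @param ec Result of [env_correlation()]; all off-diagonal entries must be
#'   defined.
#' @return An [stats::hclust] tree.
#' @export
cluster_environments_pheno <- function(ec) {
  r <- ec$r
  und <- which(is.na(r) & upper.tri(r), arr.ind = TRUE)
  if (nrow(und) > 0L) {
    stop("undefined correlation for pair(s): ",
         paste(paste(rownames(r)[und[, 1L]], colnames(r)[und[, 2L]],
                     sep = " / "), collapse = "; "))
  }
  d <- stats::as.dist(1 - r)
  stats::hclust(d, method = "average")
}
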