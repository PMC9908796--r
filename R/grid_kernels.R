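.MODEL_TERMS <- list(
  "G"              = c("g"),
  "GE"             = c("g", "e"),
  "GW"             = c("g", "w"),
  "GEW"            = c("g", "e", "w"),
  "GE-GxE"         = c("g", "e", "ge"),
  "GW-GxW"         = c("g", "w", "gw"),
  "GEW-GxE-GxW"    = c("g", "e", "w", "ge", "gw")
)

#' Random-effect terms of a multi-environment model
#'
#' Maps a model label to its random-effect term list: `g` (genomic main
#' effect), `e` (environment main effect), `w` (environmental-covariate
#' effect), `ge` and `gw` (their interactions with `g`).
#'
#' @param model One of `"G"`, `"GE"`, `"GW"`, `"GEW"`, `"GE-GxE"`,
#'   `"GW-GxW"`, `"GEW-GxE-GxW"`.
#' @return Character vector of term codes.
#' @export
model_terms <- function(model) {
  if (!model %in% names(.MODEL_TERMS)) {
    stop("unknown model '", model, "'; expected one of ",
         paste(names(.MODEL_TERMS), collapse = ", "))
  }
  .MODEL_TERMS[[model]]
}

#' Build the observation grid over line x environment cells
#'
#' Lays out every line x environment cell in a fixed environment-major order
#' (all lines of the first environment, then all lines of the second, ...),
#' copying observed phenotypes and keeping masked cells as prediction slots.
#' The fixed order makes the kernel block structure inspectable: same-
#' environment blocks are contiguous.
#'
#' @param pheno A `pheno_grid`.
#' @return An object of class `obs_grid`: list with `cells` (data.frame
#'   `line_id`, `env_id`), `y` (length-N numeric, `NA` at masked cells),
#'   `observed` (logical), `line_ids`, `env_ids`, `n_cells`.
#' @export
build_observation_grid <- function(pheno) {
  stopifnot(inherits(pheno, "pheno_grid"))
  cells <- expand.grid(line_id = pheno$line_ids, env_id = pheno$env_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies line fastest => environment-major blocks
  y <- as.vector(pheno$values)
  observed <- as.vector(pheno$mask)
  structure(list(cells = cells, y = y, observed = observed,
                 line_ids = pheno$line_ids, env_ids = pheno$env_ids,
                 n_cells = nrow(cells)),
            class = "obs_grid")
}

#' @export
print.obs_grid <- function(x, ...) {
  cat("Observation grid:", x$n_cells, "cells (",
      length(x$line_ids), "lines x", length(x$env_ids), "environments ),",
      sum(x$observed), "observed\n")
  invisible(x)
}

#' Restrict an observation grid to a subset of environments or lines
#'
#' Keeps the environment-major cell layout; used by the cross-validation
#' drivers to fit on training environments plus the (masked) target.
#'
#' @param grid An `obs_grid`.
#' @param envs Environments to keep (default all).
#' @param mask_envs Environments whose cells are forced to masked
#'   (phenotypes hidden but cells retained for prediction).
#' @param mask_lines Lines whose cells are forced to masked.
#' @return A new `obs_grid`.
#' @export
subset_grid <- function(grid, envs = NULL, mask_envs = character(0),
                        mask_lines = character(0)) {
  stopifnot(inherits(grid, "obs_grid"))
  if (is.null(envs)) envs <- grid$env_ids
  keep <- grid$cells$env_id %in% envs
  cells <- grid$cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  y <- grid$y[keep]
  observed <- grid$observed[keep]
  hide <- cells$env_id %in% mask_envs | cells$line_id %in% mask_lines
  y[hide] <- NA_real_
  observed[hide] <- FALSE
  structure(list(cells = cells, y = y, observed = observed,
                 line_ids = grid$line_ids,
                 env_ids = grid$env_ids[grid$env_ids %in% envs],
                 n_cells = nrow(cells)),
            class = "obs_grid")
}

#' Build the random-effect kernels of a multi-environment model
#'
#' Expands line-level and environment-level relationship matrices to the
#' cell level and forms the model's covariance kernels:
#' `K_g = Z_g G Z_g'` (genomic), `K_e = Z_e Z_e'` (environment identity),
#' `K_w = Z_e Omega Z_e'` (environmental covariates), and the Hadamard
#' (elementwise) interaction kernels `K_ge = K_g o K_e` and
#' `K_gw = K_g o K_w`. With the environment-major cell order, `K_ge` is
#' block-diagonal with one `G` block per environment.
#'
#' @param grid An `obs_grid`.
#' @param G Genomic relationship matrix covering every line in the grid.
#' @param Omega Environmental kernel covering every environment (required
#'   only when the model has `w` or `gw` terms).
#' @param model Model label (see [model_terms()]).
#' @return Named list of cell x cell kernel matrices, one per random term.
#' @export
build_kernels <- function(grid, G, Omega = NULL, model = "GEW-GxE-GxW") {
  stopifnot(inherits(grid, "obs_grid"))
  terms <- model_terms(model)
  li <- match(grid$cells$line_id, rownames(G))
  if (anyNA(li)) {
    stop("line(s) missing from G: ",
         paste(utils::head(unique(grid$cells$line_id[is.na(li)]), 3L),
               collapse = ", "))
  }
  ei_lab <- grid$cells$env_id
  kernels <- list()
  Kg <- G[li, li]
  if ("g" %in% terms) kernels$g <- Kg
  if (any(c("e", "ge") %in% terms)) {
    Ke <- outer(ei_lab, ei_lab, "==") * 1
    if ("e" %in% terms) kernels$e <- Ke
    if ("ge" %in% terms) kernels$ge <- Kg * Ke
  }
  if (any(c("w", "gw") %in% terms)) {
    if (is.null(Omega)) stop("Omega required for model ", model)
    oi <- match(ei_lab, rownames(Omega))
    if (anyNA(oi)) {
      stop("environment(s) missing from Omega: ",
           paste(utils::head(unique(ei_lab[is.na(oi)]), 3L), collapse = ", "))
    }
    Kw <- Omega[oi, oi]
    if ("w" %in% terms) kernels$w <- Kw
    if ("gw" %in% terms) kernels$gw <- Kg * Kw
  }
  kernels[terms]
}
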