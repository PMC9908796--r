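#' Standardize an environment x covariate table
#'
#' Centers and scales every covariate column to mean zero and unit sample
#' standard deviation across environments, producing the `W` matrix of the
#' environmental kernel `Omega = W W' / q`. Constant columns carry no
#' between-environment information and are dropped with a warning.
#'
#' @param raw Numeric matrix or data.frame, environments x covariates, with
#'   environment ids as rownames.
#' @return An object of class `ec_matrix`: the standardized matrix `W` with
#'   `env_ids` rownames and covariate ids as colnames.
#' @export
standardize_ecs <- function(raw) {
  W <- as.matrix(raw)
  if (nrow(W) < 3L) stop("need at least 3 environments to standardize ECs")
  if (is.null(rownames(W))) stop("environment ids required as rownames")
  s <- apply(W, 2L, stats::sd)
  const <- s < .Machine$double.eps^0.5
  if (any(const)) {
    warning("dropping constant EC column(s): ",
            paste(colnames(W)[const], collapse = ", "))
    W <- W[, !const, drop = FALSE]
    s <- s[!const]
  }
  if (ncol(W) == 0L) stop("no non-constant EC columns left")
  W <- sweep(W, 2L, colMeans(W), "-")
  W <- sweep(W, 2L, s, "/")
  class(W) <- c("ec_matrix", class(W))
  W
}

#' Environmental relationship kernel
#'
#' `Omega = W W' / q`, the environment x environment covariance kernel built
#' from the standardized covariate matrix `W` with `q` columns. The division
#' by `q` fixes the "proportional to WW'" constant so that the kernel
#' diagonal is near one, on the same scale as the genomic relationship
#' matrix.
#'
#' @param W Standardized EC matrix from [standardize_ecs()].
#' @return Symmetric positive semi-definite environments x environments
#'   matrix.
#' @export
build_omega <- function(W) {
  W <- unclass(as.matrix(W))
  if (ncol(W) == 0L) stop("W has no covariate columns")
  Om <- tcrossprod(W) / ncol(W)
  (Om + t(Om)) / 2
}

#' Cluster environments by environmental covariates
#'
#' Hierarchical clustering of environments on Euclidean distance over the
#' standardized EC columns of a given phenology phase (or all), with average
#' linkage.
#'
#' @param W Standardized EC matrix with columns named `<covariate>_<phase>`.
#' @param phase One of `"WS"` (whole season), `"VE"`, `"RE"`, `"RI"`, or
#'   `"all"`.
#' @return An [stats::hclust] tree over environments.
#' @export
cluster_environments_ec <- function(W, phase = "all") {
  W <- unclass(as.matrix(W))
  cols <- .phase_columns(W, phase)
  stats::hclust(stats::dist(W[, cols, drop = FALSE]), method = "average")
}

.phase_columns <- function(W, phase) {
  valid <- c("WS", "VE", "RE", "RI", "all")
  if (!phase %in% valid) {
    stop("unknown phase '", phase, "'; expected one of ",
         paste(valid, collapse = ", "))
  }
  if (phase == "all") return(seq_len(ncol(W)))
  cols <- grep(paste0("_", phase, "$"), colnames(W))
  if (length(cols) == 0L) stop("no EC columns for phase ", phase)
  cols
}

#' Select training environments nearest to a target
#'
#' Ranks candidate environments by Euclidean distance to the target in
#' standardized EC space and returns the `k` nearest, ascending by distance
#' with lexicographic tie-breaking. This is the training-set construction of
#' the covariate-selected cross-validation design (default `k = 4`).
#'
#' @param target_env Target environment id (a row of `W`).
#' @param W Standardized EC matrix (use whole-season columns upstream if
#'   desired).
#' @param k Number of environments to select.
#' @return Character vector of `k` environment ids, nearest first.
#' @export
select_training_envs <- function(target_env, W, k = 4L) {
  W <- unclass(as.matrix(W))
  if (k <= 0L) stop("k must be positive")
  if (!target_env %in% rownames(W)) {
    stop("target environment '", target_env, "' not in EC matrix")
  }
  others <- setdiff(rownames(W), target_env)
  if (k > length(others)) stop("k exceeds the number of candidate environments")
  d <- sqrt(colSums((t(W[others, , drop = FALSE]) - W[target_env, ])^2))
  others[order(d, others)][seq_len(k)]
}

#' Read / write an EC table in long format
#'
#' Delimited long-format exchange: columns `env_id`, `covariate`, `phase`,
#' `value`; one row per environment x covariate x phase.
#'
#' @param path File path.
#' @return `read_ec_table`: a wide numeric matrix (environments x
#'   `<covariate>_<phase>` columns). `write_ec_table`: `path`, invisibly.
#' @export
read_ec_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("env_id", "covariate", "phase", "value") %in% names(df)))
  col <- paste0(df$covariate, "_", df$phase)
  envs <- unique(df$env_id)
  cols <- unique(col)
  W <- matrix(NA_real_, length(envs), length(cols),
              dimnames = list(envs, cols))
  W[cbind(match(df$env_id, envs), match(col, cols))] <- df$value
  W
}

#' @rdname read_ec_table
#' @param W Environments x covariates matrix with `<covariate>_<phase>`
#'   column names.
#' @export
write_ec_table <- function(W, path) {
  W <- unclass(as.matrix(W))
  parts <- regmatches(colnames(W), regexpr("_[^_]+$", colnames(W)))
  cov <- sub("_[^_]+$", "", colnames(W))
  phase <- sub("^_", "", parts)
  df <- data.frame(
    env_id = rep(rownames(W), times = ncol(W)),
    covariate = rep(cov, each = nrow(W)),
    phase = rep(phase, each = nrow(W)),
    value = as.vector(W),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
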