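#' Impute and standardize a marker matrix
#'
#' Replaces missing dosages by the marker (column) mean, then centers each
#' marker to mean zero and scales it to unit sample standard deviation
#' (n - 1 denominator). The result is the `X` of the genomic relationship
#' matrix `G = X X' / p`.
#'
#' @param M Numeric matrix, lines x markers, entries in \{0, 0.5, 1, NA\}.
#' @return Numeric matrix of the same shape, columns with mean 0 and sd 1.
#' @export
impute_and_standardize <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 lines")
  mu <- colMeans(M, na.rm = TRUE)
  na <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na) > 0L) M[na] <- mu[na[, 2L]]
  X <- sweep(M, 2L, colMeans(M), "-")
  s <- apply(X, 2L, stats::sd)
  if (any(s < .Machine$double.eps^0.5)) {
    stop("zero-variance marker(s): ",
         paste(utils::head(colnames(M)[s < .Machine$double.eps^0.5], 3L),
               collapse = ", "),
         " (markers must be polymorphic; run filter_markers first)")
  }
  sweep(X, 2L, s, "/")
}

#' Genomic relationship matrix
#'
#' Computes `G = X X' / p` from the centered, standardized marker matrix `X`
#' with `p` markers (VanRaden-type GRM on standardized dosages).
#'
#' @param X Centered standardized marker matrix (lines x markers), e.g. from
#'   [impute_and_standardize()].
#' @return A symmetric positive semi-definite lines x lines matrix with line
#'   ids as dimnames.
#' @export
compute_grm <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 lines to build a GRM")
  if (ncol(X) < 1L) stop("need at least 1 marker")
  G <- tcrossprod(X) / ncol(X)
  (G + t(G)) / 2
}

#' Write a relationship matrix as delimited text
#'
#' Tab-delimited export with line ids as both header row and first column,
#' readable back with [read_grm()].
#'
#' @param G Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(G, path) {
  df <- data.frame(line_id = rownames(G), G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  G <- as.matrix(df[, -1L, drop = FALSE])
  rownames(G) <- df[[1L]]
  G
}

#' Principal component scores of a marker matrix
#'
#' Singular value decomposition of the centered standardized marker matrix;
#' scores are `U %*% diag(d)` and explained-variance fractions the squared
#' singular values normalized to the total.
#'
#' @param X Centered standardized marker matrix (lines x markers).
#' @param n_components Number of leading components to keep.
#' @return A list with `scores` (lines x components) and
#'   `explained_variance_fraction` (non-increasing, sums to <= 1).
#' @export
pca_scores <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(X))) {
    stop("n_components must be in [1, min(lines, markers)]")
  }
  sv <- svd(X, nu = k, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       explained_variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}
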