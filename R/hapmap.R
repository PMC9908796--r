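.HAPMAP_HEADER <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

.IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
.MISSING_CODES <- c("NN", "N", "-", "--", "./.", ".", "NA")

#' Read genotypes from a HapMap file
#'
#' Parses the tab-delimited HapMap genotype format: the 11 standard metadata
#' columns (`rs#`, `alleles`, `chrom`, `pos`, `strand`, `assembly#`, `center`,
#' `protLSID`, `assayLSID`, `panelLSID`, `QCcode`) followed by one column per
#' line (sample). Both the diploid two-letter call dialect (`"AG"`) and the
#' IUPAC single-letter dialect (`"R"` for A/G heterozygotes) are accepted;
#' `NN`, `N` and `-` are read as missing.
#'
#' @param path Path to a HapMap file.
#' @return An object of class `hapmap`: a list with `info` (data.frame with
#'   `marker_id`, `alleles`, `chrom`, `pos`), `calls` (character matrix,
#'   markers x lines, normalized to two-letter calls or `NA`), and `line_ids`.
#' @export
read_hapmap <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty HapMap file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 12L) {
    stop("HapMap header has fewer than 12 columns (11 metadata + >=1 sample)")
  }
  miss <- which(header[1:11] != .HAPMAP_HEADER)
  if (length(miss) > 0L) {
    stop("malformed HapMap header: expected column '", .HAPMAP_HEADER[miss[1L]],
         "' at position ", miss[1L], ", found '", header[miss[1L]], "'")
  }
  line_ids <- header[-(1:11)]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != length(header))) {
    stop("row ", which(ncols != length(header))[1L],
         " has ", ncols[ncols != length(header)][1L],
         " fields, expected ", length(header))
  }
  mat <- do.call(rbind, fields)
  info <- data.frame(
    marker_id = mat[, 1L],
    alleles   = mat[, 2L],
    chrom     = mat[, 3L],
    pos       = as.integer(mat[, 4L]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(info$marker_id)) {
    stop("duplicate marker id: ",
         info$marker_id[duplicated(info$marker_id)][1L])
  }
  calls <- mat[, -(1:11), drop = FALSE]
  dimnames(calls) <- list(info$marker_id, line_ids)
  calls <- normalize_calls(calls)
  structure(list(info = info, calls = calls, line_ids = line_ids),
            class = "hapmap")
}

# Normalize a character matrix of raw HapMap calls to two-letter calls / NA.
normalize_calls <- function(calls) {
  flat <- toupper(as.vector(calls))
  flat[flat %in% .MISSING_CODES] <- NA_character_
  one <- !is.na(flat) & nchar(flat) == 1L
  if (any(one)) {
    homo <- one & flat %in% c("A", "C", "G", "T")
    flat[homo] <- paste0(flat[homo], flat[homo])
    iupac <- one & flat %in% names(.IUPAC_HET)
    flat[iupac] <- .IUPAC_HET[flat[iupac]]
    bad <- one & !homo & !iupac
    if (any(bad)) stop("unrecognized single-letter call: ", flat[bad][1L])
  }
  ok <- is.na(flat) | grepl("^[ACGT]{2}$", flat)
  if (!all(ok)) stop("unrecognized genotype call: ", flat[!ok][1L])
  matrix(flat, nrow = nrow(calls), dimnames = dimnames(calls))
}

#' @export
print.hapmap <- function(x, ...) {
  cat("HapMap genotypes:", nrow(x$calls), "markers x",
      length(x$line_ids), "lines\n")
  invisible(x)
}

#' Write genotypes to a HapMap file
#'
#' Inverse of [read_hapmap()]; writes two-letter calls and `NN` for missing.
#'
#' @param hm A `hapmap` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(hm, path) {
  stopifnot(inherits(hm, "hapmap"))
  header <- c(.HAPMAP_HEADER, hm$line_ids)
  calls <- hm$calls
  calls[is.na(calls)] <- "NN"
  meta <- cbind(hm$info$marker_id, hm$info$alleles, hm$info$chrom,
                as.character(hm$info$pos), "+", "NA", "NA", "NA", "NA",
                "NA", "NA")
  rows <- apply(cbind(meta, calls), 1L, paste, collapse = "\t")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Per-marker quality statistics
#'
#' Computes, for every marker, the missing-call fraction, the minor allele
#' frequency (from allele counts among non-missing calls, heterozygotes
#' contributing one copy of each allele), and the fraction of heterozygous
#' calls among non-missing calls.
#'
#' @param hm A `hapmap` object.
#' @return A data.frame with columns `marker_id`, `missing_fraction`, `maf`,
#'   `het_fraction`.
#' @export
marker_stats <- function(hm) {
  stopifnot(inherits(hm, "hapmap"))
  calls <- hm$calls
  n <- ncol(calls)
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  is_het <- !is.na(calls) & a1 != a2
  n_obs <- rowSums(!is.na(calls))
  het_fraction <- rowSums(is_het) / n_obs
  het_fraction[n_obs == 0] <- NA_real_
  stats <- data.frame(
    marker_id = hm$info$marker_id,
    missing_fraction = 1 - n_obs / n,
    maf = rep(NA_real_, nrow(calls)),
    het_fraction = het_fraction,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(calls))) {
    obs <- c(a1[i, ], a2[i, ])
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) next
    freq <- table(obs) / length(obs)
    stats$maf[i] <- if (length(freq) == 1L) 0 else min(freq)
  }
  stats
}

#' Quality-filter markers
#'
#' Removes markers with more than `max_missing` missing calls, a minor allele
#' frequency strictly below `min_maf`, or a heterozygous-call fraction
#' strictly above `max_het` (defaults 20% / 5% / 10%). All three statistics
#' are computed once on the input and the thresholds applied jointly, so the
#' result does not depend on an application order and the filter is
#' idempotent.
#'
#' @param hm A `hapmap` object.
#' @param max_missing Maximum tolerated missing fraction (exclusive bound).
#' @param min_maf Minimum tolerated minor allele frequency (inclusive bound).
#' @param max_het Maximum tolerated heterozygosity (exclusive bound).
#' @return A list with `hapmap` (retained markers, input order preserved) and
#'   `stats` (the full statistics table with a logical `retained` column).
#' @export
filter_markers <- function(hm, max_missing = 0.20, min_maf = 0.05,
                           max_het = 0.10) {
  stopifnot(inherits(hm, "hapmap"))
  if (nrow(hm$calls) == 0L) {
    warning("no markers in input; returning empty set")
    stats <- cbind(marker_stats(hm), retained = logical(0))
    return(list(hapmap = hm, stats = stats))
  }
  stats <- marker_stats(hm)
  keep <- stats$missing_fraction <= max_missing &
    stats$maf >= min_maf &
    stats$het_fraction <= max_het
  keep[is.na(keep)] <- FALSE
  stats$retained <- keep
  out <- structure(list(
    info = hm$info[keep, , drop = FALSE],
    calls = hm$calls[keep, , drop = FALSE],
    line_ids = hm$line_ids
  ), class = "hapmap")
  rownames(out$info) <- NULL
  list(hapmap = out, stats = stats)
}

#' Encode genotype calls numerically
#'
#' Maps each biallelic marker to the 0 / 0.5 / 1 dosage scale: homozygous for
#' the panel-major allele is 0, heterozygous 0.5, homozygous for the minor
#' allele 1. Missing calls are preserved as `NA`. When both alleles are
#' equally frequent the alphabetically first allele is taken as major; the
#' choice is immaterial downstream because the genomic relationship matrix is
#' invariant to orientation after centering.
#'
#' @param hm A `hapmap` object.
#' @return A numeric matrix, lines x markers, entries in \{0, 0.5, 1, NA\}.
#' @export
encode_numeric <- function(hm) {
  stopifnot(inherits(hm, "hapmap"))
  calls <- hm$calls
  m <- nrow(calls)
  out <- matrix(NA_real_, nrow = ncol(calls), ncol = m,
                dimnames = list(hm$line_ids, hm$info$marker_id))
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  for (i in seq_len(m)) {
    obs <- c(a1[i, ], a2[i, ])
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) next
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop("marker ", hm$info$marker_id[i], " has more than two alleles: ",
           paste(alleles, collapse = ", "))
    }
    counts <- table(factor(obs, levels = alleles))
    major <- alleles[which.max(counts)]  # ties: first (alphabetical) wins
    dose <- (as.integer(a1[i, ] != major) + as.integer(a2[i, ] != major)) / 2
    out[, i] <- dose
  }
  out
}
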