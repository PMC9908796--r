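#' Configuration for the synthetic multi-environment data generator
#'
#' Defaults describe a realistic sparse multi-environment trial of an
#' elite inbred panel: 150 lines genotyped at 500 biallelic SNPs (2%
#' residual heterozygosity), 10 environments described by 8 environmental
#' covariates, environment main effects dominating the genetic signal, and
#' an unbalanced allocation with about a third of the lines observed
#' everywhere.
#'
#' @param n_lines,n_markers,n_envs,n_ecs Panel and trial sizes.
#' @param maf_range Minor-allele-frequency range (within (0, 0.5\]).
#' @param het_rate Residual heterozygosity of the inbred panel.
#' @param variances Named variance targets for the generative model
#'   components `g` (genomic), `e` (environment main), `w` (EC-mediated
#'   environment), `ge` (non-transferable interaction), `gw` (EC-mediated,
#'   transferable interaction), `eps` (residual).
#' @param ec_cor Common correlation between EC columns.
#' @param ec_noise Fraction of environment-main-effect variance *not*
#'   explained by the ECs (0 = effects perfectly predicted by ECs).
#' @param allocation_range Min/max lines observed per environment; `NULL`
#'   means a fully observed grid.
#' @param core_fraction Fraction of lines observed in every environment.
#' @param mu Grand mean of the phenotype.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 150L, n_markers = 500L, n_envs = 10L,
                       n_ecs = 8L, maf_range = c(0.05, 0.5),
                       het_rate = 0.02,
                       variances = c(g = 1, e = 2, w = 0.5, ge = 0.25,
                                     gw = 0.25, eps = 0.5),
                       ec_cor = 0.3, ec_noise = 0.2,
                       allocation_range = c(ceiling(0.35 * n_lines), n_lines),
                       core_fraction = 0.3, mu = 0, seed = 1L) {
  stopifnot(all(variances >= 0),
            maf_range[1L] > 0, maf_range[2L] <= 0.5,
            maf_range[1L] <= maf_range[2L])
  if (!is.null(allocation_range)) {
    stopifnot(allocation_range[1L] <= allocation_range[2L],
              allocation_range[2L] <= n_lines)
  }
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 n_envs = as.integer(n_envs), n_ecs = as.integer(n_ecs),
                 maf_range = maf_range, het_rate = het_rate,
                 variances = variances, ec_cor = ec_cor,
                 ec_noise = ec_noise, allocation_range = allocation_range,
                 core_fraction = core_fraction, mu = mu,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype panel
#'
#' Draws a biallelic marker panel for an inbred-line population: per-marker
#' minor allele frequencies uniform on the configured range, genotypes
#' mostly homozygous with a small heterozygosity rate, on the 0 / 0.5 / 1
#' dosage scale. Markers violating each quality filter (high missingness,
#' low MAF, high heterozygosity) can be injected to exercise QC code;
#' injected marker ids are recorded in attributes `qc_missing`, `qc_maf`,
#' `qc_het`.
#'
#' @param config A `sim_config`.
#' @param n_bad_missing,n_bad_maf,n_bad_het Numbers of extra markers to
#'   inject that violate (only) the corresponding filter.
#' @return Numeric lines x markers dosage matrix (may contain `NA` when
#'   missingness is injected).
#' @export
simulate_genotypes <- function(config, n_bad_missing = 0L, n_bad_maf = 0L,
                               n_bad_het = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  p <- config$n_markers
  line_ids <- sprintf("L%03d", seq_len(n))
  draw_marker <- function(q, h) {
    # heterozygote with prob h; homozygote minor with the complement mass
    # chosen so the expected minor allele frequency is exactly q
    p_hom_minor <- min(1, max(0, (q - h / 2) / (1 - h)))
    u <- stats::runif(n)
    dose <- ifelse(u < h, 0.5, ifelse(u < h + (1 - h) * p_hom_minor, 1, 0))
    dose
  }
  q <- stats::runif(p, config$maf_range[1L], config$maf_range[2L])
  # redraw monomorphic realizations so every emitted marker is polymorphic
  draw_polymorphic <- function(qj) {
    for (try in 1:100) {
      dose <- draw_marker(qj, config$het_rate)
      if (stats::var(dose) > 0) return(dose)
    }
    stop("failed to draw a polymorphic marker")
  }
  M <- vapply(seq_len(p), function(j) draw_polymorphic(q[j]), numeric(n))
  dimnames(M) <- list(line_ids, sprintf("M%04d", seq_len(p)))
  attr(M, "true_maf") <- q

  add <- function(M, k, prefix, gen) {
    if (k <= 0L) return(M)
    extra <- vapply(seq_len(k), function(j) gen(), numeric(n))
    colnames(extra) <- sprintf("%s%03d", prefix, seq_len(k))
    cbind(M, extra)
  }
  M <- add(M, n_bad_missing, "BADMISS", function() {
    x <- draw_marker(stats::runif(1L, 0.2, 0.5), config$het_rate)
    x[sample(n, ceiling(0.3 * n))] <- NA_real_
    x
  })
  M <- add(M, n_bad_maf, "BADMAF", function() {
    x <- numeric(n)
    x[sample(n, max(1L, floor(0.02 * n)))] <- 1
    x
  })
  M <- add(M, n_bad_het, "BADHET", function() {
    x <- draw_marker(stats::runif(1L, 0.2, 0.5), 0.5)
    x
  })
  attr(M, "qc_missing") <- if (n_bad_missing > 0L)
    sprintf("BADMISS%03d", seq_len(n_bad_missing)) else character(0)
  attr(M, "qc_maf") <- if (n_bad_maf > 0L)
    sprintf("BADMAF%03d", seq_len(n_bad_maf)) else character(0)
  attr(M, "qc_het") <- if (n_bad_het > 0L)
    sprintf("BADHET%03d", seq_len(n_bad_het)) else character(0)
  M
}

#' Convert a dosage matrix to a HapMap object
#'
#' Assigns each marker a random pair of distinct nucleotides and maps
#' dosages 0 / 0.5 / 1 to major-homozygous, heterozygous and
#' minor-homozygous two-letter calls (missing to `NN`), yielding a `hapmap`
#' object that can be written with [write_hapmap()].
#'
#' @param M Lines x markers dosage matrix.
#' @param seed Seed for the allele-letter assignment.
#' @return A `hapmap` object.
#' @export
dosage_to_hapmap <- function(M, seed = 1L) {
  set.seed(seed)
  n <- nrow(M)
  p <- ncol(M)
  calls <- matrix(NA_character_, p, n,
                  dimnames = list(colnames(M), rownames(M)))
  alleles <- character(p)
  for (j in seq_len(p)) {
    ab <- sample(c("A", "C", "G", "T"), 2L)
    alleles[j] <- paste(ab, collapse = "/")
    code <- c(paste0(ab[1L], ab[1L]), paste0(ab[1L], ab[2L]),
              paste0(ab[2L], ab[2L]))
    d <- M[, j]
    calls[j, !is.na(d)] <- code[2 * d[!is.na(d)] + 1]
  }
  info <- data.frame(marker_id = colnames(M), alleles = alleles,
                     chrom = as.character(rep_len(1:12, p)),
                     pos = seq_len(p) * 1000L, stringsAsFactors = FALSE)
  structure(list(info = info, calls = calls, line_ids = rownames(M)),
            class = "hapmap")
}

#' Simulate environments and their covariates
#'
#' Draws per-environment EC vectors from a multivariate normal with a
#' common between-covariate correlation, and environment main effects as a
#' linear function of the standardized ECs plus configurable noise -- so
#' that EC distance predicts environment-effect similarity, the working
#' assumption of covariate-based training-set selection. Optionally also
#' emits a consistent daily-weather series per environment (piecewise
#' constant within phenology phases) whose aggregation through
#' [aggregate_ecs()] reproduces the covariates, to exercise the weather
#' pipeline end to end.
#'
#' @param config A `sim_config`.
#' @param emit_weather Also generate daily weather tables.
#' @return List with `W` (standardized `ec_matrix`), `ec_raw`,
#'   `env_effects` (named, standardized scale), `env_ids`; with
#'   `emit_weather = TRUE` additionally `weather` (named list of daily
#'   data.frames), `windows`, `latitude`.
#' @export
simulate_environments <- function(config, emit_weather = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$n_envs
  env_ids <- sprintf("E%02d", seq_len(m))
  if (!emit_weather) {
    q <- config$n_ecs
    S <- matrix(config$ec_cor, q, q)
    diag(S) <- 1
    L <- chol(S)
    ec_raw <- matrix(stats::rnorm(m * q), m, q) %*% L
    dimnames(ec_raw) <- list(env_ids, sprintf("EC%d_WS", seq_len(q)))
    weather <- NULL
    windows <- NULL
    latitude <- NULL
  } else {
    latitude <- 14
    transplant <- as.Date("2019-01-15")
    harvest <- as.Date("2019-05-15")
    weather <- list()
    windows <- list()
    rows <- list()
    for (e in env_ids) {
      fs <- transplant + sample(60:75, 1L)
      fe <- fs + sample(15:30, 1L)
      w <- infer_phenology_windows(transplant, harvest,
                                   seeding_date = transplant - 25,
                                   dtf = as.integer(c(fs, fe) -
                                                      (transplant - 25)))
      dates <- seq(transplant, harvest, by = "day")
      phase <- .phase_of_day(dates, w)
      base <- function(mu, sd_between, sd_phase) {
        mu + stats::rnorm(1L, 0, sd_between) +
          stats::rnorm(3L, 0, sd_phase)[match(phase, .EC_PHASES)]
      }
      tm <- base(26, 2, 1.5)
      tr <- pmax(4, base(9, 1.5, 1))
      daily <- data.frame(
        env_id = e, date = dates,
        TMIN = tm - tr / 2, TMAX = tm + tr / 2, TM = tm,
        DPT = tm - pmax(1, base(4, 1, 0.8)),
        RH = pmin(100, pmax(30, base(75, 6, 3))),
        PP = pmax(0, base(5, 2.5, 1.5)),
        APAR = pmax(50, base(130, 12, 6)),
        CPAR = pmax(80, base(150, 10, 5))
      )
      daily <- derive_daily_variables(daily, latitude)
      weather[[e]] <- daily
      windows[[e]] <- w
      rows[[e]] <- aggregate_ecs(daily, w, whole_season = TRUE)
    }
    ec_raw <- do.call(rbind, rows)
    rownames(ec_raw) <- env_ids
  }
  W <- suppressWarnings(standardize_ecs(ec_raw))
  beta <- stats::rnorm(ncol(W))
  signal <- drop(unclass(W) %*% beta)
  signal <- signal / stats::sd(signal)
  noise <- stats::rnorm(m)
  if (config$ec_noise > 0) noise <- noise / stats::sd(noise)
  eff <- sqrt(1 - config$ec_noise) * signal + sqrt(config$ec_noise) * noise
  names(eff) <- env_ids
  out <- list(W = W, ec_raw = ec_raw, env_effects = eff, env_ids = env_ids)
  if (emit_weather) {
    out$weather <- weather
    out$windows <- windows
    out$latitude <- latitude
  }
  out
}

#' Simulate a sparse line x environment allocation mask
#'
#' Emulates sparse testing: each environment observes a uniform random
#' number of lines within `allocation_range`, always including a core set
#' of lines present everywhere (as in trials where a common check panel is
#' grown at every site).
#'
#' @param n_lines,n_envs Grid dimensions.
#' @param allocation_range Min/max lines per environment.
#' @param core_fraction Fraction of lines observed in every environment.
#' @param seed Integer seed.
#' @return Logical lines x environments matrix (`TRUE` = observed).
#' @export
make_sparse_mask <- function(n_lines, n_envs, allocation_range,
                             core_fraction = 0.3, seed = 1L) {
  stopifnot(allocation_range[1L] >= 1,
            allocation_range[2L] <= n_lines)
  core_size <- round(core_fraction * n_lines)
  if (core_size > allocation_range[1L]) {
    stop("core set (", core_size, " lines) larger than the minimum ",
         "allocation (", allocation_range[1L], ")")
  }
  set.seed(seed)
  core <- sample.int(n_lines, core_size)
  noncore <- setdiff(seq_len(n_lines), core)
  mask <- matrix(FALSE, n_lines, n_envs)
  span <- allocation_range[2L] - allocation_range[1L] + 1L
  for (j in seq_len(n_envs)) {
    cnt <- allocation_range[1L] + sample.int(span, 1L) - 1L
    extra <- noncore[sample.int(length(noncore), cnt - core_size)]
    mask[c(core, extra), j] <- TRUE
  }
  mask
}

#' Simulate phenotypes from the reaction-norm generative model
#'
#' Generates cell-level phenotypes `y_ij = mu + g_i + e_j + w_j + ge_ij +
#' gw_ij + eps_ij`: the genomic main effect from additive marker effects on
#' the centered standardized genotypes; the environment main effect from
#' the simulated environments; the `w` term as an EC-driven environment
#' effect; `ge` as an i.i.d. non-transferable line x environment deviation
#' (the model class of the `K_ge` kernel); `gw` as a sum of marker-driven
#' genetic slopes on the EC columns (transferable across environments
#' through `Omega`); and i.i.d. Gaussian noise. Every component is rescaled
#' to hit its target variance exactly over the observed cells, so the
#' realized components in the returned truth equal the targets.
#'
#' @param M Dosage matrix from [simulate_genotypes()] (QC-clean part used).
#' @param env Result of [simulate_environments()].
#' @param config A `sim_config`.
#' @param mask Logical lines x environments observation mask (default from
#'   [make_sparse_mask()] under the config, or fully observed when the
#'   config's `allocation_range` is `NULL`).
#' @return List with `pheno` (a `pheno_grid`), `truth` (components per
#'   cell, marker effects, realized variances), `G` (genomic relationship
#'   matrix of the panel).
#' @export
simulate_phenotypes <- function(M, env, config, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variances
  if (all(v == 0)) stop("all variance targets are zero")
  keep <- !grepl("^BAD", colnames(M))
  M <- M[, keep, drop = FALSE]
  X <- impute_and_standardize(M)
  G <- compute_grm(X)
  n <- nrow(X)
  m <- config$n_envs
  set.seed(config$seed + 2L)
  if (is.null(mask)) {
    mask <- if (is.null(config$allocation_range)) {
      matrix(TRUE, n, m)
    } else {
      make_sparse_mask(n, m, config$allocation_range,
                       config$core_fraction, config$seed + 3L)
    }
  }
  W <- unclass(env$W)
  obs <- as.vector(mask)

  scale_to <- function(comp, target) {
    # exact variance calibration over observed cells
    if (target == 0) return(comp * 0)
    s <- stats::sd(comp[obs])
    if (s == 0) stop("degenerate component cannot be scaled")
    comp * sqrt(target) / s
  }

  a <- stats::rnorm(ncol(X))
  g_line <- drop(X %*% a)
  g <- matrix(rep(g_line, m), n, m)
  g <- scale_to(g, v[["g"]])

  e <- matrix(rep(env$env_effects, each = n), n, m)
  e <- if (stats::sd(e[obs]) > 0) scale_to(e, v[["e"]]) else e * 0

  gamma <- stats::rnorm(ncol(W))
  w_env <- drop(W %*% gamma)
  w <- matrix(rep(w_env, each = n), n, m)
  w <- if (v[["w"]] > 0) scale_to(w, v[["w"]]) else w * 0

  ge <- scale_to(matrix(stats::rnorm(n * m), n, m), v[["ge"]])

  gw <- matrix(0, n, m)
  if (v[["gw"]] > 0) {
    for (k in seq_len(ncol(W))) {
      ak <- stats::rnorm(ncol(X))
      gw <- gw + outer(drop(X %*% ak), W[, k])
    }
    gw <- scale_to(gw, v[["gw"]])
  }

  eps <- scale_to(matrix(stats::rnorm(n * m), n, m), v[["eps"]])

  y <- config$mu + g + e + w + ge + gw + eps
  values <- ifelse(mask, y, NA_real_)
  dimnames(values) <- list(rownames(X), env$env_ids)
  long <- data.frame(
    line_id = rep(rownames(X), m),
    env_id = rep(env$env_ids, each = n),
    value = as.vector(values),
    stringsAsFactors = FALSE
  )
  pheno <- assemble_pheno_grid(long[!is.na(long$value), ], trait = "sim")
  realized <- vapply(list(g = g, e = e, w = w, ge = ge, gw = gw, eps = eps),
                     function(comp) stats::var(comp[obs]), numeric(1L))
  truth <- list(marker_effects = a, env_effects = env$env_effects,
                components = list(g = g, e = e, w = w, ge = ge, gw = gw,
                                  eps = eps),
                genetic_values = g + w + ge + gw,
                realized_variances = realized, mask = mask, mu = config$mu)
  list(pheno = pheno, truth = truth, G = G)
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_environments()], [make_sparse_mask()] and
#' [simulate_phenotypes()] into a [gp_data()] bundle plus ground truth.
#'
#' @param config A `sim_config`.
#' @param emit_weather Passed to [simulate_environments()].
#' @return List with `data` (a `gp_data`), `truth`, `M` (dosages), `env`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), emit_weather = FALSE) {
  M <- simulate_genotypes(config)
  env <- simulate_environments(config, emit_weather = emit_weather)
  sim <- simulate_phenotypes(M, env, config)
  data <- gp_data(sim$pheno, sim$G, W = env$W)
  list(data = data, truth = sim$truth, M = M, env = env, config = config)
}
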