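# Small in-code fixtures shared across test files.

# Write a tiny HapMap file from a list of rows; returns the path.
write_hapmap_text <- function(rows, line_ids, path = tempfile(fileext = ".hmp.txt")) {
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    line_ids), collapse = "\t")
  writeLines(c(header, vapply(rows, paste, character(1L), collapse = "\t")),
             path)
  path
}

hapmap_row <- function(id, alleles, calls, chrom = "1", pos = 1000L) {
  c(id, alleles, chrom, as.character(pos), "+", rep("NA", 6L), calls)
}

# A small fully-specified 3-line panel used by several parser tests.
tiny_hapmap_path <- function() {
  write_hapmap_text(list(
    hapmap_row("m1", "A/G", c("AA", "AG", "GG"), pos = 100L),
    hapmap_row("m2", "C/T", c("CC", "Y", "NN"), pos = 200L)
  ), c("l1", "l2", "l3"))
}

# Small balanced RCBD phenotype fixture with known generative values.
rcbd_plots <- function(n_lines, n_reps, s2g, s2e, seed, mu = 50) {
  set.seed(seed)
  g <- rnorm(n_lines, 0, sqrt(s2g))
  b <- rnorm(n_reps, 0, 1)
  df <- expand.grid(line_id = sprintf("L%02d", seq_len(n_lines)),
                    replicate = sprintf("R%d", seq_len(n_reps)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- mu + g[match(df$line_id, sprintf("L%02d", seq_len(n_lines)))] +
    b[match(df$replicate, sprintf("R%d", seq_len(n_reps)))] +
    rnorm(nrow(df), 0, sqrt(s2e))
  df
}

# A small simulated dataset reused by model/CV tests (cheap to build).
small_sim <- function(seed = 11L, n_envs = 6L, variances = NULL, ...) {
  cfg_args <- utils::modifyList(
    list(n_lines = 40L, n_markers = 150L, n_envs = n_envs, n_ecs = 4L,
         seed = seed),
    list(...))
  if (!is.null(variances)) cfg_args$variances <- variances
  cfg <- do.call(sim_config, cfg_args)
  simulate_dataset(cfg)
}

fast_mcmc <- function(seed = 1L) {
  mcmc_settings(n_iter = 3000L, burn_in = 500L, thin = 5L, seed = seed)
}
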