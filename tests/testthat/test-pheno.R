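test_that("grid assembly masks unobserved cells and counts conserve", {
  long <- data.frame(
    line_id = c("a", "b", "a", "b"),
    env_id = c("e1", "e1", "e2", "e3"),
    value = c(1, 2, 3, 4)
  )
  grid <- assemble_pheno_grid(long, trait = "DTF")
  expect_equal(dim(grid$values), c(2L, 3L))
  expect_equal(sum(!grid$mask), 2L)  # 6 cells - 4 records
  expect_equal(grid$values["a", "e2"], 3)
  expect_true(is.na(grid$values["b", "e2"]))

  dup <- rbind(long, long[1L, ])
  expect_error(assemble_pheno_grid(dup, trait = "DTF"), "duplicate")
})

test_that("long-format round trip preserves observed records", {
  sim <- small_sim()
  long <- pheno_grid_to_long(sim$data$pheno)
  back <- assemble_pheno_grid(long)
  expect_equal(back$values, sim$data$pheno$values)
  expect_equal(sum(back$mask), nrow(long))
})

test_that("common lines are exactly those observed everywhere", {
  sim <- small_sim()
  cl <- common_lines(sim$data$pheno)
  expect_true(all(rowSums(sim$data$pheno$mask[cl, ]) ==
                    length(sim$data$pheno$env_ids)))
  others <- setdiff(sim$data$pheno$line_ids, cl)
  expect_true(all(rowSums(sim$data$pheno$mask[others, , drop = FALSE]) <
                    length(sim$data$pheno$env_ids)))
})

test_that("environment correlations: identity, overlap rule, symmetry", {
  v <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10)
  long <- rbind(
    data.frame(line_id = paste0("l", 1:10), env_id = "e1", value = v),
    data.frame(line_id = paste0("l", 1:10), env_id = "e2", value = v),
    data.frame(line_id = paste0("l", 1:2), env_id = "e3", value = c(1, 2))
  )
  grid <- assemble_pheno_grid(long, trait = "t")
  ec <- env_correlation(grid, min_overlap = 10L)
  expect_equal(ec$r["e1", "e2"], 1)
  expect_true(is.na(ec$r["e1", "e3"]))  # only 2 shared lines
  expect_equal(ec$r, t(ec$r))
  expect_error(env_correlation(grid, min_overlap = 2L), ">= 3")
})

test_that("correlations are invariant to per-environment affine rescaling", {
  sim <- small_sim()
  grid <- sim$data$pheno
  r1 <- env_correlation(grid, min_overlap = 3L)$r
  grid2 <- grid
  scales <- seq(2, 3, length.out = length(grid$env_ids))
  grid2$values <- sweep(grid$values, 2L, scales, "*") + 7
  r2 <- env_correlation(grid2, min_overlap = 3L)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("correlation summary matches direct computation", {
  sim <- small_sim()
  ec <- env_correlation(sim$data$pheno, min_overlap = 3L)
  s <- summarize_env_correlation(ec, threshold = 0.5)
  up <- ec$r[upper.tri(ec$r)]
  m <- length(sim$data$pheno$env_ids)
  expect_equal(s$n_pairs, m * (m - 1L) / 2L)
  expect_equal(s$fraction_above, mean(up[!is.na(up)] > 0.5))
  expect_equal(s$max, max(up, na.rm = TRUE))
})

test_that("two-way ANOVA recovers the hand decomposition", {
  # 2 genotypes x 2 environments x 2 reps, cell means [[1,-1],[-1,1]],
  # zero within-cell spread: all SS in the interaction
  long <- expand.grid(line_id = c("g1", "g2"), env_id = c("e1", "e2"),
                      rep = 1:2, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$value <- ifelse((long$line_id == "g1") == (long$env_id == "e1"), 1, -1)
  res <- gxe_anova(long)
  tab <- res$table
  expect_equal(tab$sum_sq[tab$term == "genotype"], 0, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "environment"], 0, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "genotype:environment"], 8,
               tolerance = 1e-10)
  expect_true(res$interaction_testable)

  # location invariance and SS additivity
  long2 <- long
  long2$value <- long2$value + 100
  tab2 <- gxe_anova(long2)$table
  expect_equal(tab2$sum_sq, tab$sum_sq, tolerance = 1e-8)
  total <- sum((long$value - mean(long$value))^2)
  expect_equal(sum(tab$sum_sq), total, tolerance = 1e-8)
})

test_that("cell-level ANOVA flags the untestable interaction", {
  set.seed(51)
  long <- expand.grid(line_id = paste0("g", 1:6), env_id = paste0("e", 1:4),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- rnorm(nrow(long))
  res <- gxe_anova(long)
  expect_false(res$interaction_testable)
  expect_true(is.na(res$table$f_value[res$table$term == "genotype:environment"]))

  expect_error(gxe_anova(long[-1L, ]), "common_lines")
})

test_that("phenotypic clustering recovers planted blocks", {
  set.seed(61)
  base1 <- rnorm(60)
  base2 <- rnorm(60)
  make_env <- function(base) base + rnorm(60, 0, 0.3)
  cols <- cbind(make_env(base1), make_env(base1), make_env(base1),
                make_env(base2), make_env(base2), make_env(base2))
  colnames(cols) <- paste0("e", 1:6)
  long <- data.frame(line_id = rep(paste0("l", 1:60), 6L),
                     env_id = rep(colnames(cols), each = 60L),
                     value = as.vector(cols))
  grid <- assemble_pheno_grid(long, trait = "t")
  ec <- env_correlation(grid, min_overlap = 10L)
  tree <- cluster_environments_pheno(ec)
  expect_equal(nrow(tree$merge), 5L)  # n - 1 merges
  groups <- cutree(tree, k = 2L)
  expect_equal(length(unique(groups[c("e1", "e2", "e3")])), 1L)
  expect_equal(length(unique(groups[c("e4", "e5", "e6")])), 1L)
  expect_true(groups[["e1"]] != groups[["e4"]])
})

test_that("identity correlation merges everything at height one", {
  r <- diag(4)
  dimnames(r) <- list(paste0("e", 1:4), paste0("e", 1:4))
  tree <- cluster_environments_pheno(list(r = r))
  expect_equal(tree$height, rep(1, 3L), tolerance = 1e-12)

  r_na <- r
  r_na[1L, 2L] <- r_na[2L, 1L] <- NA
  expect_error(cluster_environments_pheno(list(r = r_na)), "e1 / e2")
})
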