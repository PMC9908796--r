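test_that("parser reads both call dialects and maps unknowns to missing", {
  hm <- read_hapmap(tiny_hapmap_path())
  expect_s3_class(hm, "hapmap")
  expect_equal(nrow(hm$info), 2L)
  expect_equal(hm$line_ids, c("l1", "l2", "l3"))
  expect_equal(unname(hm$calls["m1", ]), c("AA", "AG", "GG"))
  # IUPAC "Y" with alleles C/T is the heterozygote; "NN" is missing
  expect_equal(unname(hm$calls["m2", ]), c("CC", "CT", NA))
})

test_that("parser rejects malformed headers and duplicate markers", {
  bad_header <- tempfile()
  writeLines(c(paste(c("rs#", "alleles", "chrom", "WRONG", "strand",
                       "assembly#", "center", "protLSID", "assayLSID",
                       "panelLSID", "QCcode", "l1"), collapse = "\t"),
               paste(c("m1", "A/G", "1", "100", "+", rep("NA", 6L), "AA"),
                     collapse = "\t")), bad_header)
  expect_error(read_hapmap(bad_header), "pos")

  dup <- write_hapmap_text(list(
    hapmap_row("m1", "A/G", c("AA", "AG", "GG")),
    hapmap_row("m1", "C/T", c("CC", "CT", "TT"))
  ), c("l1", "l2", "l3"))
  expect_error(read_hapmap(dup), "duplicate")
})

test_that("write then parse round-trips the genotype matrix exactly", {
  cfg <- sim_config(n_lines = 15L, n_markers = 40L, seed = 5L)
  M <- simulate_genotypes(cfg, n_bad_missing = 2L)
  hm <- dosage_to_hapmap(M, seed = 5L)
  path <- tempfile(fileext = ".hmp.txt")
  write_hapmap(hm, path)
  back <- read_hapmap(path)
  expect_identical(back$calls, hm$calls)
  expect_identical(back$line_ids, hm$line_ids)
  # dosages are recovered up to major/minor orientation per marker
  M2 <- encode_numeric(back)
  for (j in colnames(M2)) {
    same <- isTRUE(all.equal(unname(M2[, j]), unname(M[, j])))
    flipped <- isTRUE(all.equal(unname(M2[, j]), unname(1 - M[, j])))
    expect_true(same || flipped, label = paste("marker", j))
  }
})

test_that("marker statistics are computed from non-missing calls", {
  hm <- read_hapmap(write_hapmap_text(list(
    hapmap_row("m1", "A/G", c("AA", "AG", "NN", "GG")),
    hapmap_row("m2", "C/T", c("CC", "CC", "CC", "CT"))
  ), paste0("l", 1:4)))
  st <- marker_stats(hm)
  expect_equal(st$missing_fraction, c(0.25, 0))
  # m1: among 3 observed calls, alleles A:3 G:3 -> maf 0.5; 1 het of 3
  expect_equal(st$maf, c(0.5, 1 / 8))
  expect_equal(st$het_fraction, c(1 / 3, 1 / 4))
})

test_that("quality filters are strict, joint, and idempotent", {
  # 6-marker toy panel over 8 lines: 2 fail missingness, 1 fails MAF
  hm <- read_hapmap(write_hapmap_text(list(
    hapmap_row("k1", "A/G", c("AA", "AA", "GG", "GG", "AA", "GG", "AA", "GG"), pos = 1L),
    hapmap_row("f1", "A/G", c("NN", "NN", "NN", "AA", "GG", "AA", "GG", "AA"), pos = 2L),
    hapmap_row("k2", "A/G", c("AA", "GG", "AA", "GG", "AA", "GG", "AA", "GG"), pos = 3L),
    hapmap_row("f2", "A/G", c("NN", "NN", "AA", "GG", "AA", "GG", "AA", "GG"), pos = 4L),
    hapmap_row("f3", "A/G", rep("AA", 8L), pos = 5L),
    hapmap_row("k3", "A/G", c("AA", "AA", "AA", "GG", "GG", "AA", "GG", "AA"), pos = 6L)
  ), paste0("l", 1:8)))
  fl <- filter_markers(hm)
  expect_equal(fl$hapmap$info$marker_id, c("k1", "k2", "k3"))
  expect_equal(sum(fl$stats$retained), 3L)
  # f1: 3/8 missing (0.375 > 0.2); f2: 2/8 (0.25 > 0.2); f3: maf 0 < 0.05
  expect_false(fl$stats$retained[fl$stats$marker_id == "f2"])
  # filtering the retained set again removes nothing (idempotence)
  fl2 <- filter_markers(fl$hapmap)
  expect_equal(fl2$hapmap$info$marker_id, fl$hapmap$info$marker_id)
})

test_that("boundary statistics survive the strict thresholds", {
  # maf exactly 0.05: 1 minor allele copy in 10 lines (20 copies)
  calls <- c(rep("AA", 9L), "AG")
  hm <- read_hapmap(write_hapmap_text(list(
    hapmap_row("edge_maf", "A/G", calls),
    hapmap_row("over_miss", "A/G", c(rep("NN", 3L), rep("AG", 2L), "AA",
                                     "GG", "AA", "GG", "AA"))
  ), paste0("l", 1:10)))
  st <- marker_stats(hm)
  expect_equal(st$maf[1L], 0.05)
  fl <- filter_markers(hm)
  expect_true("edge_maf" %in% fl$hapmap$info$marker_id)   # "lower than 5%" is strict
  expect_false("over_miss" %in% fl$hapmap$info$marker_id) # 30% missing
})

test_that("empty marker set filters to an empty set with a warning", {
  hm <- read_hapmap(tiny_hapmap_path())
  empty <- structure(list(info = hm$info[0L, ], calls = hm$calls[0L, , drop = FALSE],
                          line_ids = hm$line_ids), class = "hapmap")
  expect_warning(fl <- filter_markers(empty), "no markers")
  expect_equal(nrow(fl$hapmap$calls), 0L)
})

test_that("numeric encoding maps major/het/minor to 0 / 0.5 / 1", {
  hm <- read_hapmap(write_hapmap_text(list(
    hapmap_row("m1", "A/G", c("AA", "AA", "AG", "GG")),   # A major
    hapmap_row("m2", "C/T", rep("CT", 4L))                # all het
  ), paste0("l", 1:4)))
  M <- encode_numeric(hm)
  expect_equal(unname(M[, "m1"]), c(0, 0, 0.5, 1))
  expect_equal(unname(M[, "m2"]), rep(0.5, 4L))
})

test_that("triallelic markers are rejected by name", {
  hm <- read_hapmap(write_hapmap_text(list(
    hapmap_row("bad3", "A/G", c("AA", "AG", "CC", "GG"))
  ), paste0("l", 1:4)))
  expect_error(encode_numeric(hm), "bad3")
})

test_that("orientation flip leaves the centered GRM unchanged", {
  # 3 lines x 2 markers, hand case: m -> 1 - m is a sign flip after centering
  M <- matrix(c(0, 0.5, 1, 1, 0.5, 0), nrow = 3L,
              dimnames = list(paste0("l", 1:3), paste0("m", 1:2)))
  G1 <- compute_grm(impute_and_standardize(M))
  G2 <- compute_grm(impute_and_standardize(1 - M))
  expect_equal(G1, G2, tolerance = 1e-12)
})
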