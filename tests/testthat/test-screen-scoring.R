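# Phenotype computation, gene statistics, hit calling, activity scores and
# phenotype-signed Z scores.

test_that("phenotypes reproduce the log2-RPM-ratio arithmetic", {
  # one targeting guide and one control; totals of 1000 make RPM easy
  cnt <- counts_df(c("sgX", "nc_01"), a = c(200, 800), b = c(50, 950))
  dbl <- data.frame(screen_id = "s1", replicate = 1L, doublings = 2)
  ph <- compute_phenotypes(cnt, "nc_01", pseudocount = 1, doublings = dbl)
  raw_x <- log2((50 / 1000 * 1e6 + 1) / (200 / 1000 * 1e6 + 1))
  raw_nc <- log2((950 / 1000 * 1e6 + 1) / (800 / 1000 * 1e6 + 1))
  expect_equal(ph$phenotype[ph$sgrna_id == "sgX"], (raw_x - raw_nc) / 2)
  expect_equal(ph$phenotype[ph$sgrna_id == "nc_01"], 0)
})

test_that("equal RPM in both conditions gives phenotype zero", {
  cnt <- counts_df(c("sgX", "nc_01"), a = c(100, 100), b = c(100, 100))
  ph <- compute_phenotypes(cnt, "nc_01")
  expect_equal(ph$phenotype, c(0, 0))
})

test_that("replicate phenotypes are arithmetically averaged", {
  cnt <- rbind(counts_df(c("sgX", "nc_01"), c(100, 100), c(400, 100), replicate = 1L),
               counts_df(c("sgX", "nc_01"), c(100, 100), c(200, 100), replicate = 2L))
  ph <- compute_phenotypes(cnt, "nc_01")
  reps <- attr(ph, "replicates")
  per_rep <- reps$phenotype[reps$sgrna_id == "sgX"]
  expect_equal(ph$phenotype[ph$sgrna_id == "sgX"], mean(per_rep))
})

test_that("negative-control median is exactly zero within each replicate", {
  set.seed(7)
  ids <- c(sprintf("sg%02d", 1:20), sprintf("nc%02d", 1:9))
  cnt <- rbind(
    counts_df(ids, rpois(29, 300), rpois(29, 300), replicate = 1L),
    counts_df(ids, rpois(29, 300), rpois(29, 300), replicate = 2L))
  ph <- compute_phenotypes(cnt, sprintf("nc%02d", 1:9))
  reps <- attr(ph, "replicates")
  for (r in 1:2) {
    nc <- reps$phenotype[reps$replicate == r & grepl("^nc", reps$sgrna_id)]
    expect_identical(median(nc), 0)
  }
})

test_that("malformed count tables are rejected", {
  expect_error(compute_phenotypes(counts_df("a", 1, 1), character(0)),
               "negative controls")
  expect_error(compute_phenotypes(counts_df(c("a", "nc"), c(0, 0), c(1, 1)), "nc"),
               "zero total reads")
  cnt <- rbind(counts_df(c("a", "nc"), c(1, 1), c(1, 1), replicate = 1L),
               counts_df("nc", 1, 1, replicate = 2L))
  expect_error(compute_phenotypes(cnt, "nc"), "missing from a replicate")
})

test_that("strongest-3 effect size selects by absolute value, keeps sign", {
  expect_equal(strongest_mean(c(-3, -2, -1, 0.5, 0, 0.2)), -2)
  expect_equal(strongest_mean(c(4, 3, 2, 1, 0)), 3)
  expect_error(strongest_mean(c(1, 2)), "at least 3")
})

test_that("hit score integrates effect Z and Mann-Whitney confidence", {
  expect_equal(hit_score(10, 0.01), 20)
  expect_equal(hit_score(-10, 0.01), 20)
  expect_gte(hit_score(3, 0.5), 0)
})

test_that("hit calling is inclusive at the threshold and takes the max TSS/screen", {
  st <- data.frame(gene = c("A", "A", "B", "C", "C"),
                   tss_id = c("P1", "P2", "P1", "P1", "P1"),
                   screen_id = c("s1", "s1", "s1", "s1", "s2"),
                   score = c(25, 5, 19.99, 20, 20))
  hits <- call_hits(st, threshold = 20)
  expect_true(hits$is_hit[hits$gene == "A"])
  expect_equal(hits$tss_id[hits$gene == "A"], "P1")
  expect_false(hits$is_hit[hits$gene == "B"])
  # exact threshold is a hit; equal scores break ties to lexicographic screen
  expect_true(hits$is_hit[hits$gene == "C"])
  expect_equal(hits$screen_id[hits$gene == "C"], "s1")
})

test_that("gene statistics separate real effects from null genes", {
  set.seed(42)
  lib <- scoring_library(c("HIT", "NULL"), per_gene = 8, n_nc = 60)
  p <- c(rnorm(8, -2, 0.3),          # strong knockdown phenotypes
         rnorm(8, 0, 0.3),           # null gene, same distribution as controls
         rnorm(60, 0, 0.3))
  ph <- phen_df(lib$sgrna_id, p)
  st <- gene_stats(ph, lib, null_pseudogenes = 2000, seed = 11)
  expect_equal(nrow(st), 2)
  expect_lt(st$mw_p[st$gene == "HIT"], 1e-3)
  expect_gt(st$score[st$gene == "HIT"], 20)
  expect_gt(st$mw_p[st$gene == "NULL"], 0.05)
  expect_lt(st$score[st$gene == "NULL"], 5)
  expect_lt(st$effect[st$gene == "HIT"], 0)   # signed effect
})

test_that("gene statistics are bit-reproducible under a fixed seed", {
  set.seed(3)
  lib <- scoring_library(c("G1", "G2"), per_gene = 6, n_nc = 30)
  ph <- phen_df(lib$sgrna_id, rnorm(nrow(lib)))
  a <- gene_stats(ph, lib, null_pseudogenes = 500, seed = 99)
  b <- gene_stats(ph, lib, null_pseudogenes = 500, seed = 99)
  expect_identical(a, b)
})

test_that("activity scores normalize the strongest 3 to exactly 1", {
  lib <- scoring_library("G", per_gene = 5, n_nc = 2)
  ph <- phen_df(lib$sgrna_id, c(4, 3, 2, 1, 0, 0, 0))
  hits <- data.frame(gene = "G", tss_id = "p1@G", screen_id = "s1",
                     score = 30, is_hit = TRUE)
  act <- activity_scores(ph, hits, lib)
  expect_equal(sort(act$activity), sort(c(4, 3, 2, 1, 0) / 3))
  expect_equal(strongest_mean(act$activity), 1)
})

test_that("sensitizing genes also map their active guides near +1", {
  lib <- scoring_library("G", per_gene = 4, n_nc = 2)
  ph <- phen_df(lib$sgrna_id, c(-4, -3, -2, 0, 0, 0))
  hits <- data.frame(gene = "G", tss_id = "p1@G", screen_id = "s1",
                     score = 30, is_hit = TRUE)
  act <- activity_scores(ph, hits, lib)
  expect_equal(sort(act$activity), sort(c(4 / 3, 1, 2 / 3, 0)))
})

test_that("activity scores are invariant to rescaling a gene's phenotypes", {
  set.seed(5)
  lib <- scoring_library("G", per_gene = 7, n_nc = 2)
  p <- rnorm(7)
  hits <- data.frame(gene = "G", tss_id = "p1@G", screen_id = "s1",
                     score = 30, is_hit = TRUE)
  base <- activity_scores(phen_df(lib$sgrna_id, c(p, 0, 0)), hits, lib)
  for (c_ in c(-2, 0.1, 7)) {
    scaled <- activity_scores(phen_df(lib$sgrna_id, c(c_ * p, 0, 0)), hits, lib)
    expect_equal(scaled$activity, base$activity)
  }
})

test_that("a zero activity normalizer is an error", {
  lib <- scoring_library("G", per_gene = 4, n_nc = 2)
  ph <- phen_df(lib$sgrna_id, c(1, -1, 0, 0, 0, 0))
  hits <- data.frame(gene = "G", tss_id = "p1@G", screen_id = "s1",
                     score = 30, is_hit = TRUE)
  expect_error(activity_scores(ph, hits, lib), "normalizer is 0")
})

test_that("phenotype-signed Z scores orient both phenotype directions to +", {
  lib <- scoring_library(c("PROT", "SENS"), per_gene = 3, n_nc = 4)
  # controls with sd 0.5
  nc_p <- c(-0.5, -0.25, 0.25, 0.5) / sd(c(-0.5, -0.25, 0.25, 0.5)) * 0.5
  ph <- phen_df(lib$sgrna_id, c(1, 0.5, 0, -1, -0.5, 0, nc_p))
  z <- ricin_z_scores(ph, lib, c(PROT = 1, SENS = -1))
  expect_equal(z$z_signed[z$sgrna_id == "PROT_01"], 2)
  expect_equal(z$z_signed[z$sgrna_id == "SENS_01"], 2)
  expect_error(ricin_z_scores(ph, lib, c(PROT = 1)), "missing expected sign")
  ph0 <- phen_df(lib$sgrna_id, c(1, 0.5, 0, -1, -0.5, 0, rep(0.3, 4)))
  expect_error(ricin_z_scores(ph0, lib, c(PROT = 1, SENS = -1)),
               "zero variance")
})
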