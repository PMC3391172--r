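test_that("simulations are fully determined by config + seed", {
  cfg <- sim_stage_config(n_genes = 120, n_replicates = 4, seed = 77)
  s1 <- simulate_stage_set(cfg)
  s2 <- simulate_stage_set(cfg)
  expect_identical(s1$stages, s2$stages)
  expect_identical(s1$annotation, s2$annotation)
  s3 <- simulate_stage_set(sim_stage_config(n_genes = 120, n_replicates = 4,
                                            seed = 78))
  expect_false(identical(s1$stages[[1]]$A, s3$stages[[1]]$A))

  pc <- sim_panel_config(n_genes = 150, seed = 5)
  p1 <- simulate_tissue_panel(pc)
  p2 <- simulate_tissue_panel(pc)
  expect_identical(p1$panel$signals, p2$panel$signals)
  expect_identical(p1$panel$calls, p2$panel$calls)
  expect_identical(p1$truth$specific, p2$truth$specific)
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_stage_config(var_among = -1), "non-negative")
  expect_error(sim_stage_config(x_fraction = 1.2), "fractions")
  expect_error(sim_stage_config(stage_labels = c("A", "A")), "unique")
  expect_error(sim_panel_config(specific_fold = 1), "exceed 1")
  expect_error(sim_panel_config(tissues = c("head", "gut")),
               "testis and ovary")
})

test_that("zero within-replicate variance collapses replicates", {
  sim <- simulate_stage_set(sim_stage_config(
    n_genes = 50, n_replicates = 6, stage_labels = "4thF",
    var_within = 0, x_shift = 0, seed = 2))
  A <- sim$stages[[1]]$A
  expect_true(all(A == A[, 1]))
  expect_equal(unname(pairwise_correlations(A)), rep(1, choose(6, 2)))
})

test_that("realized variance components converge to the configured ones", {
  sim <- simulate_stage_set(sim_stage_config(
    n_genes = 10000, n_replicates = 10, stage_labels = "4thF",
    var_among = 1.3, var_within = 0.6, x_shift = 0, seed = 41))
  v <- variance_components(sim$stages[[1]])
  expect_equal(v$var_among, 1.3, tolerance = 0.05)
  expect_equal(v$var_within, 0.6, tolerance = 0.05)
})

test_that("default stage config encodes the study-like error profile", {
  cfg <- sim_stage_config()
  expect_equal(cfg$n_genes, 14000)
  expect_equal(cfg$n_replicates, 10)
  expect_equal(cfg$stage_labels, STAGE_LABELS)
  # var_within/(var_within+var_among) equals the stated per-stage percents
  expect_equal(100 * cfg$var_within / (cfg$var_within + cfg$var_among),
               unname(c(29.7, 33.3, 24.9, 23.9, 26.5, 32.2, 44.2)),
               tolerance = 1e-10)
  expect_equal(cfg$x_shift, c(0, 0, 0, 0, -0.5, -0.5, -0.5))
})

test_that("planted ratio-specific genes are recovered by classification", {
  sim <- simulate_tissue_panel(sim_panel_config(
    n_genes = 3000, specific_fraction = 0.02, specific_fold = 12,
    absent_fraction = 0, sexbias_coupling = 0, seed = 13))
  calls <- classify_specific(sim$panel)
  for (tis in sim$truth$tissues) {
    rec10 <- calls$gene_id[calls$tissue == tis & calls$min_ratio > 10]
    expect_true(all(sim$truth$specific[[tis]] %in% rec10))
  }
})

test_that("planted presence/absence sets are recovered exactly under
           clean call separation", {
  sim <- simulate_tissue_panel(sim_panel_config(
    n_genes = 1200, call_threshold = 0.01, call_flip_prob = 0,
    seed = 3))
  pa <- presence_absence_specific(sim$panel)
  planted <- unlist(sim$truth$pa_specific, use.names = FALSE)
  expect_setequal(pa$gene_id, planted)
  for (tis in sim$truth$tissues)
    expect_setequal(pa$gene_id[pa$tissue == tis],
                    sim$truth$pa_specific[[tis]])
})

test_that("planted testis-bias coupling shows up in the sex-bias calls", {
  sim <- simulate_tissue_panel(sim_panel_config(
    n_genes = 4000, sexbias_coupling = 0.5, seed = 21))
  sx <- sex_bias_panel(sim$panel)
  tb <- sx$gene_id[sx$class == "testis-biased"]
  expect_true(all(sim$truth$testis_biased %in% tb))
})

test_that("simulations round-trip through the canonical files", {
  dir <- tempfile()
  sim <- simulate_stage_set(sim_stage_config(n_genes = 25, n_replicates = 3,
                                             seed = 10))
  write_simulation(sim, dir)
  back <- read_stage_expression(file.path(dir, "expression.tsv"))
  expect_equal(unname(back[["Adult"]]$A), unname(sim$stages[["Adult"]]$A),
               tolerance = 1e-12)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$linkage_class, sim$annotation$linkage_class)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(truth$on_x, sim$annotation$chromosome == "X")

  psim <- simulate_tissue_panel(sim_panel_config(n_genes = 20, seed = 1))
  write_simulation(psim, dir)
  pback <- read_tissue_panel(file.path(dir, "panel.tsv"))
  expect_equal(pback$signals, psim$panel$signals, tolerance = 1e-10)
})
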