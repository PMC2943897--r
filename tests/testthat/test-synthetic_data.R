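planted_default <- data.frame(ligand = "LIGA", receptor = "RECA", rho = 0.9,
                              delta_l = 2, delta_r = 2, group = "both",
                              stringsAsFactors = FALSE)

test_that("identical seeds reproduce the compendium exactly; seeds differ across datasets", {
  cfg <- simulation_config(seed = 77, n_null_pairs = 5,
                           planted_pairs = planted_default)
  c1 <- simulate_compendium(cfg)
  c2 <- simulate_compendium(cfg)
  for (d in seq_along(c1$datasets))
    expect_identical(c1$datasets[[d]]$exprs, c2$datasets[[d]]$exprs)
  # different datasets draw from distinct streams
  common <- intersect(rownames(c1$datasets[[2]]$exprs), rownames(c1$datasets[[3]]$exprs))
  expect_false(isTRUE(all.equal(c1$datasets[[2]]$exprs[common, 1],
                                c1$datasets[[3]]$exprs[common, 1])))
  # and a different master seed changes everything
  c3 <- simulate_compendium(simulation_config(seed = 78, n_null_pairs = 5,
                                              planted_pairs = planted_default))
  expect_false(identical(c1$datasets[[1]]$exprs, c3$datasets[[1]]$exprs))
})

test_that("the noise-free limit gives exact planted correlation", {
  planted <- data.frame(ligand = "LIGA", receptor = "RECA", rho = 1,
                        delta_l = 0, delta_r = 0, group = "both")
  cfg <- simulation_config(seed = 9, n_datasets = 1, n_pairs = 10,
                           n_unpaired_tumor = 0, n_null_pairs = 1,
                           sigma = 0, probe_sd = 0, planted_pairs = planted)
  comp <- simulate_compendium(cfg)
  ds <- comp$datasets[[1]]
  E <- log2(ds$exprs)
  tum <- ds$annotations$sample_id[ds$annotations$tissue == "tumor"]
  expect_equal(cor(E["LIGA", tum], E["RECA", tum]), 1, tolerance = 1e-12)
})

test_that("a planted log2 fold change shifts paired differences by delta", {
  reps <- 20
  d_bar <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- simulation_config(seed = 300 + i, n_datasets = 1, n_pairs = 16,
                             n_unpaired_tumor = 0, n_null_pairs = 1,
                             probe_sd = 0, planted_pairs = planted_default)
    comp <- simulate_compendium(cfg)
    v <- get_values(comp$datasets[[1]], "LIGA", "paired")
    d_bar[i] <- mean(v$tumor - v$normal)
  }
  expect_lt(abs(mean(d_bar) - 2), 0.15)
})

test_that("multi-probe genes, platform masks and unpaired tumors are honored", {
  cfg <- simulation_config(
    seed = 55, n_datasets = 2, n_pairs = c(4, 5), n_unpaired_tumor = c(3, 0),
    n_null_pairs = 2, probe_multiplicity = c(LIGA = 3),
    planted_pairs = planted_default,
    platform_masks = list(c("LIGA", "RECA", "NLIG001", "NREC001"),
                          c("LIGA", "RECA", "NLIG001", "NREC001",
                            "NLIG002", "NREC002"))
  )
  comp <- simulate_compendium(cfg)
  ds1 <- comp$datasets[[1]]
  expect_equal(sum(ds1$probe_map$gene == "LIGA"), 3)
  expect_equal(nrow(ds1$exprs), 3 + 3)      # 3 LIGA probes + 3 single-probe genes
  expect_equal(nrow(comp$datasets[[2]]$exprs), 3 + 5)
  # unpaired tumors exist but do not pair
  expect_equal(sum(ds1$annotations$tissue == "tumor"), 7)
  expect_equal(nrow(ds1$pairs), 4)

  # masks that remove every planted pair warn
  cfg_bad <- simulation_config(
    seed = 56, n_datasets = 1, n_pairs = 4, n_unpaired_tumor = 0,
    n_null_pairs = 2, planted_pairs = planted_default,
    platform_masks = list(c("NLIG001", "NREC001"))
  )
  expect_warning(simulate_compendium(cfg_bad), "planted")
})

test_that("invalid configurations are rejected", {
  bad <- planted_default; bad$rho <- 1.5
  expect_error(simulation_config(seed = 1, planted_pairs = bad), "rho")
  expect_error(simulation_config(seed = 1, sigma = -1), ">= 0")
  expect_error(simulation_config(), "seed")
})

test_that("fixture bundles round-trip exactly and record the seed", {
  cfg <- simulation_config(seed = 123, n_datasets = 2, n_pairs = c(4, 5),
                           n_unpaired_tumor = 0, n_null_pairs = 3,
                           planted_pairs = planted_default)
  comp <- simulate_compendium(cfg)
  dir <- withr::local_tempdir()
  man <- write_fixture_bundle(comp, dir)
  expect_equal(man$seed, 123)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  bundle <- load_fixture_bundle(dir)
  expect_equal(bundle$seed, 123)
  expect_equal(length(bundle$datasets), 2)
  for (d in 1:2)
    expect_equal(bundle$datasets[[d]]$exprs, comp$datasets[[d]]$exprs,
                 tolerance = 0)
  expect_equal(as.data.frame(bundle$catalog), as.data.frame(comp$catalog),
               ignore_attr = TRUE)
  expect_equal(bundle$truth$pairs$rho, comp$truth$pairs$rho)
})

test_that("a null compendium rarely yields qualified probes at default thresholds", {
  qualified_frac <- numeric(25)
  for (i in seq_len(25)) {
    cfg <- simulation_config(seed = 9000 + i, n_datasets = 5,
                             n_pairs = rep(8, 5), n_unpaired_tumor = 0,
                             n_null_pairs = 20)
    comp <- simulate_compendium(cfg)
    res <- suppressMessages(run_lr_pipeline(comp$datasets, comp$catalog,
                                            bypass_screen = TRUE))
    qualified_frac[i] <- res$summary$n_qualified_probes / res$summary$n_probes_tested
  }
  expect_lt(mean(qualified_frac), 0.01)
})
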