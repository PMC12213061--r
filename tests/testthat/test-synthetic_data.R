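reg <- load_registry()

test_that("zero-noise adenine simulation round-trips through the count route", {
  cfg <- simulation_config(strain_ids = reg$strain_id, adenine_cv = 0, seed = 1)
  meas <- simulate_adenine(cfg, reg, 2.574e8)
  conc <- genomes_from_adenine_count(meas, reg)
  expect_equal(conc$copies_per_ml, rep(2.574e8, nrow(conc)), tolerance = 1e-12)
  # spot value: E. coli at its worked concentration gives ~1e-9 mol/mL adenine
  ec <- meas$adenine_mol_per_ml[meas$strain_id == "NBRC 3301"][1]
  expect_equal(ec, 2.574e8 / 2.574106e8 * 1e-9, tolerance = 1e-6)
})

test_that("zero-noise cytometry simulation round-trips exactly", {
  cfg <- simulation_config(strain_ids = reg$strain_id, cytometry_cv = 0, seed = 1)
  meas <- simulate_cytometry(cfg, reg, 1e12)
  conc <- cells_from_cytometry(meas)
  expect_equal(conc$copies_per_ml, rep(1e12, nrow(conc)), tolerance = 1e-12)
})

test_that("identical config and seed give identical simulated tables", {
  cfg <- simulation_config(strain_ids = reg$strain_id[1:5], seed = 99)
  expect_identical(simulate_adenine(cfg, reg, 1e12), simulate_adenine(cfg, reg, 1e12))
  expect_identical(simulate_ddpcr(cfg), simulate_ddpcr(cfg))
  expect_identical(simulate_sequencing(cfg, registry = reg),
                   simulate_sequencing(cfg, registry = reg))
  st1 <- simulate_study(cfg, reg)
  st2 <- simulate_study(cfg, reg)
  expect_identical(st1$abundance, st2$abundance)
  # a different seed changes the draws
  cfg2 <- simulation_config(strain_ids = reg$strain_id[1:5], seed = 100)
  expect_false(identical(simulate_adenine(cfg2, reg, 1e12),
                         simulate_adenine(cfg, reg, 1e12)))
})

test_that("lognormal channel noise realises the configured CV", {
  cfg <- simulation_config(strain_ids = c("NBRC 3301", "NBRC 13719"),
                           adenine_cv = 0.05, n_replicates = 5000, seed = 2)
  meas <- simulate_adenine(cfg, reg, 1e12)
  x <- meas$adenine_mol_per_ml[meas$strain_id == "NBRC 3301"]
  expect_gte(sd(x) / mean(x), 0.045)
  expect_lte(sd(x) / mean(x), 0.055)
})

test_that("simulated ddPCR wells behave like binomial droplet counts", {
  ids <- c("A", "B")
  toy <- toy_registry(ids)
  # lambda 0.2 / 0.1: fractions should average 2/3 across seeded runs
  fr <- sapply(1:200, function(s) {
    cfg <- simulation_config(strain_ids = ids,
                             true_fractions = c(A = 2 / 3, B = 1 / 3),
                             template_copies_per_ul = 0.3 / (0.85e-3),
                             n_replicates = 1, seed = s)
    ab <- abundance_from_ddpcr(simulate_ddpcr(cfg))
    ab$fraction[ab$strain_id == "A"]
  })
  expect_lt(abs(mean(fr) - 2 / 3), 0.01)

  # a zero-fraction strain never fires a droplet
  cfg0 <- simulation_config(strain_ids = ids, true_fractions = c(A = 1, B = 0),
                            seed = 3)
  wells <- simulate_ddpcr(cfg0)
  expect_true(all(wells$positive_droplets[wells$strain_id == "B"] == 0))

  # saturating configurations are rejected up front
  cfg_sat <- simulation_config(strain_ids = ids, template_copies_per_ul = 2e4,
                               seed = 3)
  expect_mf_error(simulate_ddpcr(cfg_sat), "mockforge_schema_error")
})

test_that("simulated sequencing recovers truth and responds to extraction bias", {
  ids <- reg$strain_id
  cfg <- simulation_config(strain_ids = ids, sequencing_depth = 1e6, seed = 4)
  cts <- simulate_sequencing(cfg, registry = reg)
  ab <- abundance_from_counts(cts[[1]])
  expect_true(all(abs(ab$fraction - 1 / 15) < 0.005))

  # halving one strain's extraction efficiency halves its recovered share
  # (closed form in the deterministic limit)
  biased <- simulation_config(strain_ids = ids,
                              extraction_bias = c("NBRC 3301" = 0.5),
                              assay_stochastic = FALSE, seed = 4)
  ab_b <- abundance_from_counts(simulate_sequencing(biased, registry = reg)[[1]])
  expected <- (1 / 15) * 0.5 / ((14 / 15) + (1 / 15) * 0.5)
  expect_equal(ab_b$fraction[ab_b$strain_id == "NBRC 3301"], expected,
               tolerance = 1e-12)

  # zero depth propagates a no-signal error through the readout
  zero <- simulation_config(strain_ids = ids, sequencing_depth = 0, seed = 4)
  expect_mf_error(abundance_from_counts(simulate_sequencing(zero, registry = reg)[[1]]),
                  "mockforge_no_data_error")
})

test_that("simulate_study with zero noise recovers the design perfectly", {
  cfg <- simulation_config(strain_ids = reg$strain_id, adenine_cv = 0,
                           cytometry_cv = 0, assay_stochastic = FALSE, seed = 5)
  st <- simulate_study(cfg, reg)
  expect_equal(max(st$qc$cv$cv_percent), 0)
  expect_equal(st$qc$afd$afd, rep(1, nrow(st$qc$afd)), tolerance = 1e-9)
  # recipes are the textbook defaults: 26.667 uL per strain at 1e12 stocks
  expect_equal(unname(st$recipes[["cell_hplc/B1"]]$per_strain_volume_ul),
               rep(4e10 / 15 * 1e4 / 1e12, 15), tolerance = 1e-9)
})

test_that("lower enumeration noise gives a better-ranked mock", {
  cfg <- simulation_config(strain_ids = reg$strain_id, seed = 6)
  st <- simulate_study(cfg, reg)
  cv_h <- st$qc$cv$cv_percent[st$qc$cv$condition == "cell_hplc"]
  cv_f <- st$qc$cv$cv_percent[st$qc$cv$condition == "cell_fcm"]
  expect_lt(median(cv_h), median(cv_f))
  tests <- st$qc$tests
  expect_lt(tests$p[tests$metric == "cv"], 0.05)
})
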