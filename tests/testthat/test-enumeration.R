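reg <- load_registry()

adenine_meas <- function(strain_id = "NBRC 3301", adenine = 1e-9, dilution = 1) {
  data.frame(strain_id = strain_id, adenine_mol_per_ml = adenine,
             dilution_factor = dilution, stringsAsFactors = FALSE)
}

test_that("count route converts adenine to genome copies", {
  out <- genomes_from_adenine_count(adenine_meas(), reg)
  expect_s3_class(out, "genome_concentration")
  expect_equal(out$copies_per_ml, 2.574106e8, tolerance = 1e-6)
  expect_equal(out$basis, "genomes")
  expect_equal(out$method, "adenine_hplc")

  # constructed identity: adenine for exactly one genome/mL at GC = 0.5
  toy <- toy_registry("T1", 1e6, 50)
  one <- genomes_from_adenine_count(adenine_meas("T1", 5e5 / MF_AVOGADRO), toy)
  expect_equal(one$copies_per_ml, 1.0)

  expect_equal(genomes_from_adenine_count(adenine_meas(adenine = 0), reg)$copies_per_ml, 0)
})

test_that("mass route matches the step-by-step dNMP computation", {
  out <- genomes_from_adenine_mass(adenine_meas(), reg)
  expect_equal(out$copies_per_ml, 2.55044e8, tolerance = 1e-5)
  expect_equal(genomes_from_adenine_mass(adenine_meas(adenine = 0), reg)$copies_per_ml, 0)

  # with pair sums forced to 660 the two routes are algebraically identical
  m660 <- dnmp_masses(damp = 330, dtmp = 330, dgmp = 330, dcmp = 330)
  expect_equal(genomes_from_adenine_mass(adenine_meas(), reg, m660)$copies_per_ml,
               genomes_from_adenine_count(adenine_meas(), reg)$copies_per_ml)
})

test_that("count and mass routes agree within 2% across the GC range", {
  gcs <- seq(0.25, 0.70, by = 0.05)
  toy <- toy_registry(paste0("G", seq_along(gcs)), 3e6, gcs * 100)
  meas <- adenine_meas(toy$strain_id, 1e-9)
  count <- genomes_from_adenine_count(meas, toy)$copies_per_ml
  mass <- genomes_from_adenine_mass(meas, toy)$copies_per_ml
  expect_true(all(abs(mass / count - 1) < 0.02))
})

test_that("cytometry bead-ratio counting matches the worked mass balance", {
  meas <- data.frame(strain_id = "X", cell_events = 8000, bead_events = 800,
                     bead_stock_per_ml = 1e8, bead_spike_ratio = 1 / 100,
                     dilution_factor = 1000)
  out <- cells_from_cytometry(meas)
  expect_equal(out$copies_per_ml, 1e10, tolerance = 1e-12)
  expect_equal(out$basis, "cells")

  meas$cell_events <- 0
  expect_equal(cells_from_cytometry(meas)$copies_per_ml, 0)

  # identity event ratio: cells = stock * spike * dilution (exact mass balance)
  meas$cell_events <- 800
  expect_equal(cells_from_cytometry(meas)$copies_per_ml, 1e8 * 0.01 * 1000)

  meas$bead_events <- 0
  expect_mf_error(cells_from_cytometry(meas), "mockforge_no_data_error")
})

test_that("microscopy field counts scale by filter geometry and volume", {
  meas <- data.frame(strain_id = "X", field_counts = I(list(rep(40, 30))),
                     field_area_mm2 = 0.01, filter_area_mm2 = 100,
                     volume_filtered_ml = 0.1, dilution_factor = 1000)
  expect_equal(cells_from_microscopy(meas)$copies_per_ml, 4e9)

  meas$field_counts <- I(list(rep(0, 30)))
  expect_equal(cells_from_microscopy(meas)$copies_per_ml, 0)

  ident <- data.frame(strain_id = "X", field_counts = "1",
                      field_area_mm2 = 1, filter_area_mm2 = 1,
                      volume_filtered_ml = 1, dilution_factor = 1)
  expect_equal(cells_from_microscopy(ident)$copies_per_ml, 1)

  meas$field_counts <- I(list(numeric(0)))
  expect_mf_error(cells_from_microscopy(meas), "mockforge_insufficient_data")
  meas$field_counts <- I(list(1))
  meas$field_area_mm2 <- 200
  expect_mf_error(cells_from_microscopy(meas), "mockforge_domain_error")
})

test_that("OD normalisation divides and records the OD", {
  conc <- genomes_from_adenine_count(adenine_meas(), reg)
  conc$copies_per_ml <- 2e9
  expect_equal(normalize_to_od(conc, 2)$copies_per_ml, 1e9)
  expect_equal(normalize_to_od(conc, 1)$copies_per_ml, conc$copies_per_ml)
  expect_equal(normalize_to_od(conc, 2)$od600, 2)
  expect_equal(normalize_to_od(genomes_from_adenine_count(adenine_meas(), reg),
                               0.5)$copies_per_ml,
               5.148213e8, tolerance = 1e-6)
  expect_mf_error(normalize_to_od(conc, 0), "mockforge_domain_error")
})

test_that("all conversions are linear in the raw signal and dilutions compose", {
  # doubling the raw measurement doubles the output, for every channel
  base_a <- genomes_from_adenine_count(adenine_meas(adenine = 2e-9), reg)
  expect_equal(base_a$copies_per_ml,
               2 * genomes_from_adenine_count(adenine_meas(), reg)$copies_per_ml)
  cyt <- data.frame(strain_id = "X", cell_events = 4000, bead_events = 800,
                    bead_stock_per_ml = 1e8, bead_spike_ratio = 0.01,
                    dilution_factor = 10)
  cyt2 <- cyt; cyt2$cell_events <- 8000
  expect_equal(cells_from_cytometry(cyt2)$copies_per_ml,
               2 * cells_from_cytometry(cyt)$copies_per_ml)
  mic <- data.frame(strain_id = "X", field_counts = "10,20,30",
                    field_area_mm2 = 0.01, filter_area_mm2 = 10,
                    volume_filtered_ml = 1, dilution_factor = 10)
  mic2 <- mic; mic2$field_counts <- "20,40,60"
  expect_equal(cells_from_microscopy(mic2)$copies_per_ml,
               2 * cells_from_microscopy(mic)$copies_per_ml)

  # dilution d1 then d2 == dilution d1 * d2
  d12 <- genomes_from_adenine_count(adenine_meas(dilution = 50), reg)$copies_per_ml
  d1 <- genomes_from_adenine_count(adenine_meas(dilution = 5), reg)$copies_per_ml
  expect_equal(d12, d1 * 10)
})

test_that("replicate aggregation summarises concentrations, not raw signals", {
  meas <- adenine_meas(rep("NBRC 3301", 3), c(0.9e-9, 1.0e-9, 1.1e-9))
  meas$replicate_id <- paste0("R", 1:3)
  conc <- genomes_from_adenine_count(meas, reg)
  agg <- aggregate_concentrations(conc)
  expect_equal(agg$n, 3L)
  expect_equal(agg$mean_copies_per_ml, mean(conc$copies_per_ml))
  expect_equal(agg$sd_copies_per_ml, sd(conc$copies_per_ml))
})

test_that("invalid dilution factors and unknown strains are rejected", {
  expect_mf_error(genomes_from_adenine_count(adenine_meas(dilution = 0.5), reg),
                  "mockforge_domain_error")
  expect_mf_error(genomes_from_adenine_count(adenine_meas("nope"), reg),
                  "mockforge_consistency_error")
})
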