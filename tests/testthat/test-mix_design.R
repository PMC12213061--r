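reg <- load_registry()

cell_stocks <- function(ids, conc = 1e12, available = Inf) {
  data.frame(strain_id = ids, copies_per_ml = conc, available_ml = available,
             stringsAsFactors = FALSE)
}

test_that("cell-mock recipe reproduces the worked 3-strain mass balance", {
  ids <- c("A", "B", "C")
  design <- mock_design("cell", ids, target_total_copies_per_ml = 3e9)
  recipe <- design_cell_mock(cell_stocks(ids, 1e11), design)
  expect_equal(unname(recipe$per_strain_volume_ul), rep(100, 3))
  expect_equal(recipe$diluent_volume_ul, 9700)
  expect_equal(recipe$total_volume_ul, 10000)
})

test_that("default 15-strain cell mock hits 26.67 uL per strain", {
  design <- mock_design("cell", reg$strain_id)
  recipe <- design_cell_mock(cell_stocks(reg$strain_id), design)
  expect_equal(unname(recipe$per_strain_volume_ul), rep(4e10 / 15 * 1e4 / 1e12, 15))
  expect_equal(unname(recipe$per_strain_volume_ul[1]), 26.6667, tolerance = 1e-5)
  expect_equal(sum(recipe$achieved), 4e10)
})

test_that("infeasible and insufficient-stock designs fail with named errors", {
  ids <- c("A", "B")
  per_strain <- mock_design("cell", ids, target_total_copies_per_ml = 1e10,
                            concentration_mode = "per_strain")
  expect_mf_error(design_cell_mock(cell_stocks(ids, 5e9), per_strain),
                  "mockforge_infeasible_error")
  # enough concentration but not enough volume: names the offending strain
  st <- cell_stocks(ids, c(1e12, 1e12), available = c(Inf, 1e-6))
  err <- tryCatch(design_cell_mock(st, mock_design("cell", ids)), error = identity)
  expect_s3_class(err, "mockforge_insufficient_stock")
  expect_match(conditionMessage(err), "B")
  # missing stock for a design strain
  expect_mf_error(design_cell_mock(cell_stocks("A"), mock_design("cell", ids)),
                  "mockforge_consistency_error")
})

test_that("dna_copies_per_ul converts mass to genome molarity", {
  expect_equal(dna_copies_per_ul(10, registry_record(reg, "NBRC 3301")),
               1.9189e6, tolerance = 1e-4)
  expect_equal(dna_copies_per_ul(10, registry_record(reg, "NBRC 3202")),
               4.7765e6, tolerance = 1e-4)
  expect_equal(dna_copies_per_ul(0, registry_record(reg, "NBRC 3301")), 0)
})

test_that("dna-mock recipe is equimolar with mass proportional to genome size", {
  toy <- toy_registry(c("S1", "S2"), c(1e6, 2e6))
  stocks <- data.frame(strain_id = c("S1", "S2"), ng_per_ul = 100, available_ml = Inf)
  design <- mock_design("dna", c("S1", "S2"),
                        aliquot_volume_ul = 20, aliquot_count = 50)  # 1 mL batch
  recipe <- design_dna_mock(stocks, design, toy)
  expect_equal(unname(recipe$achieved[c("S1", "S2")]), c(50 / 3, 100 / 3))
  expect_equal(unname(recipe$per_strain_volume_ul[c("S1", "S2")]),
               c(500 / 3, 1000 / 3))
  expect_equal(recipe$diluent_volume_ul, 500)
  # identical strains get identical volumes by symmetry
  sym <- toy_registry(c("T1", "T2", "T3"), 2e6)
  sym_stocks <- data.frame(strain_id = sym$strain_id, ng_per_ul = 100, available_ml = Inf)
  sym_recipe <- design_dna_mock(sym_stocks, mock_design("dna", sym$strain_id), sym)
  expect_equal(length(unique(round(sym_recipe$per_strain_volume_ul, 9))), 1L)
})

test_that("15-strain dna mock: finals proportional to genome size, equimolar, 50 ng/uL", {
  stocks <- data.frame(strain_id = reg$strain_id, ng_per_ul = 200, available_ml = Inf)
  recipe <- design_dna_mock(stocks, mock_design("dna", reg$strain_id), reg)
  finals <- recipe$achieved[reg$strain_id]
  expect_equal(sum(finals), 50)
  expect_equal(unname(finals / reg$genome_size_bp),
               rep(50 / sum(reg$genome_size_bp), 15))
  molar <- dna_copies_per_ul(unname(finals), reg)
  expect_true(max(abs(molar / molar[1] - 1)) < 1e-9)
})

test_that("verify_recipe passes a valid recipe and catches a perturbed one", {
  design <- mock_design("cell", reg$strain_id)
  stocks <- cell_stocks(reg$strain_id)
  recipe <- design_cell_mock(stocks, design)
  v <- verify_recipe(recipe, stocks, design)
  expect_true(v$pass)
  expect_equal(sum(v$per_strain$achieved), 4e10)

  bad <- recipe
  bad$per_strain_volume_ul[["NBRC 3301"]] <- bad$per_strain_volume_ul[["NBRC 3301"]] * 1.1
  bad$diluent_volume_ul <- bad$total_volume_ul - sum(bad$per_strain_volume_ul)
  v2 <- verify_recipe(bad, stocks, design)
  expect_false(v2$pass)
  expect_match(paste(v2$messages, collapse = " "), "NBRC 3301")

  # empty recipe against an empty design passes vacuously
  empty <- structure(list(kind = "cell", per_strain_volume_ul = numeric(0),
                          diluent_volume_ul = 0, total_volume_ul = 0,
                          achieved = numeric(0)), class = "mock_recipe")
  expect_true(verify_recipe(empty, cell_stocks(character(0)), NULL)$pass)
})

test_that("recipes conserve volume and scale inversely with stock concentration", {
  for (n in c(2, 5, 15)) {
    ids <- paste0("S", seq_len(n))
    design <- mock_design("cell", ids, target_total_copies_per_ml = 4e10)
    conc <- 10^seq(11.5, 12.5, length.out = n)
    r1 <- design_cell_mock(cell_stocks(ids, conc), design)
    expect_equal(sum(r1$per_strain_volume_ul) + r1$diluent_volume_ul,
                 r1$total_volume_ul)
    # copy conservation: achieved * total volume == stock * pipetted volume
    expect_equal(unname(r1$achieved * r1$total_volume_ul),
                 unname(conc * r1$per_strain_volume_ul))
    r2 <- design_cell_mock(cell_stocks(ids, 2 * conc), design)
    expect_equal(unname(r2$per_strain_volume_ul),
                 unname(r1$per_strain_volume_ul) / 2)
  }
})

test_that("design constructor rejects bad geometry", {
  expect_mf_error(mock_design("cell", "only-one"), "mockforge_schema_error")
  expect_mf_error(mock_design("cell", c("A", "A")), "mockforge_schema_error")
  expect_mf_error(mock_design("cell", c("A", "B"), target_total_copies_per_ml = -1),
                  "mockforge_domain_error")
})
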