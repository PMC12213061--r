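# Mixing-recipe design for cell mocks (equal genome copies per strain) and
# DNA mocks (equimolar genomes at a target total mass concentration).

#' Describe a mock community design
#'
#' Captures the batch geometry and targets of a mock community. Defaults
#' reproduce the reference production batches: cell mocks are mixed at a
#' community concentration of 4e10 copies/mL and dispensed as 100 aliquots
#' of 100 uL; DNA mocks are adjusted to 50 ng/uL total and dispensed as 50
#' aliquots of 30 uL.
#'
#' The sentence "mixed at 4e10 per mL" is ambiguous between a community
#' total and a per-strain level; `concentration_mode` makes the choice
#' explicit (default `"total"`, i.e. each of n strains is targeted at
#' `target_total_copies_per_ml / n`).
#'
#' @param kind `"cell"` or `"dna"`.
#' @param strain_ids At least two strain identifiers.
#' @param target_total_copies_per_ml Cell-mock concentration target,
#'   copies/mL (default 4e10).
#' @param concentration_mode `"total"` (target is the community sum) or
#'   `"per_strain"` (target applies to every strain individually).
#' @param aliquot_volume_ul,aliquot_count Batch geometry; defaults 100 uL x
#'   100 (cell) or 30 uL x 50 (dna).
#' @param target_total_ng_per_ul DNA-mock total mass concentration target
#'   (default 50 ng/uL).
#' @param dead_volume_ul Extra volume prepared beyond the dispensed
#'   aliquots (default 0).
#' @return A `mock_design` object.
#' @export
mock_design <- function(kind = c("cell", "dna"), strain_ids,
                        target_total_copies_per_ml = 4e10,
                        concentration_mode = c("total", "per_strain"),
                        aliquot_volume_ul = NULL, aliquot_count = NULL,
                        target_total_ng_per_ul = 50,
                        dead_volume_ul = 0) {
  kind <- match.arg(kind)
  concentration_mode <- match.arg(concentration_mode)
  strain_ids <- as.character(strain_ids)
  if (length(strain_ids) < 2L)
    mf_stop("a mock design needs at least two strains", "mockforge_schema_error")
  if (anyDuplicated(strain_ids))
    mf_stop("duplicated strain_id in design", "mockforge_schema_error")
  aliquot_volume_ul <- aliquot_volume_ul %||% if (kind == "cell") 100 else 30
  aliquot_count <- aliquot_count %||% if (kind == "cell") 100L else 50L
  if (aliquot_volume_ul <= 0 || aliquot_count < 1 || dead_volume_ul < 0)
    mf_stop("aliquot geometry must be positive", "mockforge_domain_error")
  if (target_total_copies_per_ml <= 0 || target_total_ng_per_ul <= 0)
    mf_stop("concentration targets must be positive", "mockforge_domain_error")
  structure(list(kind = kind, strain_ids = strain_ids,
                 target_total_copies_per_ml = target_total_copies_per_ml,
                 concentration_mode = concentration_mode,
                 aliquot_volume_ul = aliquot_volume_ul,
                 aliquot_count = as.integer(aliquot_count),
                 target_total_ng_per_ul = target_total_ng_per_ul,
                 dead_volume_ul = dead_volume_ul),
            class = "mock_design")
}

design_total_volume_ul <- function(design) {
  design$aliquot_volume_ul * design$aliquot_count + design$dead_volume_ul
}

new_recipe <- function(kind, per_strain_volume_ul, diluent_volume_ul,
                       total_volume_ul, achieved) {
  r <- structure(list(kind = kind,
                      per_strain_volume_ul = per_strain_volume_ul,
                      diluent_volume_ul = diluent_volume_ul,
                      total_volume_ul = total_volume_ul,
                      achieved = achieved),
                 class = "mock_recipe")
  vol_sum <- sum(per_strain_volume_ul) + diluent_volume_ul
  if (total_volume_ul > 0 &&
      abs(vol_sum - total_volume_ul) > 1e-6 * total_volume_ul)
    mf_stop("recipe volumes do not conserve total volume", "mockforge_consistency_error")
  r
}

#' @export
print.mock_recipe <- function(x, ...) {
  cat(sprintf("%s-mock recipe: %d strains, total %.4f uL (diluent %.4f uL)\n",
              x$kind, length(x$per_strain_volume_ul), x$total_volume_ul,
              x$diluent_volume_ul))
  unit <- if (x$kind == "cell") "copies/mL" else "ng/uL"
  df <- data.frame(strain_id = names(x$per_strain_volume_ul),
                   volume_ul = round(unname(x$per_strain_volume_ul), 4),
                   achieved = signif(unname(x$achieved[names(x$per_strain_volume_ul)]), 6))
  names(df)[3] <- paste0("achieved_", if (x$kind == "cell") "copies_per_ml" else "ng_per_ul")
  print(df, row.names = FALSE)
  invisible(x)
}

check_stocks <- function(stocks, design, conc_col) {
  stopifnot_cols(stocks, c("strain_id", conc_col, "available_ml"), "stock table")
  if (anyDuplicated(stocks$strain_id))
    mf_stop("duplicated strain_id in stock table", "mockforge_schema_error")
  missing <- setdiff(design$strain_ids, stocks$strain_id)
  if (length(missing) > 0L)
    mf_stop(sprintf("no stock for design strain(s): %s",
                    paste(missing, collapse = ", ")), "mockforge_consistency_error")
  if (any(stocks[[conc_col]] <= 0) || any(stocks$available_ml <= 0))
    mf_stop("stock concentrations and volumes must be positive", "mockforge_domain_error")
  stocks[match(design$strain_ids, stocks$strain_id), , drop = FALSE]
}

#' Design a cell-mock mixing recipe
#'
#' Computes per-strain pipette volumes so that every strain contributes the
#' same number of cells/genomes to the batch, with diluent filling to the
#' total batch volume. Targets are a mass balance: `volume_i =
#' per_strain_target * total_volume / stock_concentration_i`.
#'
#' @param stocks Data frame with `strain_id`, `copies_per_ml` (> 0, from an
#'   enumeration method plus the dilution/condensation bookkeeping of the
#'   glycerol stock) and `available_ml`.
#' @param design A `mock_design` of kind `"cell"`.
#' @return A `mock_recipe` with per-strain volumes (uL), diluent volume and
#'   achieved per-strain concentrations.
#' @examples
#' reg <- load_registry()
#' stocks <- data.frame(strain_id = reg$strain_id, copies_per_ml = 1e12,
#'                      available_ml = 5)
#' design <- mock_design("cell", reg$strain_id)
#' design_cell_mock(stocks, design)
#' @export
design_cell_mock <- function(stocks, design) {
  stopifnot(inherits(design, "mock_design"))
  if (design$kind != "cell")
    mf_stop("design_cell_mock needs a design of kind 'cell'", "mockforge_consistency_error")
  stocks <- check_stocks(stocks, design, "copies_per_ml")
  n <- length(design$strain_ids)
  total_ul <- design_total_volume_ul(design)
  per_target <- switch(design$concentration_mode,
                       total = design$target_total_copies_per_ml / n,
                       per_strain = design$target_total_copies_per_ml)
  vol_ul <- per_target * total_ul / stocks$copies_per_ml
  diluent <- total_ul - sum(vol_ul)
  if (diluent < -1e-9 * total_ul)
    mf_stop("stocks too dilute: strain volumes exceed the batch volume",
            "mockforge_infeasible_error")
  too_little <- vol_ul / 1000 > stocks$available_ml
  if (any(too_little))
    mf_stop(sprintf("insufficient stock for strain(s): %s",
                    paste(stocks$strain_id[too_little], collapse = ", ")),
            "mockforge_insufficient_stock")
  diluent <- max(diluent, 0)
  achieved <- stocks$copies_per_ml * vol_ul / total_ul
  names(vol_ul) <- names(achieved) <- stocks$strain_id
  new_recipe("cell", vol_ul, diluent, total_ul, achieved)
}

#' Genome copies per microlitre of a DNA solution
#'
#' Converts a mass concentration to a genome molar (copy) concentration via
#' the genome size and the 660 g/mol/bp duplex convention:
#' `copies/uL = ng_per_ul * 1e-9 / genome_mass_grams`.
#'
#' @param ng_per_ul Mass concentration, ng/uL, >= 0.
#' @param record Registry row(s) for the strain.
#' @return Numeric vector, genome copies per uL.
#' @examples
#' reg <- load_registry()
#' dna_copies_per_ul(10, registry_record(reg, "NBRC 3301"))  # ~1.919e6
#' @export
dna_copies_per_ul <- function(ng_per_ul, record) {
  if (any(ng_per_ul < 0))
    mf_stop("ng_per_ul must be >= 0", "mockforge_domain_error")
  ng_per_ul * 1e-9 / genome_mass_grams(record)
}

#' Design a DNA-mock mixing recipe (equimolar genomes)
#'
#' Equimolar genomes means each strain's final *mass* concentration must be
#' proportional to its genome size; the proportionality is scaled so the
#' total equals the target mass concentration (default 50 ng/uL), and
#' volumes follow by mass balance from the stock concentrations.
#'
#' @param stocks Data frame with `strain_id`, `ng_per_ul` (> 0) and
#'   `available_ml`.
#' @param design A `mock_design` of kind `"dna"`.
#' @param registry A `strain_registry` providing genome sizes.
#' @return A `mock_recipe` with achieved per-strain ng/uL; the implied
#'   genome molarities are identical across strains.
#' @export
design_dna_mock <- function(stocks, design, registry) {
  stopifnot(inherits(design, "mock_design"))
  if (design$kind != "dna")
    mf_stop("design_dna_mock needs a design of kind 'dna'", "mockforge_consistency_error")
  stocks <- check_stocks(stocks, design, "ng_per_ul")
  rec <- registry_record(registry, design$strain_ids)
  total_ul <- design_total_volume_ul(design)
  final_ng <- design$target_total_ng_per_ul * rec$genome_size_bp / sum(rec$genome_size_bp)
  vol_ul <- final_ng * total_ul / stocks$ng_per_ul
  diluent <- total_ul - sum(vol_ul)
  if (diluent < -1e-9 * total_ul)
    mf_stop("stocks too dilute: strain volumes exceed the batch volume",
            "mockforge_infeasible_error")
  too_little <- vol_ul / 1000 > stocks$available_ml
  if (any(too_little))
    mf_stop(sprintf("insufficient stock for strain(s): %s",
                    paste(stocks$strain_id[too_little], collapse = ", ")),
            "mockforge_insufficient_stock")
  diluent <- max(diluent, 0)
  achieved <- stocks$ng_per_ul * vol_ul / total_ul
  names(vol_ul) <- names(achieved) <- stocks$strain_id
  new_recipe("dna", vol_ul, diluent, total_ul, achieved)
}

#' Verify a recipe by independent mass balance
#'
#' Recomputes what each strain's concentration in the batch would be from
#' the raw volumes and stock concentrations (not from the recipe's own
#' `achieved` field), compares against the design targets, and reports a
#' pass/fail at relative tolerance 1e-6 per strain plus volume conservation.
#'
#' @param recipe A `mock_recipe`.
#' @param stocks The stock table the recipe was built from.
#' @param design The `mock_design` the recipe was built for.
#' @param registry Required for `"dna"` recipes (genome sizes).
#' @param tol Relative tolerance (default 1e-6).
#' @return A `recipe_verification` list: `pass` flag, per-strain table with
#'   targets, recomputed values and relative errors, and failure messages.
#' @export
verify_recipe <- function(recipe, stocks, design, registry = NULL, tol = 1e-6) {
  stopifnot(inherits(recipe, "mock_recipe"))
  strain_ids <- names(recipe$per_strain_volume_ul)
  design_ids <- if (is.null(design)) character() else design$strain_ids
  if (length(strain_ids) == 0L && length(design_ids) == 0L) {
    return(structure(list(pass = TRUE, per_strain = data.frame(), messages = character()),
                     class = "recipe_verification"))
  }
  if (!setequal(strain_ids, design_ids))
    mf_stop("recipe and design cover different strain sets", "mockforge_consistency_error")
  conc_col <- if (recipe$kind == "cell") "copies_per_ml" else "ng_per_ul"
  stocks <- check_stocks(stocks, design, conc_col)
  vol <- recipe$per_strain_volume_ul[stocks$strain_id]
  achieved <- stocks[[conc_col]] * vol / recipe$total_volume_ul

  n <- length(design_ids)
  target <- if (recipe$kind == "cell") {
    switch(design$concentration_mode,
           total = rep(design$target_total_copies_per_ml / n, n),
           per_strain = rep(design$target_total_copies_per_ml, n))
  } else {
    if (is.null(registry))
      mf_stop("verifying a dna recipe needs the registry", "mockforge_schema_error")
    rec <- registry_record(registry, stocks$strain_id)
    design$target_total_ng_per_ul * rec$genome_size_bp / sum(rec$genome_size_bp)
  }
  rel_err <- abs(achieved - target) / target
  msgs <- character()
  if (any(rel_err > tol))
    msgs <- c(msgs, sprintf("achieved concentration off target for strain(s): %s",
                            paste(stocks$strain_id[rel_err > tol], collapse = ", ")))
  vol_sum <- sum(vol) + recipe$diluent_volume_ul
  if (abs(vol_sum - recipe$total_volume_ul) > 1e-6 * recipe$total_volume_ul)
    msgs <- c(msgs, "volumes do not sum to the total batch volume")
  structure(list(pass = length(msgs) == 0L,
                 per_strain = data.frame(strain_id = stocks$strain_id,
                                         volume_ul = unname(vol),
                                         target = target,
                                         achieved = achieved,
                                         rel_error = rel_err,
                                         stringsAsFactors = FALSE),
                 messages = msgs),
            class = "recipe_verification")
}
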