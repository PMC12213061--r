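# Enumeration: raw adenine-HPLC / flow-cytometry / microscopy measurements
# -> genome or cell concentrations of the initial cell resuspension.

#' Deoxyribonucleoside monophosphate molar masses
#'
#' Masses (g/mol) used by the mass-route adenine conversion. Defaults are the
#' free-acid dNMP masses; their A:T and G:C pair sums (~654 g/mol) sit just
#' below the conventional 660 g/mol/bp duplex value, which is why the count
#' route and mass route differ by about 1%.
#'
#' @param damp,dtmp,dgmp,dcmp Molar masses in g/mol, all positive.
#' @return A `dnmp_masses` list.
#' @export
dnmp_masses <- function(damp = 331.22, dtmp = 322.21, dgmp = 347.22, dcmp = 307.20) {
  m <- list(damp = damp, dtmp = dtmp, dgmp = dgmp, dcmp = dcmp)
  if (any(unlist(m) <= 0))
    mf_stop("all dNMP masses must be positive", "mockforge_domain_error")
  class(m) <- "dnmp_masses"
  m
}

new_genome_concentration <- function(strain_id, replicate_id, copies_per_ml,
                                     method, basis, od600 = NA_real_) {
  stopifnot(method %in% c("adenine_hplc", "flow_cytometry", "microscopy"))
  stopifnot(basis %in% c("genomes", "cells"))
  if (method == "adenine_hplc" && any(basis != "genomes"))
    mf_stop("adenine_hplc measures genomes, not cells", "mockforge_consistency_error")
  if (method != "adenine_hplc" && any(basis != "cells"))
    mf_stop(sprintf("%s measures cells, not genomes", method), "mockforge_consistency_error")
  if (any(copies_per_ml < 0))
    mf_stop("copies_per_ml must be >= 0", "mockforge_domain_error")
  out <- data.frame(strain_id = strain_id, replicate_id = replicate_id,
                    copies_per_ml = copies_per_ml, method = method,
                    basis = basis, od600 = od600, stringsAsFactors = FALSE)
  class(out) <- c("genome_concentration", "data.frame")
  out
}

check_meas <- function(meas, cols, what) {
  stopifnot_cols(meas, cols, what)
  if (!"replicate_id" %in% names(meas)) meas$replicate_id <- as.character(seq_len(nrow(meas)))
  if ("dilution_factor" %in% names(meas) && any(meas$dilution_factor < 1))
    mf_stop(sprintf("%s: dilution_factor must be >= 1", what), "mockforge_domain_error")
  meas
}

#' Genome concentration from an adenine-HPLC measurement (count route)
#'
#' Converts moles of adenine released by acid depurination of genomic DNA
#' directly into genome copies: each A:T base pair contributes one adenine,
#' so `copies/mL = adenine_mol_per_ml * N_A / adenines_per_genome * dilution`.
#' This is the reference route; [genomes_from_adenine_mass()] is the
#' mass-based cross-check.
#'
#' @param meas Data frame with columns `strain_id`, `adenine_mol_per_ml`
#'   (moles adenine per mL of the assayed solution), `dilution_factor`
#'   (assayed solution relative to the initial resuspension, >= 1) and
#'   optionally `replicate_id`.
#' @param registry A `strain_registry` covering all measured strains.
#' @return A `genome_concentration` data frame (`basis = "genomes"`).
#' @examples
#' reg <- load_registry()
#' m <- data.frame(strain_id = "NBRC 3301", adenine_mol_per_ml = 1e-9,
#'                 dilution_factor = 1)
#' genomes_from_adenine_count(m, reg)$copies_per_ml  # ~2.574e8
#' @export
genomes_from_adenine_count <- function(meas, registry) {
  meas <- check_meas(meas, c("strain_id", "adenine_mol_per_ml", "dilution_factor"),
                     "adenine measurement table")
  if (any(meas$adenine_mol_per_ml < 0))
    mf_stop("adenine_mol_per_ml must be >= 0", "mockforge_domain_error")
  rec <- registry_record(registry, meas$strain_id)
  apg <- adenines_per_genome(rec)
  copies <- meas$adenine_mol_per_ml * MF_AVOGADRO / apg * meas$dilution_factor
  new_genome_concentration(meas$strain_id, meas$replicate_id, copies,
                           "adenine_hplc", "genomes")
}

#' Genome concentration from an adenine-HPLC measurement (mass route)
#'
#' Converts adenine to total DNA mass via the strain's base composition and
#' the dNMP molar masses, then divides by the mass of a single genome copy.
#' With adenine nucleotide fraction `f_A = (1 - GC)/2`:
#' total nucleotide mol = adenine mol / f_A; mean nucleotide mass
#' `m = f_A (dAMP + dTMP) + (GC/2)(dGMP + dCMP)`; DNA grams = mol * m;
#' copies = grams / genome mass. Agrees with the count route to ~1%
#' (the residual comes from the 660 g/mol/bp convention vs the dNMP sums).
#'
#' @inheritParams genomes_from_adenine_count
#' @param masses A [dnmp_masses()] set.
#' @return A `genome_concentration` data frame (`basis = "genomes"`).
#' @export
genomes_from_adenine_mass <- function(meas, registry, masses = dnmp_masses()) {
  meas <- check_meas(meas, c("strain_id", "adenine_mol_per_ml", "dilution_factor"),
                     "adenine measurement table")
  if (any(meas$adenine_mol_per_ml < 0))
    mf_stop("adenine_mol_per_ml must be >= 0", "mockforge_domain_error")
  stopifnot(inherits(masses, "dnmp_masses"))
  rec <- registry_record(registry, meas$strain_id)
  gc <- rec$gc_fraction
  if (any(gc <= 0 | gc >= 1))
    mf_stop("gc_fraction must lie strictly between 0 and 1", "mockforge_degenerate_error")
  f_a <- (1 - gc) / 2
  total_nt_mol <- meas$adenine_mol_per_ml / f_a
  mean_nt_mass <- f_a * (masses$damp + masses$dtmp) + (gc / 2) * (masses$dgmp + masses$dcmp)
  dna_grams <- total_nt_mol * mean_nt_mass
  copies <- dna_grams / genome_mass_grams(rec) * meas$dilution_factor
  new_genome_concentration(meas$strain_id, meas$replicate_id, copies,
                           "adenine_hplc", "genomes")
}

#' Cell concentration from flow cytometry with reference beads
#'
#' Stained sample is spiked with a known volume ratio `r` (default protocol
#' 1/100) of a bead suspension of known concentration. In the measured
#' mixture the bead concentration is `bead_stock * r / (1 + r)`; cells per
#' mL of the mixture follow from the event ratio, and the factor `(1 + r)`
#' corrects back to the unspiked stained sample (a 1% effect at r = 1/100,
#' applied exactly rather than ignored).
#'
#' @param meas Data frame with columns `strain_id`, `cell_events` (>= 0),
#'   `bead_events` (> 0), `bead_stock_per_ml` (> 0), `bead_spike_ratio`
#'   (in (0, 1]), `dilution_factor` (>= 1), optionally `replicate_id`.
#'   `cell_events` may be non-integral (simulator expectations).
#' @return A `genome_concentration` data frame (`basis = "cells"`).
#' @export
cells_from_cytometry <- function(meas) {
  meas <- check_meas(meas, c("strain_id", "cell_events", "bead_events",
                             "bead_stock_per_ml", "bead_spike_ratio",
                             "dilution_factor"), "cytometry measurement table")
  if (any(meas$bead_events <= 0))
    mf_stop("bead_events must be > 0: no reference events", "mockforge_no_data_error")
  if (any(meas$cell_events < 0))
    mf_stop("cell_events must be >= 0", "mockforge_domain_error")
  if (any(meas$bead_spike_ratio <= 0 | meas$bead_spike_ratio > 1))
    mf_stop("bead_spike_ratio must lie in (0, 1]", "mockforge_domain_error")
  if (any(meas$bead_stock_per_ml <= 0))
    mf_stop("bead_stock_per_ml must be > 0", "mockforge_domain_error")
  r <- meas$bead_spike_ratio
  bead_conc_mixture <- meas$bead_stock_per_ml * r / (1 + r)
  cells_mixture <- meas$cell_events / meas$bead_events * bead_conc_mixture
  cells <- cells_mixture * (1 + r) * meas$dilution_factor
  new_genome_concentration(meas$strain_id, meas$replicate_id, cells,
                           "flow_cytometry", "cells")
}

#' Cell concentration from microscopy field counts
#'
#' Stained cells are trapped on a filter of known effective area and a known
#' volume is filtered; cells are counted in >= 30 imaged fields (arithmetic
#' mean over fields, no edge correction) and scaled by the field-to-filter
#' area ratio and the filtered volume.
#'
#' @param meas Data frame with columns `strain_id`, `field_counts` (either a
#'   list column of non-negative integer vectors or a comma-separated
#'   character column), `field_area_mm2`, `filter_area_mm2`,
#'   `volume_filtered_ml`, `dilution_factor`, optionally `replicate_id`.
#' @return A `genome_concentration` data frame (`basis = "cells"`).
#' @export
cells_from_microscopy <- function(meas) {
  meas <- check_meas(meas, c("strain_id", "field_counts", "field_area_mm2",
                             "filter_area_mm2", "volume_filtered_ml",
                             "dilution_factor"), "microscopy measurement table")
  counts <- meas$field_counts
  if (!is.list(counts)) {
    counts <- lapply(as.character(counts), function(s) {
      as_num_checked(strsplit(s, ",", fixed = TRUE)[[1L]], "field_counts",
                     "microscopy measurement table")
    })
  }
  n_fields <- vapply(counts, length, integer(1))
  if (any(n_fields < 1L))
    mf_stop("each microscopy measurement needs at least one field",
            "mockforge_insufficient_data")
  if (any(unlist(counts) < 0))
    mf_stop("field counts must be >= 0", "mockforge_domain_error")
  if (any(meas$field_area_mm2 <= 0 | meas$filter_area_mm2 <= 0 |
          meas$volume_filtered_ml <= 0))
    mf_stop("areas and filtered volume must be > 0", "mockforge_domain_error")
  if (any(meas$field_area_mm2 > meas$filter_area_mm2))
    mf_stop("field_area_mm2 cannot exceed filter_area_mm2", "mockforge_domain_error")
  mean_counts <- vapply(counts, mean, numeric(1))
  cells <- mean_counts * (meas$filter_area_mm2 / meas$field_area_mm2) /
    meas$volume_filtered_ml * meas$dilution_factor
  new_genome_concentration(meas$strain_id, meas$replicate_id, cells,
                           "microscopy", "cells")
}

#' Normalise a concentration to one OD600 unit
#'
#' Divides the concentration by the measured optical density of the
#' suspension so counts from differently dense cultures are comparable;
#' the OD is recorded on the result.
#'
#' @param conc A `genome_concentration` data frame.
#' @param od600 Measured OD600 of the suspension(s), > 0; recycled.
#' @return The concentration table, rescaled, with `od600` set.
#' @export
normalize_to_od <- function(conc, od600) {
  stopifnot(inherits(conc, "genome_concentration"))
  if (any(od600 <= 0))
    mf_stop("od600 must be > 0", "mockforge_domain_error")
  conc$copies_per_ml <- conc$copies_per_ml / od600
  conc$od600 <- od600
  conc
}

#' Aggregate replicate concentrations
#'
#' Summarises a concentration table to mean, sample standard deviation and
#' replicate count per (strain, method). Aggregation happens on the
#' converted concentrations, never on the raw signals.
#'
#' @param conc A `genome_concentration` data frame.
#' @return Data frame with columns `strain_id`, `method`, `basis`,
#'   `mean_copies_per_ml`, `sd_copies_per_ml`, `n`.
#' @export
aggregate_concentrations <- function(conc) {
  stopifnot(inherits(conc, "genome_concentration"))
  key <- interaction(conc$strain_id, conc$method, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(conc)), key), function(i) {
    x <- conc$copies_per_ml[i]
    data.frame(strain_id = conc$strain_id[i[1L]], method = conc$method[i[1L]],
               basis = conc$basis[i[1L]], mean_copies_per_ml = mean(x),
               sd_copies_per_ml = if (length(x) >= 2L) stats::sd(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
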