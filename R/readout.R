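# Readout: ddPCR droplet counts and shotgun-sequencing count tables ->
# per-strain relative abundances comparable to the theoretical design.

#' Poisson mean template copies per droplet
#'
#' In droplet digital PCR the sample is partitioned into ~20,000 droplets;
#' template molecules distribute approximately Poisson, so the fraction of
#' PCR-negative droplets estimates `exp(-lambda)` and
#' `lambda = -ln(1 - positive/total)`.
#'
#' @param positive_droplets Fluorescence-positive droplet count(s), in
#'   `[0, total)`; may be non-integral (simulator expectations).
#' @param total_droplets Total accepted droplets, > 0.
#' @return Mean template copies per droplet (vectorised).
#' @examples
#' ddpcr_lambda(2000, 20000)  # -log(0.9) = 0.105361
#' @export
ddpcr_lambda <- function(positive_droplets, total_droplets) {
  if (any(total_droplets <= 0))
    mf_stop("total_droplets must be > 0", "mockforge_no_data_error")
  if (any(positive_droplets < 0 | positive_droplets > total_droplets))
    mf_stop("positive_droplets must lie in [0, total_droplets]", "mockforge_domain_error")
  if (any(positive_droplets == total_droplets))
    mf_stop("all droplets positive: reaction saturated, lambda undefined",
            "mockforge_saturation_error")
  -log(1 - positive_droplets / total_droplets)
}

check_wells <- function(wells) {
  wells <- stopifnot_cols(wells, c("strain_id", "total_droplets", "positive_droplets"),
                          "ddPCR well table")
  if (!"droplet_volume_nl" %in% names(wells)) wells$droplet_volume_nl <- 0.85
  if (!"template_dilution_factor" %in% names(wells)) wells$template_dilution_factor <- 1
  if (!"probe_copies_per_genome" %in% names(wells)) wells$probe_copies_per_genome <- 1L
  if (!"batch_id" %in% names(wells)) wells$batch_id <- "B1"
  if (!"replicate_id" %in% names(wells)) wells$replicate_id <- "R1"
  if (any(wells$droplet_volume_nl <= 0))
    mf_stop("droplet_volume_nl must be > 0", "mockforge_domain_error")
  if (any(wells$template_dilution_factor < 1))
    mf_stop("template_dilution_factor must be >= 1", "mockforge_domain_error")
  if (any(wells$probe_copies_per_genome < 1))
    mf_stop("probe_copies_per_genome must be >= 1", "mockforge_domain_error")
  wells
}

#' Genome-equivalent template concentration from a ddPCR well
#'
#' Scales the Poisson estimate by droplet volume (default 0.85 nL,
#' instrument-nominal), undoes the template dilution and divides by the
#' probe copies per genome so multi-copy targets report genome equivalents:
#' `copies/uL = lambda / (droplet_volume_nl * 1e-3) * dilution / probe_copies`.
#'
#' @param wells Data frame with columns `strain_id`, `total_droplets`,
#'   `positive_droplets` and optionally `droplet_volume_nl` (default 0.85),
#'   `template_dilution_factor` (default 1), `probe_copies_per_genome`
#'   (default 1), `batch_id`, `replicate_id`.
#' @return The well table with a `copies_per_ul` column appended.
#' @export
ddpcr_concentration <- function(wells) {
  wells <- check_wells(wells)
  lam <- ddpcr_lambda(wells$positive_droplets, wells$total_droplets)
  wells$copies_per_ul <- lam / (wells$droplet_volume_nl * 1e-3) *
    wells$template_dilution_factor / wells$probe_copies_per_genome
  wells
}

#' Relative abundances from ddPCR wells
#'
#' Within each (batch, replicate) group — one well per strain — the
#' genome-equivalent concentrations are normalised to fractions summing
#' to 1.
#'
#' @inheritParams ddpcr_concentration
#' @param condition Optional label carried onto the output (e.g. which
#'   preparation method produced the assayed mock).
#' @return An abundance data frame with columns `strain_id`, `batch_id`,
#'   `replicate_id`, `assay` (`"ddpcr"`), `condition`, `fraction`.
#' @export
abundance_from_ddpcr <- function(wells, condition = NA_character_) {
  wells <- check_wells(wells)
  key <- interaction(wells$batch_id, wells$replicate_id, drop = TRUE)
  out <- lapply(split(seq_len(nrow(wells)), key), function(i) {
    g <- wells[i, , drop = FALSE]
    dup <- g$strain_id[duplicated(g$strain_id)]
    if (length(dup) > 0L)
      mf_stop(sprintf("strain measured twice in batch %s replicate %s: %s",
                      g$batch_id[1L], g$replicate_id[1L], paste(dup, collapse = ", ")),
              "mockforge_schema_error")
    conc <- ddpcr_concentration(g)$copies_per_ul
    total <- sum(conc)
    if (total <= 0)
      mf_stop(sprintf("all wells negative in batch %s replicate %s",
                      g$batch_id[1L], g$replicate_id[1L]), "mockforge_no_data_error")
    data.frame(strain_id = g$strain_id, batch_id = g$batch_id,
               replicate_id = g$replicate_id, assay = "ddpcr",
               condition = condition, fraction = conc / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Read a pseudoalignment count table
#'
#' Parses the kallisto `abundance.tsv` layout (`target_id`, `length`,
#' `eff_length`, `est_counts`, `tpm`), maps sequence targets to strains via
#' a user-supplied two-column mapping (multiple targets per strain, e.g.
#' replicons, are summed) and attaches genome lengths from the registry.
#'
#' @param path Path to the tab-separated abundance file.
#' @param mapping Data frame (or path to a tab-separated file) with columns
#'   `target_id`, `strain_id`.
#' @param registry A `strain_registry` covering the mapped strains.
#' @param batch_id,replicate_id Labels attached to the resulting table.
#' @return A `count_table` data frame with columns `strain_id`,
#'   `mapped_count`, `genome_length_bp`, `batch_id`, `replicate_id`.
#' @export
read_count_table <- function(path, mapping, registry,
                             batch_id = "B1", replicate_id = "R1") {
  ab <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(ab, c("target_id", "est_counts"), "abundance file")
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- utils::read.delim(mapping, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  stopifnot_cols(mapping, c("target_id", "strain_id"), "target mapping")
  idx <- match(ab$target_id, mapping$target_id)
  if (anyNA(idx))
    mf_stop(sprintf("unmapped target_id(s): %s",
                    paste(ab$target_id[is.na(idx)], collapse = ", ")),
            "mockforge_schema_error")
  strain <- mapping$strain_id[idx]
  counts <- as_num_checked(ab$est_counts, "est_counts", "abundance file")
  if (any(counts < 0))
    mf_stop("est_counts must be >= 0", "mockforge_domain_error")
  summed <- tapply(counts, strain, sum)
  rec <- registry_record(registry, names(summed))
  out <- data.frame(strain_id = names(summed),
                    mapped_count = as.numeric(summed),
                    genome_length_bp = rec$genome_size_bp,
                    batch_id = batch_id, replicate_id = replicate_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("count_table", "data.frame")
  out
}

#' Relative abundances from a count table
#'
#' `genome_normalized` (default) divides counts by genome length before
#' normalising, putting shotgun abundances on the same genome-copy basis as
#' ddPCR; `raw` normalises the counts as-is (read-mass basis).
#'
#' @param table A `count_table` (columns `strain_id`, `mapped_count`,
#'   `genome_length_bp`, and optionally `batch_id`, `replicate_id`);
#'   multiple (batch, replicate) groups are normalised independently.
#' @param mode `"genome_normalized"` or `"raw"`.
#' @param condition Optional label carried onto the output.
#' @return An abundance data frame (`assay = "shotgun"`), fractions summing
#'   to 1 within each (batch, replicate).
#' @export
abundance_from_counts <- function(table, mode = c("genome_normalized", "raw"),
                                  condition = NA_character_) {
  mode <- match.arg(mode)
  table <- stopifnot_cols(table, c("strain_id", "mapped_count", "genome_length_bp"),
                          "count table")
  if (!"batch_id" %in% names(table)) table$batch_id <- "B1"
  if (!"replicate_id" %in% names(table)) table$replicate_id <- "R1"
  if (any(table$genome_length_bp <= 0))
    mf_stop("genome_length_bp must be > 0", "mockforge_domain_error")
  key <- interaction(table$batch_id, table$replicate_id, drop = TRUE)
  out <- lapply(split(seq_len(nrow(table)), key), function(i) {
    g <- table[i, , drop = FALSE]
    w <- switch(mode,
                genome_normalized = g$mapped_count / g$genome_length_bp,
                raw = g$mapped_count)
    if (sum(w) <= 0)
      mf_stop(sprintf("all counts zero in batch %s replicate %s",
                      g$batch_id[1L], g$replicate_id[1L]), "mockforge_no_data_error")
    data.frame(strain_id = g$strain_id, batch_id = g$batch_id,
               replicate_id = g$replicate_id, assay = "shotgun",
               condition = condition, fraction = w / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Validate and bind abundance tables
#'
#' Checks that fractions within every (condition, assay, batch, replicate)
#' group sum to 1 within 1e-9 and binds the pieces into one
#' `abundance_table`.
#'
#' @param ... Abundance data frames as produced by [abundance_from_ddpcr()]
#'   or [abundance_from_counts()].
#' @return A validated `abundance_table`.
#' @export
abundance_table <- function(...) {
  tab <- do.call(rbind, lapply(list(...), as.data.frame))
  tab <- stopifnot_cols(tab, c("strain_id", "batch_id", "replicate_id",
                               "assay", "fraction"), "abundance table")
  if (!"condition" %in% names(tab)) tab$condition <- NA_character_
  if (any(tab$fraction < 0 | tab$fraction > 1))
    mf_stop("fractions must lie in [0, 1]", "mockforge_domain_error")
  # paste-based key: interaction() would silently drop NA conditions
  key <- paste(tab$condition, tab$assay, tab$batch_id, tab$replicate_id, sep = "\r")
  sums <- tapply(tab$fraction, key, sum)
  if (any(abs(sums - 1) > 1e-9))
    mf_stop("fractions must sum to 1 within every (condition, assay, batch, replicate) group",
            "mockforge_consistency_error")
  class(tab) <- c("abundance_table", "data.frame")
  tab
}
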