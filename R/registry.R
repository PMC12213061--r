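#' Avogadro constant (2019 SI exact value), mol^-1
#'
#' Used in every conversion between particle counts and molar amounts.
#' @export
MF_AVOGADRO <- 6.02214076e23

#' Mean molecular weight of one duplex DNA base pair, g/mol/bp
#'
#' The conventional 660 g/mol per base pair used to convert DNA mass to
#' genome molarity.
#' @export
MF_BP_MASS <- 660

#' Load a strain registry
#'
#' A registry holds the per-strain genome facts every conversion depends on:
#' total genome size (bp, summed over replicons), GC content and 16S rRNA
#' gene copy number. The packaged default describes the 15 strains of the
#' reference cell/DNA mock communities (human symbionts plus environmental
#' bacteria spanning a wide range of GC content, genome size and cell-wall
#' type).
#'
#' GC content is *stored* as a fraction (`gc_fraction`) but *read and
#' written* as percent (`gc_percent` column), so the 100-fold conversion
#' happens exactly once, at the file boundary.
#'
#' @param source Path to a UTF-8 tab-separated registry file with header
#'   columns `name`, `strain_id`, `genome_size_bp`, `gc_percent`,
#'   `rrs_copies`, `accessions` (comma-separated) and optionally
#'   `gram_stain`. `NULL` (default) loads the packaged 15-strain fixture.
#' @return A `strain_registry` data frame with one row per strain and both
#'   `gc_percent` and derived `gc_fraction` columns.
#' @examples
#' reg <- load_registry()
#' nrow(reg)                       # 15
#' reg[reg$strain_id == "NBRC 3301", "genome_size_bp"]
#' @export
load_registry <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "table1_strains.tsv",
                          package = "mockforge", mustWork = TRUE)
  }
  raw <- utils::read.delim(source, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", strip.white = TRUE)
  stopifnot_cols(raw, c("name", "strain_id", "genome_size_bp", "gc_percent",
                        "rrs_copies", "accessions"), "registry file")
  size <- as_num_checked(raw$genome_size_bp, "genome_size_bp", "registry file")
  gc_pct <- as_num_checked(raw$gc_percent, "gc_percent", "registry file")
  rrs <- as_num_checked(raw$rrs_copies, "rrs_copies", "registry file")

  bad <- which(size < 1 | size != round(size))
  if (length(bad) > 0L)
    mf_stop(sprintf("registry row %d ('%s'): genome_size_bp must be a positive integer",
                    bad[1L], raw$strain_id[bad[1L]]), "mockforge_schema_error")
  bad <- which(gc_pct <= 0 | gc_pct >= 100)
  if (length(bad) > 0L)
    mf_stop(sprintf("registry row %d ('%s'): gc_percent must lie strictly between 0 and 100",
                    bad[1L], raw$strain_id[bad[1L]]), "mockforge_schema_error")
  bad <- which(rrs < 1 | rrs != round(rrs))
  if (length(bad) > 0L)
    mf_stop(sprintf("registry row %d ('%s'): rrs_copies must be a positive integer",
                    bad[1L], raw$strain_id[bad[1L]]), "mockforge_schema_error")
  dup <- raw$strain_id[duplicated(raw$strain_id)]
  if (length(dup) > 0L)
    mf_stop(sprintf("duplicated strain_id in registry: %s",
                    paste(unique(dup), collapse = ", ")), "mockforge_schema_error")

  gram <- if ("gram_stain" %in% names(raw)) raw$gram_stain else rep(NA_character_, nrow(raw))
  gram[!nzchar(gram %||% "")] <- NA_character_
  ok <- is.na(gram) | gram %in% c("positive", "negative", "unknown")
  if (!all(ok))
    mf_stop(sprintf("registry row %d: gram_stain must be positive/negative/unknown",
                    which(!ok)[1L]), "mockforge_schema_error")

  reg <- data.frame(
    name = raw$name,
    strain_id = raw$strain_id,
    genome_size_bp = size,
    gc_percent = gc_pct,
    gc_fraction = gc_pct / 100,
    rrs_copies = rrs,
    accessions = raw$accessions,
    gram_stain = gram,
    stringsAsFactors = FALSE
  )
  class(reg) <- c("strain_registry", "data.frame")
  reg
}

#' Write a strain registry to a tab-separated file
#'
#' Inverse of [load_registry()]: GC is written back as percent. A written
#' registry reloads with all fields identical.
#'
#' @param registry A `strain_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "strain_registry"))
  out <- registry[, c("name", "strain_id", "genome_size_bp", "gc_percent",
                      "rrs_copies", "accessions", "gram_stain")]
  write_tsv(out, path)
  invisible(path)
}

#' Look up one strain in a registry
#'
#' @param registry A `strain_registry`.
#' @param strain_id Collection identifier, matched exactly.
#' @return The matching one-row data frame.
#' @export
registry_record <- function(registry, strain_id) {
  i <- match(strain_id, registry$strain_id)
  if (anyNA(i))
    mf_stop(sprintf("strain_id not in registry: %s",
                    paste(strain_id[is.na(i)], collapse = ", ")),
            "mockforge_consistency_error")
  registry[i, , drop = FALSE]
}

#' Adenine residues per duplex genome
#'
#' In duplex DNA every A:T pair carries exactly one adenine, so a genome of
#' `L` bp with GC fraction `g` contains `L * (1 - g)` adenine residues.
#' This is the divisor that turns a molar adenine measurement into a genome
#' count.
#'
#' @param record A registry row (or any list/data frame with
#'   `genome_size_bp` and `gc_fraction`). Vectorised over rows.
#' @return Numeric vector of adenine residues per genome copy.
#' @examples
#' reg <- load_registry()
#' adenines_per_genome(registry_record(reg, "NBRC 3301"))  # 2,339,507.2
#' @export
adenines_per_genome <- function(record) {
  gc <- record$gc_fraction
  if (any(gc >= 1))
    mf_stop("gc_fraction >= 1: genome would contain no adenine", "mockforge_degenerate_error")
  if (any(gc <= 0))
    mf_stop("gc_fraction must lie strictly between 0 and 1", "mockforge_domain_error")
  record$genome_size_bp * (1 - gc)
}

#' Mass of a single genome copy, grams
#'
#' Uses the conventional 660 g/mol per duplex base pair and the exact
#' Avogadro constant: `genome_size_bp * 660 / N_A`.
#'
#' @inheritParams adenines_per_genome
#' @return Numeric vector, grams per genome copy.
#' @examples
#' reg <- load_registry()
#' genome_mass_grams(registry_record(reg, "NBRC 3301"))  # ~5.21e-15 g
#' @export
genome_mass_grams <- function(record) {
  L <- record$genome_size_bp
  if (any(L < 1))
    mf_stop("genome_size_bp must be >= 1", "mockforge_domain_error")
  L * MF_BP_MASS / MF_AVOGADRO
}
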