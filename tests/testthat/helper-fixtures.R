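# Fixture builders shared across the suite. Everything is generated in code;
# the only file fixture is the packaged 15-strain registry.

# a minimal registry built through the real loader so invariants apply
toy_registry <- function(strain_id = c("S1", "S2"),
                         genome_size_bp = c(1e6, 2e6),
                         gc_percent = 50,
                         rrs_copies = 1) {
  df <- data.frame(name = paste("Strain", strain_id), strain_id = strain_id,
                   genome_size_bp = rep_len(genome_size_bp, length(strain_id)),
                   gc_percent = rep_len(gc_percent, length(strain_id)),
                   rrs_copies = rep_len(rrs_copies, length(strain_id)),
                   accessions = paste0("ACC", seq_along(strain_id)),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_tsv(df, path)
  load_registry(path)
}

# an abundance table where every group is exactly the given fractions
perfect_abundance <- function(fractions, batches = paste0("B", 1:3),
                              replicates = paste0("R", 1:3),
                              assay = "ddpcr", condition = "cond") {
  grid <- expand.grid(strain_id = names(fractions), batch_id = batches,
                      replicate_id = replicates, stringsAsFactors = FALSE)
  grid$assay <- assay
  grid$condition <- condition
  grid$fraction <- fractions[grid$strain_id]
  grid
}

expect_mf_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
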