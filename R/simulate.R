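# Seeded simulator of every measurement type the pipeline consumes, so
# enumeration -> design -> readout -> QC is testable end to end with no
# external data.

#' Simulation configuration
#'
#' Describes a simulated mock-community study: which strains, the true
#' composition, the batch/replicate structure (default 3 batches x
#' triplicate assays, the reference production design) and per-channel
#' noise levels.
#'
#' Noise models: continuous measurements (adenine, cytometry) get
#' multiplicative lognormal noise with unit mean and the stated CV —
#' concentrations are positive, so additive Gaussian noise would be wrong
#' at the tails; discrete channels use their natural counting distributions
#' (binomial droplets, multinomial reads). Channel CV defaults (adenine
#' 0.03, cytometry 0.15) encode the qualitative finding the simulator is
#' built to reproduce: genome counting by adenine-HPLC is markedly more
#' reproducible than event counting by flow cytometry.
#'
#' A single root `seed` deterministically derives independent per-channel
#' substreams, so adding a channel never perturbs the draws of another.
#'
#' @param strain_ids Strains to simulate (default: all 15 packaged strains).
#' @param true_fractions Named true composition; default uniform 1/n.
#' @param n_batches,n_replicates Batch and within-batch replicate counts
#'   (defaults 3 and 3).
#' @param adenine_cv,cytometry_cv Multiplicative noise CVs of the two
#'   enumeration channels (defaults 0.03 and 0.15).
#' @param droplet_total Accepted droplets per ddPCR well (default 20000).
#' @param droplet_volume_nl Droplet volume, nL (default 0.85).
#' @param template_copies_per_ul Total template concentration loaded into
#'   ddPCR (default 3500 copies/uL, putting per-strain lambda near 0.2 for
#'   a 15-strain mock — mid Poisson range, far from saturation).
#' @param sequencing_depth Reads per shotgun replicate (default 1e6).
#' @param extraction_bias Optional named multiplicative bias applied to
#'   each strain's template share (models differential DNA extraction,
#'   e.g. by cell-wall strength); default none.
#' @param stock_copies_per_ml True concentration of every simulated
#'   glycerol stock (default 1e12 copies/mL).
#' @param assay_stochastic If `FALSE`, ddPCR and sequencing return exact
#'   expected values instead of random draws (used for zero-noise
#'   round-trip identities).
#' @param seed Root seed (integer).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(strain_ids = NULL, true_fractions = NULL,
                              n_batches = 3L, n_replicates = 3L,
                              adenine_cv = 0.03, cytometry_cv = 0.15,
                              droplet_total = 20000L, droplet_volume_nl = 0.85,
                              template_copies_per_ul = 3500,
                              sequencing_depth = 1e6,
                              extraction_bias = NULL,
                              stock_copies_per_ml = 1e12,
                              assay_stochastic = TRUE,
                              seed = 1L) {
  if (is.null(strain_ids)) strain_ids <- load_registry()$strain_id
  strain_ids <- as.character(strain_ids)
  n <- length(strain_ids)
  if (n < 2L)
    mf_stop("simulation needs at least two strains", "mockforge_schema_error")
  if (is.null(true_fractions)) {
    true_fractions <- stats::setNames(rep(1 / n, n), strain_ids)
  } else {
    if (!setequal(names(true_fractions), strain_ids))
      mf_stop("true_fractions names must match strain_ids", "mockforge_consistency_error")
    true_fractions <- true_fractions[strain_ids]
    if (abs(sum(true_fractions) - 1) > 1e-9)
      mf_stop("true_fractions must sum to 1", "mockforge_domain_error")
  }
  if (adenine_cv < 0 || cytometry_cv < 0)
    mf_stop("noise CVs must be >= 0", "mockforge_domain_error")
  if (n_batches < 1L || n_replicates < 1L)
    mf_stop("n_batches and n_replicates must be >= 1", "mockforge_domain_error")
  bias <- stats::setNames(rep(1, n), strain_ids)
  if (!is.null(extraction_bias)) {
    unknown <- setdiff(names(extraction_bias), strain_ids)
    if (length(unknown) > 0L)
      mf_stop(sprintf("extraction_bias for unknown strain(s): %s",
                      paste(unknown, collapse = ", ")), "mockforge_consistency_error")
    if (any(extraction_bias < 0))
      mf_stop("extraction_bias must be >= 0", "mockforge_domain_error")
    bias[names(extraction_bias)] <- extraction_bias
  }
  structure(list(strain_ids = strain_ids, true_fractions = true_fractions,
                 n_batches = as.integer(n_batches),
                 n_replicates = as.integer(n_replicates),
                 adenine_cv = adenine_cv, cytometry_cv = cytometry_cv,
                 droplet_total = as.integer(droplet_total),
                 droplet_volume_nl = droplet_volume_nl,
                 template_copies_per_ul = template_copies_per_ul,
                 sequencing_depth = sequencing_depth,
                 extraction_bias = bias,
                 stock_copies_per_ml = stock_copies_per_ml,
                 assay_stochastic = isTRUE(assay_stochastic),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic 31-bit substream seed from (root seed, channel label)
substream_seed <- function(seed, channel) {
  h <- (seed %% 2147483647) + 1
  for (c in utf8ToInt(channel)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# unit-mean lognormal multipliers with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate adenine-HPLC measurements
#'
#' Inverts the count-route conversion: the noiseless adenine amount of a
#' stock at `true_copies_per_ml` is `copies * adenines_per_genome / N_A`
#' (at dilution 1), and replicates receive unit-mean lognormal noise with
#' CV `adenine_cv`. At zero noise the round trip through
#' [genomes_from_adenine_count()] is the identity.
#'
#' @param config A [simulation_config()].
#' @param registry Registry covering the configured strains.
#' @param true_copies_per_ml True stock concentration(s), recycled over
#'   strains.
#' @param stream Extra label mixed into the random substream (used by
#'   [simulate_study()] to separate conditions/batches).
#' @return Adenine measurement data frame ready for
#'   [genomes_from_adenine_count()].
#' @export
simulate_adenine <- function(config, registry, true_copies_per_ml,
                             stream = "") {
  stopifnot(inherits(config, "simulation_config"))
  rec <- registry_record(registry, config$strain_ids)
  copies <- rep_len(true_copies_per_ml, nrow(rec))
  apg <- adenines_per_genome(rec)
  nrep <- config$n_replicates
  base <- rep(copies * apg / MF_AVOGADRO, each = nrep)
  noise <- with_seed(substream_seed(config$seed, paste0("adenine/", stream)),
                     lognormal_noise(length(base), config$adenine_cv))
  data.frame(strain_id = rep(rec$strain_id, each = nrep),
             replicate_id = rep(paste0("R", seq_len(nrep)), times = nrow(rec)),
             adenine_mol_per_ml = base * noise,
             dilution_factor = 1, stringsAsFactors = FALSE)
}

#' Simulate flow-cytometry measurements
#'
#' Inverts [cells_from_cytometry()] for a fixed bead protocol (bead stock
#' 1e8/mL, 1/100 spike, 1000 bead events, 1e4-fold sample dilution) and
#' applies unit-mean lognormal noise with CV `cytometry_cv` to the cell
#' event count. The noiseless channel returns expected (possibly
#' non-integral) event counts so the zero-noise round trip is exact.
#'
#' @inheritParams simulate_adenine
#' @return Cytometry measurement data frame ready for
#'   [cells_from_cytometry()].
#' @export
simulate_cytometry <- function(config, registry, true_copies_per_ml,
                               stream = "") {
  stopifnot(inherits(config, "simulation_config"))
  rec <- registry_record(registry, config$strain_ids)
  copies <- rep_len(true_copies_per_ml, nrow(rec))
  bead_stock <- 1e8; spike <- 0.01; bead_events <- 1000; dilution <- 1e4
  nrep <- config$n_replicates
  events_true <- rep(copies * bead_events / (bead_stock * spike * dilution),
                     each = nrep)
  noise <- with_seed(substream_seed(config$seed, paste0("cytometry/", stream)),
                     lognormal_noise(length(events_true), config$cytometry_cv))
  data.frame(strain_id = rep(rec$strain_id, each = nrep),
             replicate_id = rep(paste0("R", seq_len(nrep)), times = nrow(rec)),
             cell_events = events_true * noise,
             bead_events = bead_events, bead_stock_per_ml = bead_stock,
             bead_spike_ratio = spike, dilution_factor = dilution,
             stringsAsFactors = FALSE)
}

#' Simulate ddPCR wells
#'
#' Per strain, the Poisson occupancy is `lambda_i = fraction_i *
#' total_copies_per_ul * droplet_volume_nl * 1e-3`; positive droplets are
#' drawn as `Binomial(droplet_total, 1 - exp(-lambda_i))` (or set to the
#' exact expectation when `assay_stochastic = FALSE`). Configurations
#' implying `lambda > 5` are rejected: that close to saturation the
#' estimator degenerates and a real assay would be re-diluted.
#'
#' @param config A [simulation_config()].
#' @param true_fractions Named composition of the assayed template.
#' @param total_copies_per_ul Total template concentration; default from
#'   the config.
#' @param batch_id Batch label stamped on the wells.
#' @param stream Extra substream label.
#' @return ddPCR well data frame (one well per strain per replicate) ready
#'   for [abundance_from_ddpcr()].
#' @export
simulate_ddpcr <- function(config, true_fractions = config$true_fractions,
                           total_copies_per_ul = config$template_copies_per_ul,
                           batch_id = "B1", stream = "") {
  stopifnot(inherits(config, "simulation_config"))
  f <- true_fractions[config$strain_ids]
  lambda <- f * total_copies_per_ul * config$droplet_volume_nl * 1e-3
  if (any(lambda > 5))
    mf_stop("configured template concentration saturates the droplets (lambda > 5); dilute the template",
            "mockforge_schema_error")
  nrep <- config$n_replicates
  lam_rep <- rep(lambda, each = nrep)
  p <- 1 - exp(-lam_rep)
  pos <- if (config$assay_stochastic) {
    with_seed(substream_seed(config$seed, paste0("ddpcr/", batch_id, "/", stream)),
              stats::rbinom(length(p), config$droplet_total, p))
  } else {
    config$droplet_total * p
  }
  data.frame(strain_id = rep(config$strain_ids, each = nrep),
             batch_id = batch_id,
             replicate_id = rep(paste0("R", seq_len(nrep)), times = length(f)),
             total_droplets = config$droplet_total,
             positive_droplets = pos,
             droplet_volume_nl = config$droplet_volume_nl,
             template_dilution_factor = 1, probe_copies_per_genome = 1L,
             stringsAsFactors = FALSE)
}

#' Simulate shotgun-sequencing count tables
#'
#' Reads are multinomial over strains with weights `fraction_i *
#' genome_length_i * extraction_bias_i` (longer genomes draw more reads at
#' equal copy number; extraction bias shifts the template). The
#' genome-normalised abundance of the noiseless expectation equals the
#' bias-weighted truth.
#'
#' @inheritParams simulate_ddpcr
#' @param registry Registry providing genome lengths.
#' @return List of `count_table` data frames, one per replicate.
#' @export
simulate_sequencing <- function(config, true_fractions = config$true_fractions,
                                registry, batch_id = "B1", stream = "") {
  stopifnot(inherits(config, "simulation_config"))
  rec <- registry_record(registry, config$strain_ids)
  f <- true_fractions[config$strain_ids]
  w <- f * rec$genome_size_bp * config$extraction_bias[config$strain_ids]
  w <- w / sum(w)
  nrep <- config$n_replicates
  depth <- config$sequencing_depth
  counts <- if (config$assay_stochastic && depth > 0) {
    with_seed(substream_seed(config$seed, paste0("seq/", batch_id, "/", stream)),
              stats::rmultinom(nrep, size = depth, prob = w))
  } else {
    matrix(rep(depth * w, nrep), ncol = nrep)
  }
  lapply(seq_len(nrep), function(r) {
    out <- data.frame(strain_id = config$strain_ids,
                      mapped_count = counts[, r],
                      genome_length_bp = rec$genome_size_bp,
                      batch_id = batch_id, replicate_id = paste0("R", r),
                      stringsAsFactors = FALSE)
    class(out) <- c("count_table", "data.frame")
    out
  })
}

#' Simulate a full mock-community comparison study
#'
#' End-to-end harness reproducing the reference comparison design: the same
#' strains are enumerated by two channels with different noise —
#' `cell_hplc` (adenine channel, CV `adenine_cv`) and `cell_fcm`
#' (cytometry channel, CV `cytometry_cv`) — and for each condition and
#' batch a cell-mock recipe is computed from the *estimated* stock
#' concentrations while the achieved composition follows from the *true*
#' concentrations. That gap is exactly how enumeration error becomes
#' batch-to-batch composition variability. Each batch is then read out by
#' ddPCR and simulated shotgun sequencing in `n_replicates` replicates, and
#' the pooled abundance table is QC-scored with a Welch comparison of the
#' two conditions.
#'
#' With all noise at zero (and `assay_stochastic = FALSE`) the pipeline
#' returns CV = 0 and AFD = 1 for every strain.
#'
#' @param config A [simulation_config()].
#' @param registry Registry covering the configured strains (default: the
#'   packaged registry).
#' @return A list: `config`, `true_stocks`, per-condition `recipes` and
#'   `estimated_stocks`, the pooled `abundance` table, and the `qc`
#'   report ([qc_report()]) comparing `cell_hplc` vs `cell_fcm`.
#' @export
simulate_study <- function(config, registry = load_registry()) {
  stopifnot(inherits(config, "simulation_config"))
  reg <- registry_record(registry, config$strain_ids)
  n <- length(config$strain_ids)
  true_conc <- stats::setNames(rep(config$stock_copies_per_ml, n), config$strain_ids)
  design <- mock_design("cell", config$strain_ids)
  total_ul <- design_total_volume_ul(design)

  conditions <- c("cell_hplc", "cell_fcm")
  recipes <- list(); est_stocks <- list(); ab_all <- list()
  for (cond in conditions) {
    for (b in seq_len(config$n_batches)) {
      bid <- paste0("B", b)
      stream <- paste0(cond, "/", bid)
      conc <- if (cond == "cell_hplc") {
        meas <- simulate_adenine(config, reg, true_conc, stream = stream)
        genomes_from_adenine_count(meas, reg)
      } else {
        meas <- simulate_cytometry(config, reg, true_conc, stream = stream)
        cells_from_cytometry(meas)
      }
      agg <- aggregate_concentrations(conc)
      stocks <- data.frame(strain_id = agg$strain_id,
                           copies_per_ml = agg$mean_copies_per_ml,
                           available_ml = Inf, stringsAsFactors = FALSE)
      recipe <- design_cell_mock(stocks, design)
      recipes[[paste(cond, bid, sep = "/")]] <- recipe
      est_stocks[[paste(cond, bid, sep = "/")]] <- stocks

      # achieved composition from TRUE concentrations and pipetted volumes
      vol <- recipe$per_strain_volume_ul[config$strain_ids]
      achieved <- true_conc * vol / total_ul
      frac <- achieved / sum(achieved)
      template <- frac * config$extraction_bias[config$strain_ids]
      template <- template / sum(template)

      wells <- simulate_ddpcr(config, template, batch_id = bid, stream = cond)
      ab_all[[paste(cond, bid, "ddpcr", sep = "/")]] <-
        abundance_from_ddpcr(wells, condition = cond)
      cts <- simulate_sequencing(config, template, reg, batch_id = bid, stream = cond)
      for (r in seq_along(cts)) {
        ab_all[[paste(cond, bid, "seq", r, sep = "/")]] <-
          abundance_from_counts(cts[[r]], "genome_normalized", condition = cond)
      }
    }
  }
  abundance <- do.call(abundance_table, ab_all)
  qc <- qc_report(abundance, expected_fraction = 1 / n,
                  compare = list(c("cell_hplc", "cell_fcm")))
  list(config = config, true_stocks = true_conc, recipes = recipes,
       estimated_stocks = est_stocks, abundance = abundance, qc = qc)
}
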