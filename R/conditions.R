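# Classed error conditions so callers (and the CLI) can distinguish failure modes.

mf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mockforge_error"), call = call))
}

# condition classes used throughout:
#   mockforge_schema_error        malformed or incomplete input table / config
#   mockforge_domain_error        value outside its mathematical domain
#   mockforge_degenerate_error    degenerate composition (no adenine, zero variance ...)
#   mockforge_insufficient_data   too few replicates / fields / batches
#   mockforge_saturation_error    all ddPCR droplets positive
#   mockforge_no_data_error       zero droplets / all-zero signal
#   mockforge_infeasible_error    design cannot be reached by dilution
#   mockforge_insufficient_stock  not enough stock volume for the recipe
#   mockforge_consistency_error   mismatched strain sets between artefacts

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    mf_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")),
            "mockforge_schema_error")
  }
  invisible(df)
}

as_num_checked <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad) > 0L || anyNA(out)) {
    row <- if (length(bad) > 0L) bad[1L] else which(is.na(out))[1L]
    mf_stop(sprintf("%s: column '%s' is not numeric at row %d (value '%s')",
                    what, col, row, as.character(x)[row]),
            "mockforge_schema_error")
  }
  out
}
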