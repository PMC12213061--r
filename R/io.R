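# Shared table readers/writers: UTF-8 tab-separated, header-first, empty
# field (never ".") as the missing marker, repr-precision numbers.

#' Write a data frame as a tab-separated table
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, format(x, digits = 17, scientific = NA, trim = TRUE))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return Data frame with character/numeric columns as parsed by
#'   [utils::read.delim()]; empty fields become `NA`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8",
                    na.strings = "")
}

#' Read a flat key-value configuration file
#'
#' One `key: value` (or `key = value`, or tab-separated) pair per line;
#' blank lines and `#` comments are ignored. Values that parse as numbers
#' become numeric; comma-separated values become character vectors.
#'
#' @param path Input path.
#' @return Named list.
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=\t]+)[:=\t]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      mf_stop(sprintf("cannot parse config line: '%s'", ln), "mockforge_schema_error")
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
      num <- suppressWarnings(as.numeric(val))
      if (!anyNA(num)) val <- num
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num) && nzchar(val)) val <- num
    }
    out[[key]] <- val
  }
  out
}

#' Write a mixing recipe as a tab-separated table
#'
#' One row per strain plus a `diluent` component row; columns `component`,
#' `volume_ul` and the achieved concentration (`achieved_copies_per_ml` for
#' cell recipes, `achieved_ng_per_ul` for DNA recipes).
#'
#' @param recipe A `mock_recipe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recipe <- function(recipe, path) {
  stopifnot(inherits(recipe, "mock_recipe"))
  achieved_col <- if (recipe$kind == "cell") "achieved_copies_per_ml" else "achieved_ng_per_ul"
  df <- data.frame(component = c(names(recipe$per_strain_volume_ul), "diluent"),
                   volume_ul = c(unname(recipe$per_strain_volume_ul),
                                 recipe$diluent_volume_ul),
                   achieved = c(unname(recipe$achieved[names(recipe$per_strain_volume_ul)]),
                                NA_real_),
                   stringsAsFactors = FALSE)
  names(df)[3L] <- achieved_col
  write_tsv(df, path)
  invisible(path)
}

#' Read a mixing recipe written by [write_recipe()]
#'
#' @param path Input path.
#' @param kind `"cell"` or `"dna"`.
#' @return A `mock_recipe`.
#' @export
read_recipe <- function(path, kind = c("cell", "dna")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  achieved_col <- if (kind == "cell") "achieved_copies_per_ml" else "achieved_ng_per_ul"
  stopifnot_cols(df, c("component", "volume_ul", achieved_col), "recipe file")
  dil <- df$component == "diluent"
  strains <- df[!dil, , drop = FALSE]
  vol <- stats::setNames(strains$volume_ul, strains$component)
  achieved <- stats::setNames(strains[[achieved_col]], strains$component)
  new_recipe(kind, vol, if (any(dil)) df$volume_ul[dil][1L] else 0,
             sum(df$volume_ul), achieved)
}

#' Write a QC report as JSON (plus optional tidy TSVs)
#'
#' @param report A `qc_report`.
#' @param path JSON output path.
#' @param tsv_prefix If non-`NULL`, also writes `<prefix>_cv.tsv` and
#'   `<prefix>_afd.tsv`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path, tsv_prefix = NULL) {
  stopifnot(inherits(report, "qc_report"))
  payload <- list(expected_fraction = report$expected_fraction,
                  afd_mode = report$afd_mode,
                  cv = report$cv, afd = report$afd)
  if (!is.null(report$tests)) payload$tests <- report$tests
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(tsv_prefix)) {
    write_tsv(report$cv, paste0(tsv_prefix, "_cv.tsv"))
    write_tsv(report$afd, paste0(tsv_prefix, "_afd.tsv"))
  }
  invisible(path)
}
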