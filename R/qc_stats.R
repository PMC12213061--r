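# QC statistics: batch-to-batch reproducibility (CV), accuracy against the
# theoretical composition (AFD), and between-method comparison (Welch t).

#' Coefficient of variation, percent
#'
#' Sample standard deviation (n - 1 denominator) over the mean, times 100.
#' Scale-invariant: `cv_percent(k * x) == cv_percent(x)` for k > 0.
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(0.06, 0.07, 0.08))  # 14.2857
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L)
    mf_stop("CV needs at least two values", "mockforge_insufficient_data")
  m <- mean(values)
  if (m <= 0)
    mf_stop("CV needs a positive mean", "mockforge_domain_error")
  stats::sd(values) / m * 100
}

#' Absolute fold difference between observed and expected abundance
#'
#' The fold ratio between a measured and a theoretical abundance, folded to
#' be >= 1 (`"fold"` mode, the default) or expressed as the absolute log2
#' ratio (`"abs_log2"`); the two satisfy `fold == 2^abs_log2`. Symmetric in
#' its arguments. Zero abundances cannot be scored — exclude them upstream.
#'
#' @param observed,expected Positive abundances (vectorised).
#' @param mode `"fold"` or `"abs_log2"`.
#' @return AFD value(s): >= 1 in fold mode, >= 0 in abs_log2 mode.
#' @examples
#' afd(0.10, 1/15)            # 1.5
#' afd(0.0333333, 1/15, "abs_log2")  # ~1
#' @export
afd <- function(observed, expected, mode = c("fold", "abs_log2")) {
  mode <- match.arg(mode)
  if (any(observed <= 0) || any(expected <= 0))
    mf_stop("AFD needs strictly positive abundances (zero observed abundances cannot be scored; exclude them)",
            "mockforge_domain_error")
  ratio <- observed / expected
  switch(mode,
         fold = pmax(ratio, 1 / ratio),
         abs_log2 = abs(log2(ratio)))
}

#' Welch's two-sample t-test (unequal variances)
#'
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value from the
#' t-distribution. Implemented directly from the formulas;
#' `stats::t.test()` serves as an independent cross-check in the test
#' suite, never as the implementation.
#'
#' If both variances are zero: equal means give the degenerate convention
#' `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))  # t = -1.5492, df = 2.9412
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    mf_stop("Welch's t-test needs at least two values per group",
            "mockforge_insufficient_data")
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Quality-control report for a mock community
#'
#' Scores an abundance table against the theoretical equimolar composition:
#'
#' * **CV**: replicates are averaged within batch first, then the percent
#'   CV of each strain's batch means is computed across batches (>= 2
#'   batches required) — batch-to-batch reproducibility of the preparation.
#' * **AFD**: absolute fold difference of each (strain, batch) mean against
#'   `expected_fraction` — compositional accuracy. Zero observed batch
#'   means are excluded with a warning rather than mapped to infinity.
#' * **Group tests**: for each requested pair of condition labels, Welch's
#'   two-sided t-test on the pooled per-strain CV sets and on the pooled
#'   AFD sets. Significance stars annotate the report only; they drive no
#'   logic.
#'
#' Strains are grouped by (condition, assay) so, e.g., the same mock read
#' out by ddPCR and shotgun sequencing is scored separately per assay.
#'
#' @param table An abundance table (see [abundance_table()]).
#' @param expected_fraction Theoretical per-strain fraction (default 1/15,
#'   i.e. 6.7% for the 15-strain equimolar design).
#' @param afd_mode `"fold"` (default) or `"abs_log2"`; the report names the
#'   mode used.
#' @param compare List of length-2 character vectors of condition labels to
#'   test against each other, e.g. `list(c("cell_hplc", "cell_fcm"))`.
#' @return A `qc_report`: data frames `cv` (condition, assay, strain_id,
#'   cv_percent), `afd` (condition, assay, strain_id, batch_id, afd),
#'   `tests` (label_a, label_b, metric, t, df, p, stars), plus
#'   `expected_fraction` and `afd_mode`.
#' @export
qc_report <- function(table, expected_fraction = 1 / 15,
                      afd_mode = c("fold", "abs_log2"), compare = NULL) {
  afd_mode <- match.arg(afd_mode)
  if (expected_fraction <= 0 || expected_fraction >= 1)
    mf_stop("expected_fraction must lie in (0, 1)", "mockforge_domain_error")
  tab <- abundance_table(table)

  # replicate -> batch means (paste keys: NA conditions must not drop groups)
  key <- paste(tab$condition, tab$assay, tab$strain_id, tab$batch_id, sep = "\r")
  bm <- do.call(rbind, lapply(split(seq_len(nrow(tab)), key), function(i) {
    data.frame(condition = tab$condition[i[1L]], assay = tab$assay[i[1L]],
               strain_id = tab$strain_id[i[1L]], batch_id = tab$batch_id[i[1L]],
               fraction = mean(tab$fraction[i]), stringsAsFactors = FALSE)
  }))

  skey <- paste(bm$condition, bm$assay, bm$strain_id, sep = "\r")
  cv_rows <- lapply(split(seq_len(nrow(bm)), skey), function(i) {
    if (length(i) < 2L)
      mf_stop(sprintf("strain %s (%s/%s) has fewer than two batches",
                      bm$strain_id[i[1L]], bm$condition[i[1L]], bm$assay[i[1L]]),
              "mockforge_insufficient_data")
    data.frame(condition = bm$condition[i[1L]], assay = bm$assay[i[1L]],
               strain_id = bm$strain_id[i[1L]],
               cv_percent = cv_percent(bm$fraction[i]), stringsAsFactors = FALSE)
  })
  cv_df <- do.call(rbind, cv_rows)
  rownames(cv_df) <- NULL

  zero <- bm$fraction <= 0
  if (any(zero)) {
    warning(sprintf("excluding %d zero batch-mean abundance(s) from AFD (strains: %s)",
                    sum(zero), paste(unique(bm$strain_id[zero]), collapse = ", ")))
  }
  afd_df <- bm[!zero, c("condition", "assay", "strain_id", "batch_id")]
  afd_df$afd <- afd(bm$fraction[!zero], expected_fraction, afd_mode)
  rownames(afd_df) <- NULL

  tests <- NULL
  if (!is.null(compare)) {
    tests <- do.call(rbind, lapply(compare, function(pair) {
      stopifnot(length(pair) == 2L)
      rows <- lapply(c(cv = "cv", afd = "afd"), function(metric) {
        df <- if (metric == "cv") cv_df else afd_df
        col <- if (metric == "cv") "cv_percent" else "afd"
        x <- df[[col]][df$condition == pair[1L]]
        y <- df[[col]][df$condition == pair[2L]]
        if (length(x) < 2L || length(y) < 2L)
          mf_stop(sprintf("condition '%s' or '%s' has too few %s values for a Welch test",
                          pair[1L], pair[2L], metric), "mockforge_insufficient_data")
        w <- welch_t(x, y)
        data.frame(label_a = pair[1L], label_b = pair[2L], metric = metric,
                   t = w$t, df = w$df, p = w$p,
                   stars = if (w$p < 0.01) "**" else if (w$p < 0.05) "*" else "",
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
    rownames(tests) <- NULL
  }

  structure(list(cv = cv_df, afd = afd_df, tests = tests,
                 expected_fraction = expected_fraction, afd_mode = afd_mode),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Mock-community QC report (expected fraction %.4f = %.1f%%, AFD mode '%s')\n",
              x$expected_fraction, 100 * x$expected_fraction, x$afd_mode))
  grp <- paste(x$cv$condition, x$cv$assay, sep = "/")
  for (g in unique(grp)) {
    i <- grp == g
    j <- paste(x$afd$condition, x$afd$assay, sep = "/") == g
    cat(sprintf("  %-25s median CV %6.2f%%  median AFD %6.3f  (n strains = %d)\n",
                g, stats::median(x$cv$cv_percent[i]), stats::median(x$afd$afd[j]), sum(i)))
  }
  if (!is.null(x$tests)) {
    cat("  Welch tests:\n")
    for (k in seq_len(nrow(x$tests))) {
      cat(sprintf("    %s vs %s [%s]: t = %.3f, df = %.2f, p = %.3g %s\n",
                  x$tests$label_a[k], x$tests$label_b[k], x$tests$metric[k],
                  x$tests$t[k], x$tests$df[k], x$tests$p[k], x$tests$stars[k]))
    }
  }
  invisible(x)
}

#' Boxplots of per-strain CV and AFD by condition
#'
#' Quick visual QC mirroring the standard presentation: one box per
#' (condition, assay) group for CV and for AFD.
#'
#' @param x A `qc_report`.
#' @param ... Passed to [graphics::boxplot()].
#' @return The report, invisibly.
#' @export
plot.qc_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  grp_cv <- interaction(x$cv$condition, x$cv$assay, drop = TRUE)
  graphics::boxplot(x$cv$cv_percent ~ grp_cv, xlab = "", ylab = "CV (%)",
                    main = "Reproducibility", las = 2, ...)
  grp_afd <- interaction(x$afd$condition, x$afd$assay, drop = TRUE)
  graphics::boxplot(x$afd$afd ~ grp_afd, xlab = "",
                    ylab = paste0("AFD (", x$afd_mode, ")"),
                    main = "Accuracy", las = 2, ...)
  invisible(x)
}
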