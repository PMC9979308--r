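#' Imaging-versus-pathology staging contingency table
#'
#' A `K x K` table of nonnegative integer counts with **rows the
#' imaging-assigned stage and columns the pathological (ground-truth)
#' stage**. The axis convention is enforced by explicit labels in the CSV
#' header to prevent silent transposition.
#'
#' @param counts `K x K` nonnegative integer matrix.
#' @param labels ordered character vector of `K` stage names.
#' @return an object of class `staging_table`.
#' @export
staging_table <- function(counts, labels = rownames(counts)) {
  m <- as.matrix(counts)
  if (nrow(m) != ncol(m)) stop_invalid("staging table must be square")
  if (any(m < 0) || any(m != round(m))) stop_invalid("counts must be nonnegative integers")
  if (sum(m) <= 0) stop_invalid("staging table must have a positive total")
  if (is.null(labels)) labels <- paste0("stage", seq_len(nrow(m)))
  if (length(labels) != nrow(m)) stop_invalid("label count must match table size")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(imaging = labels, pathology = labels)
  structure(list(counts = m, labels = as.character(labels)),
            class = "staging_table")
}

#' @export
print.staging_table <- function(x, ...) {
  cat("Staging table (rows = imaging call, cols = pathology), n =",
      sum(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Read / write a staging table as CSV
#'
#' The CSV carries the stage labels as header row and first column; the
#' first header cell names the axes (`imaging\\pathology`) so a transposed
#' file is detectable by eye.
#'
#' @param path file path.
#' @return `read_staging_table()` returns a [staging_table].
#' @export
read_staging_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (!identical(colnames(m), labels))
    stop_invalid("staging CSV labels differ between rows and columns")
  staging_table(m, labels)
}

#' @rdname read_staging_table
#' @param table a [staging_table].
#' @export
write_staging_table <- function(table, path) {
  stopifnot(inherits(table, "staging_table"))
  df <- data.frame(check.names = FALSE,
                   `imaging\\pathology` = table$labels,
                   as.data.frame(table$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-stage diagnostic sensitivity
#'
#' Fraction of pathological stage-`k` cases that imaging also called stage
#' `k`: the diagonal count over the pathological column total.
#'
#' @param table a [staging_table].
#' @param stage stage index or label.
#' @return a fraction in `[0, 1]`, or `NA` (undefined-metric sentinel) when
#'   no pathological case of that stage exists.
#' @export
sensitivity <- function(table, stage) {
  stopifnot(inherits(table, "staging_table"))
  k <- stage_index(table, stage)
  denom <- sum(table$counts[, k])
  if (denom == 0) return(NA_real_)
  table$counts[k, k] / denom
}

#' Per-stage diagnostic specificity
#'
#' One-vs-rest: among pathological non-`k` cases, the fraction *not*
#' assigned stage `k` by imaging.
#'
#' @inheritParams sensitivity
#' @return a fraction in `[0, 1]`, or `NA` when the table has a single
#'   represented stage.
#' @export
specificity <- function(table, stage) {
  stopifnot(inherits(table, "staging_table"))
  k <- stage_index(table, stage)
  non_k <- sum(table$counts) - sum(table$counts[, k])
  if (non_k == 0) return(NA_real_)
  false_pos <- sum(table$counts[k, -k])
  1 - false_pos / non_k
}

#' Overall diagnostic coincidence rate
#'
#' Fraction of cases where the imaging stage equals the pathological stage:
#' the table trace over its grand total.
#'
#' @inheritParams sensitivity
#' @return a fraction in `[0, 1]`.
#' @export
coincidence_rate <- function(table) {
  stopifnot(inherits(table, "staging_table"))
  sum(diag(table$counts)) / sum(table$counts)
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic with `(K-1)^2` degrees of freedom, without continuity
#' correction. When any expected count falls below 5 the standard
#' small-sample caveat is flagged in the result rather than silently
#' ignored.
#'
#' @inheritParams sensitivity
#' @return a list with `statistic`, `df`, `p_value`,
#'   `low_expected_counts` (logical flag).
#' @export
chi_square_test <- function(table) {
  stopifnot(inherits(table, "staging_table"))
  m <- table$counts
  keep_r <- rowSums(m) > 0; keep_c <- colSums(m) > 0
  if (!any(keep_r) || !any(keep_c)) stop_invalid("degenerate table")
  m2 <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m2) < 2 || ncol(m2) < 2)
    stop_invalid("chi-square requires at least two non-empty rows and columns")
  expected <- outer(rowSums(m2), colSums(m2)) / sum(m2)
  stat <- sum((m2 - expected)^2 / expected)
  df <- (nrow(m2) - 1) * (ncol(m2) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       low_expected_counts = any(expected < 5))
}

#' Cohen's kappa agreement coefficient
#'
#' Chance-corrected agreement between the imaging and pathological calls:
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the table trace
#' over the total and expected agreement `p_e` from the margins.
#'
#' @inheritParams sensitivity
#' @return kappa in `[-1, 1]` (`NA` sentinel if `p_e = 1`).
#' @export
agreement_kappa <- function(table) {
  stopifnot(inherits(table, "staging_table"))
  m <- table$counts; n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Evaluate a staging cohort
#'
#' Computes per-stage sensitivity and specificity, the overall coincidence
#' rate, the Pearson chi-square test and Cohen's kappa, and renders a
#' benchmark-style report with percentages rounded half-up to 2 decimals.
#'
#' Printed clinical tables sometimes quote specificity and coincidence
#' denominators that are not derivable from the published contingency
#' counts; this function always computes the standard definitions from the
#' counts themselves and says so in the report footnote.
#'
#' @inheritParams sensitivity
#' @param rounding decimal places for the rendered percentages.
#' @return a list of class `stage_metrics` with elements `per_stage`
#'   (data.frame), `coincidence_rate`, `chi_square`, `kappa`, `n`, `report`
#'   (character vector).
#' @export
evaluate_cohort <- function(table, rounding = 2) {
  stopifnot(inherits(table, "staging_table"))
  K <- length(table$labels)
  sens <- vapply(seq_len(K), function(k) sensitivity(table, k), 0)
  spec <- vapply(seq_len(K), function(k) specificity(table, k), 0)
  cr <- coincidence_rate(table)
  chi <- chi_square_test(table)
  kap <- agreement_kappa(table)
  per_stage <- data.frame(
    stage = table$labels,
    sensitivity_pct = round_half_up(100 * sens, rounding),
    specificity_pct = round_half_up(100 * spec, rounding),
    n_pathology = as.integer(colSums(table$counts)),
    n_imaging = as.integer(rowSums(table$counts)),
    stringsAsFactors = FALSE)
  rep_lines <- c(
    sprintf("n = %d patients, %d stages (%s)", sum(table$counts), K,
            paste(table$labels, collapse = ", ")),
    sprintf("overall coincidence rate (trace/total): %s%%",
            fmt(round_half_up(100 * cr, rounding))),
    sprintf("Cohen's kappa: %s", fmt(round(kap, 4))),
    sprintf("Pearson chi-square: %s (df = %d, p = %s%s)",
            fmt(round(chi$statistic, 4)), chi$df, fmt(signif(chi$p_value, 4)),
            if (chi$low_expected_counts) "; expected counts < 5 present" else ""),
    paste(utils::capture.output(print(per_stage, row.names = FALSE)),
          collapse = "\n"),
    paste("note: sensitivity/specificity/coincidence are the standard",
          "one-vs-rest definitions computed from the table counts."))
  structure(list(per_stage = per_stage, coincidence_rate = cr,
                 chi_square = chi, kappa = kap, n = sum(table$counts),
                 report = rep_lines),
            class = "stage_metrics")
}

#' @export
print.stage_metrics <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

#' @noRd
stage_index <- function(table, stage) {
  if (is.character(stage)) {
    k <- match(stage, table$labels)
    if (is.na(k)) stop_invalid("unknown stage label: ", stage)
    return(k)
  }
  k <- as.integer(stage)
  if (k < 1 || k > length(table$labels)) stop_invalid("stage index out of range")
  k
}

#' Round half away from zero (the convention of printed clinical tables)
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
fmt <- function(x) format(x, trim = TRUE, scientific = FALSE)
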