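# Published-cohort reference tables and the aggregation checker.
#
# The CSVs under inst/extdata/ transcribe the printed per-patient tables of
# the emulated pilot cohort: the sample inventory (26 samples of 10 patients),
# the matched data-point counts, and the per-patient cross-validated metrics
# with their printed "Mean" row.  They are inputs to the aggregation utility,
# not computed results.

#' Load the bundled reference tables
#'
#' @return list with data.frames `samples` (patient, sample, organ), `counts`
#'   (patient, total, tumor, non_tumor) and `crossval` (per-patient metrics,
#'   `NA` for cells printed "-", logical `tumor_free`, plus a `Mean` row).
#' @export
reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "hsiclass",
                                  mustWork = TRUE)
  list(
    samples = read.csv(path("reference_sample_inventory.csv"),
                       stringsAsFactors = FALSE),
    counts = read.csv(path("reference_datapoint_counts.csv"),
                      stringsAsFactors = FALSE),
    crossval = read.csv(path("reference_crossval_metrics.csv"),
                        stringsAsFactors = FALSE)
  )
}

#' Verify the bookkeeping and mean row of printed per-patient tables
#'
#' Recomputes, from the per-patient rows, the totals and the cohort mean row
#' using the same aggregation semantics as [aggregate_mean()] (tumor-free
#' patients contribute only to specificity), and compares each cell with the
#' printed value at 2-decimal half-up rounding.
#'
#' @param counts data.frame like `reference_tables()$counts`.
#' @param crossval data.frame like `reference_tables()$crossval`, including a
#'   `Mean` row holding the printed means.
#' @param samples data.frame like `reference_tables()$samples`.
#' @return object of class `table_check`: list with `grand_total`,
#'   `per_patient_consistent`, `n_samples`, `organ_counts`, `mean_recomputed`,
#'   `mean_printed`, `mean_ok` (per metric), `all_ok`.
#' @export
run_table_check <- function(counts = NULL, crossval = NULL, samples = NULL) {
  ref <- reference_tables()
  if (is.null(counts)) counts <- ref$counts
  if (is.null(crossval)) crossval <- ref$crossval
  if (is.null(samples)) samples <- ref$samples
  if (nrow(counts) == 0 || nrow(crossval) == 0) stop("empty reference table")

  per_ok <- counts$tumor + counts$non_tumor == counts$total
  grand <- sum(counts$total)

  mean_row <- crossval$patient == "Mean"
  printed <- crossval[mean_row, c("sensitivity", "specificity", "ppv",
                                  "npv", "auc", "mcc")]
  pp <- crossval[!mean_row, , drop = FALSE]
  recomputed <- aggregate_mean(pp)
  mean_ok <- round_half_up(recomputed, 2) == unlist(printed)

  organ_counts <- table(samples$organ)
  structure(list(grand_total = grand,
                 per_patient_consistent = all(per_ok),
                 n_samples = nrow(samples),
                 organ_counts = organ_counts,
                 mean_recomputed = recomputed,
                 mean_printed = unlist(printed),
                 mean_ok = mean_ok,
                 all_ok = all(per_ok) && all(mean_ok)),
            class = "table_check")
}

#' @export
print.table_check <- function(x, ...) {
  cat("table_check:\n")
  cat("  grand total data points:", x$grand_total,
      if (x$per_patient_consistent) "(rows consistent)" else "(ROW MISMATCH)",
      "\n")
  cat("  samples:", x$n_samples, "-",
      paste(names(x$organ_counts), x$organ_counts, sep = "=", collapse = ", "),
      "\n")
  cat("  mean row recomputed:",
      paste(names(x$mean_recomputed),
            sprintf("%.2f", round_half_up(x$mean_recomputed, 2)),
            sep = "=", collapse = " "), "\n")
  cat("  cells matching printed mean:", sum(x$mean_ok), "/", length(x$mean_ok),
      if (x$all_ok) "- PASS" else "- FAIL", "\n")
  invisible(x)
}
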