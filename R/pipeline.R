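# Pipeline orchestration: config, per-sample stage runner, end-to-end driver,
# report writing, and the command-line entry point.

#' Default pipeline configuration
#'
#' All tunable analysis thresholds in one serializable list: calibration
#' denominator guard (`calib_eps`), glare/background reflectance thresholds,
#' the 20-pixel edge-erosion margin, the 20-pixel block size with its minimum
#' valid fraction, the HSV annotation windows, the feature mode, the SVM `C`
#' and the CV threshold mode.  A run's config is embedded in its report.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    calib_eps = 1e-6,
    glare_thr = 0.95, bg_thr = 0.10,
    edge_margin = 20,
    block = 20, min_valid_fraction = 0.8,
    normalize_before_patching = FALSE,
    feature_mode = "mixed",
    svm_C = 1, threshold_mode = "heldout",
    positive = "tumor",
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the preprocessing chain on one sample
#'
#' demosaic -> calibrate -> validity mask -> edge erosion -> annotation
#' segmentation -> control-point registration -> patch averaging, in the
#' stage order of the acquisition protocol.
#'
#' @param sample an `hsi_sample` (from [simulate_cohort()] / [read_cohort()]).
#' @param config a [default_config()] list.
#' @param hsv_windows HSV windows for the annotation colors.
#' @return a `patch_table` with a `"stage_counts"` attribute (named vector of
#'   patch counts through the filtering stages).
#' @export
sample_to_patches <- function(sample, config = default_config(),
                              hsv_windows = default_hsv_windows()) {
  bands <- sample$bands
  raw <- demosaic(sample$raw, bands)
  refs <- reference_set(demosaic(sample$white, bands),
                        demosaic(sample$dark, bands))
  refl <- calibrate(raw, refs, eps = config$calib_eps)
  mask <- make_validity_mask(refl, glare_thr = config$glare_thr,
                             bg_thr = config$bg_thr)
  mask <- erode_edges(mask, margin = config$edge_margin)
  ann_src <- hsv_masks(sample$annotation, hsv_windows)
  ann <- tps_warp(ann_src, sample$control_points,
                  out_dim = dim(refl$data)[1:2], method = "nearest",
                  background = LABEL_CODES[["unannotated"]])
  if (isTRUE(config$normalize_before_patching)) {
    d <- dim(refl$data)
    m <- minmax_normalize(matrix(refl$data, d[1] * d[2], d[3]))
    refl <- hypercube(array(m, d), bands, "normalized")
  }
  pt <- patch_average(refl, mask, ann, block = config$block,
                      min_valid_fraction = config$min_valid_fraction,
                      patient_id = sample$patient_id,
                      sample_id = sample$sample_id)
  attr(pt, "stage_counts") <- c(
    blocks_total = length(label_patches(ann, block = config$block)$label),
    blocks_retained = nrow(pt),
    blocks_labeled = sum(pt$label %in% c("tumor", "non_tumor")),
    blocks_tumor = sum(pt$label == "tumor"),
    blocks_non_tumor = sum(pt$label == "non_tumor"))
  pt
}

#' Run the full pipeline on a cohort
#'
#' Executes every stage on every sample, pools the retained patches, extracts
#' the 19 spectral features, runs leave-one-patient-out cross-validation of
#' the class-weighted linear SVM, and aggregates the per-patient metrics.
#'
#' @param cohort an `hsi_cohort` or a path to a [generate_cohort()] directory.
#' @param config a [default_config()] list.
#' @param specs feature specs (default the 19-feature set).
#' @param quiet suppress per-stage messages.
#' @return a `metrics_report` (see [lopo_cv()]) with additional elements
#'   `stage_counts` (per-sample patch accounting), `patches`, `features` and
#'   the full `config`.
#' @export
run_pipeline <- function(cohort, config = default_config(),
                         specs = default_feature_specs(), quiet = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "hsi_cohort"))
  say <- function(...) if (!quiet) message(...)
  tabs <- list(); counts <- list()
  for (k in seq_along(cohort$samples)) {
    smp <- cohort$samples[[k]]
    pt <- sample_to_patches(smp, config)
    key <- paste0(smp$patient_id, "/", smp$sample_id)
    counts[[key]] <- attr(pt, "stage_counts")
    say(sprintf("%s: %d blocks -> %d retained -> %d labeled (%d tumor)",
                key, counts[[key]]["blocks_total"],
                counts[[key]]["blocks_retained"],
                counts[[key]]["blocks_labeled"],
                counts[[key]]["blocks_tumor"]))
    tabs[[key]] <- pt
  }
  patches <- do.call(rbind, tabs)
  rownames(patches) <- NULL
  ft <- build_feature_table(patches, cohort$bands, specs,
                            mode = config$feature_mode)
  say(sprintf("feature table: %d patches x %d features (%d tumor / %d non-tumor)",
              nrow(ft), length(specs), sum(ft$label == "tumor"),
              sum(ft$label == "non_tumor")))
  feat_cols <- vapply(specs, `[[`, character(1), "name")
  report <- lopo_cv(as.matrix(ft[, feat_cols]), ft$label, ft$patient_id,
                    C = config$svm_C, threshold_mode = config$threshold_mode,
                    positive = config$positive)
  report$stage_counts <- do.call(rbind, counts)
  report$patches <- patches
  report$features <- ft
  report$config <- utils::modifyList(report$config, config)
  report
}

#' Write a metrics report to disk
#'
#' Writes the per-patient table as CSV (undefined cells rendered "-"),
#' the full report (metrics, ROC point lists, stage counts, config) as JSON,
#' and the pooled feature table as CSV.
#'
#' @param report a `metrics_report` from [run_pipeline()] or [lopo_cv()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- report$per_patient
  disp <- pp
  for (cl in c("sensitivity", "specificity", "ppv", "npv", "auc", "mcc")) {
    disp[[cl]] <- ifelse(is.na(pp[[cl]]), "-",
                         sprintf("%.2f", round_half_up(pp[[cl]], 2)))
  }
  mean_disp <- as.data.frame(as.list(
    ifelse(is.na(report$mean), "-",
           sprintf("%.2f", round_half_up(report$mean, 2)))))
  write.csv(disp, file.path(dir, "per_patient.csv"), row.names = FALSE)
  write.csv(mean_disp, file.path(dir, "mean_row.csv"), row.names = FALSE)
  if (!is.null(report$features)) {
    write.csv(report$features, file.path(dir, "features.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(per_patient = report$per_patient, mean = as.list(report$mean),
         roc = report$roc, errors = report$errors,
         stage_counts = report$stage_counts, config = report$config),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  invisible(dir)
}

#' Simulate subcommand: write a synthetic cohort with a config snapshot
#' @param outdir output directory.
#' @param sim generator config.
#' @param seed master seed.
#' @param force overwrite a non-empty directory.
#' @return manifest, invisibly.
#' @export
run_simulate <- function(outdir, sim = default_sim_config(), seed = 1,
                         force = FALSE) {
  generate_cohort(outdir, sim = sim, seed = seed, force = force)
}

# Minimal flag parser for the CLI: --flag value pairs plus a subcommand.
parse_cli_args <- function(args) {
  if (!length(args)) return(list(cmd = "help", opts = list()))
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--force", "--quiet")) {
      opts[[sub("^--", "", a)]] <- TRUE
      i <- i + 1
    } else if (startsWith(a, "--")) {
      if (i == length(args)) stop("missing value for ", a)
      opts[[sub("^--", "", a)]] <- args[i + 1]
      i <- i + 2
    } else stop("unexpected argument: ", a)
  }
  list(cmd = cmd, opts = opts)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR [--seed N] [--config PATH] [--force]`,
#' `run --cohort DIR --out DIR [--config PATH] [--quiet]`, and
#' `table-check`.  Config files are JSON with the fields of
#' [default_config()] / [default_sim_config()].
#'
#' @param args character vector, defaults to `commandArgs(TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(TRUE)) {
  pa <- parse_cli_args(args)
  o <- pa$opts
  load_cfg <- function(builder) {
    if (!is.null(o$config)) {
      do.call(builder, jsonlite::read_json(o$config, simplifyVector = TRUE))
    } else builder()
  }
  if (pa$cmd == "simulate") {
    if (is.null(o$out)) stop("simulate needs --out DIR")
    run_simulate(o$out, sim = load_cfg(default_sim_config),
                 seed = as.integer(o$seed %||% 1),
                 force = isTRUE(o$force))
    message("cohort written to ", o$out)
  } else if (pa$cmd == "run") {
    if (is.null(o$cohort) || is.null(o$out)) {
      stop("run needs --cohort DIR and --out DIR")
    }
    rep <- run_pipeline(o$cohort, config = load_cfg(default_config),
                        quiet = isTRUE(o$quiet))
    print(rep)
    write_report(rep, o$out)
    message("report written to ", o$out)
  } else if (pa$cmd == "table-check") {
    print(run_table_check())
  } else {
    cat("usage: hsi-oncopipe <simulate|run|table-check> [--flags]\n")
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
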