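# Synthetic cohort generation: in-memory simulation plus on-disk round trip.

#' Default synthetic-cohort configuration
#'
#' The defaults state the emulated world: 10 patients contributing 26 samples
#' with the per-patient sample counts of the emulated pilot cohort
#' (4,1,2,3,5,3,2,2,3,1), of which patients 2, 3, 4 and 8 carry no tumor (so
#' reports exercise the "-" semantics); 400x400 demosaiced scenes (the raw
#' mosaic is 2000x2000); heterogeneous non-tumor tissue; log-normal amplitude
#' spread 0.15; per-band noise sd 0.01 reflectance; 1% glare; a 10-bit sensor
#' (saturation 1023, dark current 64, white level 900, read noise 2 counts);
#' and a small random affine annotation misalignment recovered exactly by the
#' control-point registration.
#'
#' @param ... named overrides of any default field.
#' @return named list of generator settings.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_patients = 10,
    samples_per_patient = c(4, 1, 2, 3, 5, 3, 2, 2, 3, 1),
    tumor_free_patients = c(2, 3, 4, 8),
    scene_rows = 400, scene_cols = 400,
    separation = 1, heterogeneous = TRUE,
    amplitude_sd = 0.15, noise_sd = 0.01,
    glare_fraction = 0.01, illumination_gradient = 0.3,
    dark_current = 64, white_level = 900, saturation = 1023,
    sensor_noise_sd = 2, quantize = TRUE, warp_magnitude = 1,
    mixed_region_prob = 0.4,
    band_centers = default_band_centers()
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate a synthetic cohort in memory
#'
#' Draws per-sample scenes (non-overlapping blob regions, one per quadrant)
#' and renders each with [render_sample()].  The seed fully determines the
#' cohort.
#'
#' @param sim a [default_sim_config()] list.
#' @param seed integer master seed.
#' @return object of class `hsi_cohort`: list with `samples` (each an
#'   `hsi_sample` plus `patient_id`, `sample_id`, `organ`), `manifest`
#'   data.frame, `bands`, `library`, `sim`, `seed`.
#' @export
simulate_cohort <- function(sim = default_sim_config(), seed = 1) {
  stopifnot(sim$n_patients >= 2)
  spp <- rep_len(sim$samples_per_patient, sim$n_patients)
  n_samples <- sum(spp)
  bands <- make_band_table(sim$band_centers)
  library <- default_spectral_library(bands,
                                      separation = sim$separation,
                                      heterogeneous = sim$heterogeneous,
                                      amplitude_sd = sim$amplitude_sd,
                                      noise_sd = sim$noise_sd)
  nt_pool <- setdiff(names(library$endmembers), c("tumor", "paper"))
  samples <- vector("list", n_samples)
  manifest <- NULL
  with_seed(seed, {
    sample_seeds <- sample.int(2147483646L, n_samples)
    k <- 0
    for (p in seq_len(sim$n_patients)) {
      pid <- sprintf("P%02d", p)
      has_tumor <- !(p %in% sim$tumor_free_patients)
      for (s in seq_len(spp[p])) {
        k <- k + 1
        sid <- LETTERS[s]
        organ <- sample(c("ovary", "omentum", "intestines", "mesenterium"),
                        1, prob = c(0.50, 0.38, 0.08, 0.04))
        n_reg <- 4L  # one region per scene quadrant
        if (has_tumor) {
          n_tum <- sample(1:2, 1)
          classes <- c(rep("connective", n_tum),
                       sample(nt_pool, n_reg - n_tum, replace = TRUE))
          fracs <- c(runif(n_tum, 0.65, 1), rep(0, n_reg - n_tum))
          if (runif(1) < sim$mixed_region_prob && n_reg - n_tum >= 1) {
            fracs[n_tum + 1] <- runif(1, 0.05, 0.45)  # a mixed (1-50%) region
          }
        } else {
          classes <- sample(nt_pool, n_reg, replace = TRUE)
          fracs <- rep(0, n_reg)
        }
        regions <- random_regions(sim$scene_rows, sim$scene_cols,
                                  classes, fracs)
        scene <- scene_spec(sim$scene_rows, sim$scene_cols, regions,
                            glare_fraction = sim$glare_fraction,
                            illumination_gradient = sim$illumination_gradient,
                            dark_current = sim$dark_current,
                            white_level = sim$white_level,
                            saturation = sim$saturation,
                            sensor_noise_sd = sim$sensor_noise_sd,
                            quantize = sim$quantize,
                            warp_magnitude = sim$warp_magnitude,
                            seed = sample_seeds[k])
        smp <- render_sample(scene, library, bands)
        smp$patient_id <- pid
        smp$sample_id <- sid
        smp$organ <- organ
        samples[[k]] <- smp
        manifest <- rbind(manifest,
                          data.frame(patient_id = pid, sample_id = sid,
                                     organ = organ,
                                     has_tumor = has_tumor,
                                     seed = sample_seeds[k],
                                     stringsAsFactors = FALSE))
      }
    }
  })
  structure(list(samples = samples, manifest = manifest, bands = bands,
                 library = library, sim = sim, seed = as.integer(seed)),
            class = "hsi_cohort")
}

#' @export
print.hsi_cohort <- function(x, ...) {
  cat(sprintf("hsi_cohort: %d samples from %d patients (seed %d)\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Per sample: raw/white/dark mosaic frames as ASCII PGM, the annotation
#' image as ASCII PPM, the ground-truth label mask as PGM (palette
#' 0 unannotated, 1 non_tumor, 2 tumor, 3 mixed), and the control points as
#' CSV (`x_src,y_src,x_dst,y_dst`, 0-based).  A `manifest.csv` lists every
#' sample with its file paths and a `config.json` snapshot makes the run
#' reproducible.  Identical (config, seed) yield byte-identical output.
#'
#' @param outdir output directory (created; must be empty unless `force`).
#' @param sim generator configuration, see [default_sim_config()].
#' @param seed master seed.
#' @param force overwrite a non-empty directory.
#' @param cohort optionally a pre-built [simulate_cohort()] result to write.
#' @return the manifest data.frame, invisibly.
#' @export
generate_cohort <- function(outdir, sim = default_sim_config(), seed = 1,
                            force = FALSE, cohort = NULL) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory ", outdir, " is not empty (use force = TRUE)")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(sim, seed)
  man <- cohort$manifest
  paths <- data.frame(raw = character(nrow(man)), white = "", dark = "",
                      annotation = "", control_points = "", truth = "",
                      stringsAsFactors = FALSE)
  for (k in seq_len(nrow(man))) {
    smp <- cohort$samples[[k]]
    pdir <- file.path(outdir, man$patient_id[k])
    dir.create(pdir, showWarnings = FALSE)
    stem <- paste0(man$patient_id[k], "_", man$sample_id[k])
    rel <- function(nm) file.path(man$patient_id[k], paste0(stem, "_", nm))
    sat <- smp$scene$saturation
    write_pgm(smp$raw, file.path(outdir, rel("raw.pgm")), maxval = sat)
    write_pgm(smp$white, file.path(outdir, rel("white.pgm")), maxval = sat)
    write_pgm(smp$dark, file.path(outdir, rel("dark.pgm")), maxval = sat)
    write_ppm(smp$annotation, file.path(outdir, rel("annotation.ppm")))
    write_pgm(smp$truth, file.path(outdir, rel("truth.pgm")), maxval = 3)
    write.csv(smp$control_points, file.path(outdir, rel("points.csv")),
              row.names = FALSE)
    paths[k, ] <- c(rel("raw.pgm"), rel("white.pgm"), rel("dark.pgm"),
                    rel("annotation.ppm"), rel("points.csv"), rel("truth.pgm"))
  }
  manifest <- cbind(man, paths)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  snap <- cohort$sim
  snap$seed <- cohort$seed
  jsonlite::write_json(snap, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [generate_cohort()]
#' @param dir cohort directory containing `manifest.csv` and `config.json`.
#' @return an `hsi_cohort` (without the spectral library, which is not needed
#'   downstream).
#' @export
read_cohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  bands <- make_band_table(cfg$band_centers)
  samples <- lapply(seq_len(nrow(man)), function(k) {
    structure(list(
      raw = read_pgm(file.path(dir, man$raw[k])),
      white = read_pgm(file.path(dir, man$white[k])),
      dark = read_pgm(file.path(dir, man$dark[k])),
      annotation = read_ppm(file.path(dir, man$annotation[k])),
      control_points = read.csv(file.path(dir, man$control_points[k])),
      truth = read_pgm(file.path(dir, man$truth[k])),
      bands = bands,
      patient_id = man$patient_id[k], sample_id = man$sample_id[k],
      organ = man$organ[k]), class = "hsi_sample")
  })
  structure(list(samples = samples, manifest = man, bands = bands,
                 library = NULL, sim = cfg, seed = cfg$seed),
            class = "hsi_cohort")
}
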