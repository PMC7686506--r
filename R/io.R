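# fixed-precision number formatting so repeated runs produce byte-identical
# CSV output
fmt_num <- function(x) {
  if (is.numeric(x)) as.numeric(signif(x, 6)) else x
}

write_csv6 <- function(df, path) {
  df[] <- lapply(df, fmt_num)
  write.csv(df, path, row.names = FALSE)
}

# multi-page unsigned-16-bit TIFF writers; r-tiff maps [0,1] onto the
# integer range, so a scale factor is stored in the sidecar JSON
write_stack_tiff <- function(stack, path, scale = 65535) {
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k)
    pmin(stack$frames[, , k] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(
    frequency_hz = stack$config$frequency_hz,
    n_phase_steps = stack$config$n_phase_steps,
    exposure_ms = stack$exposure_ms, channel = stack$channel,
    intensity_scale = scale
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_stack_tiff <- function(path) {
  sidecar <- sub("\\.tiff?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    frames[, , k] <- round(pages[[k]] * meta$intensity_scale)
  raw_frame_stack(frames, flim_config(meta$frequency_hz, meta$n_phase_steps),
                  channel = meta$channel, exposure_ms = meta$exposure_ms)
}

#' Write a lifetime map to disk
#'
#' The map is stored as a scaled unsigned-16-bit TIFF (integer TIFF being
#' the portable dialect of the available writer) with the ns-per-unit
#' scale in a sidecar JSON, plus an explicit validity-mask TIFF; invalid
#' pixels are stored as zero and restored to `NA` on reading.
#'
#' @param map a [lifetime_map()]
#' @param path output TIFF path; the mask goes to `<path>_mask.tif` and
#'   metadata to a `.json` sidecar
#' @param scale_ns full-scale lifetime in ns
#' @return the path, invisibly
#' @export
write_lifetime_map <- function(map, path, scale_ns = 32) {
  tau <- map$tau_ns
  tau[!map$valid] <- 0
  tiff::writeTIFF(pmin(tau / scale_ns, 1), path, bits.per.sample = 16)
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  tiff::writeTIFF(map$valid * 1, mask_path, bits.per.sample = 8)
  jsonlite::write_json(list(channel = map$channel,
                            frequency_hz = map$frequency_hz,
                            scale_ns = scale_ns, units = "ns"),
                       sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lifetime map written by [write_lifetime_map()]
#'
#' @param path TIFF path
#' @return a [lifetime_map()] (the stored `dc` is not preserved; a unit
#'   image is substituted)
#' @export
read_lifetime_map <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  tau <- tiff::readTIFF(path) * meta$scale_ns
  valid <- tiff::readTIFF(sub("\\.tiff?$", "_mask.tif", path)) > 0.5
  tau[!valid] <- NA_real_
  lifetime_map(tau, valid, dc = matrix(1, nrow(tau), ncol(tau)),
               channel = meta$channel, frequency_hz = meta$frequency_hz)
}

#' Write a synthetic cohort to disk
#'
#' Per-sample directory with `nadh.tif` / `ppix.tif` (16-page raw stacks
#' plus JSON sidecars), `mask.tif` and `truth.json`, alongside a
#' cohort-level `manifest.csv`, `config.json` and the calibration
#' reference stack.
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (smp in cohort$samples) {
    sdir <- file.path(dir, smp$sample_id)
    dir.create(sdir, showWarnings = FALSE)
    write_stack_tiff(smp$stacks$NADH, file.path(sdir, "nadh.tif"))
    write_stack_tiff(smp$stacks$PPIX, file.path(sdir, "ppix.tif"))
    tiff::writeTIFF(smp$mask * 1, file.path(sdir, "mask.tif"),
                    bits.per.sample = 8)
    jsonlite::write_json(
      smp[c("patient_id", "sample_id", "diagnosis", "grade", "tissue",
            "ala", "true_tau_nadh_ns", "true_tau_ppix_ns", "has_vessel")],
      file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  write_stack_tiff(cohort$reference, file.path(dir, "reference.tif"))
  write_csv6(cohort$manifest, file.path(dir, "manifest.csv"))
  cfg <- cohort$config
  jsonlite::write_json(
    list(mode = cfg$mode, image_size = cfg$image_size,
         photon_budget = cfg$photon_budget,
         pixel_jitter_cv = cfg$pixel_jitter_cv,
         ppix_components = cfg$ppix_components,
         nadh_components = cfg$nadh_components,
         vessel_tau_ns = cfg$vessel_tau_ns,
         vessel_fraction = cfg$vessel_fraction,
         necrotic_tau_ns = cfg$necrotic_tau_ns,
         necrotic_ppix_factor = cfg$necrotic_ppix_factor,
         instrument_phase_rad = cfg$instrument_phase_rad,
         instrument_modulation = cfg$instrument_modulation,
         background_dc = cfg$background_dc,
         frequency_hz = cfg$flim$frequency_hz,
         n_phase_steps = cfg$flim$n_phase_steps,
         noise = cfg$noise, seed = cohort$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory
#' @return a `flim_cohort`
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  config <- cohort_config(
    mode = meta$mode, inventory = manifest[, c("patient_id", "sample_id",
                                               "diagnosis", "grade",
                                               "tissue", "ala")],
    image_size = meta$image_size, photon_budget = meta$photon_budget,
    pixel_jitter_cv = meta$pixel_jitter_cv,
    ppix_components = meta$ppix_components,
    nadh_components = meta$nadh_components,
    vessel_tau_ns = meta$vessel_tau_ns,
    vessel_fraction = meta$vessel_fraction,
    necrotic_tau_ns = meta$necrotic_tau_ns,
    necrotic_ppix_factor = meta$necrotic_ppix_factor,
    instrument_phase_rad = meta$instrument_phase_rad,
    instrument_modulation = meta$instrument_modulation,
    background_dc = meta$background_dc, frequency_hz = meta$frequency_hz,
    n_phase_steps = meta$n_phase_steps, noise = meta$noise,
    seed = meta$seed)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    sdir <- file.path(dir, row$sample_id)
    truth <- jsonlite::read_json(file.path(sdir, "truth.json"),
                                 simplifyVector = TRUE)
    structure(list(
      patient_id = row$patient_id, sample_id = row$sample_id,
      diagnosis = row$diagnosis, grade = row$grade, tissue = row$tissue,
      ala = row$ala, true_tau_nadh_ns = truth$true_tau_nadh_ns,
      true_tau_ppix_ns = truth$true_tau_ppix_ns,
      has_vessel = isTRUE(truth$has_vessel),
      stacks = list(NADH = read_stack_tiff(file.path(sdir, "nadh.tif")),
                    PPIX = read_stack_tiff(file.path(sdir, "ppix.tif"))),
      mask = tiff::readTIFF(file.path(sdir, "mask.tif")) > 0.5
    ), class = "flim_sample")
  })
  names(samples) <- manifest$sample_id
  structure(list(samples = samples,
                 reference = read_stack_tiff(file.path(dir, "reference.tif")),
                 manifest = manifest, config = config, seed = meta$seed),
            class = "flim_cohort")
}

#' Write pipeline-run result tables to disk
#'
#' Emits `cohort_table.csv`, `sample_summaries.csv`, per-key
#' `group_summaries_<key>.csv` and `pairwise_tests_<key>.csv`,
#' `phasors.csv` / `chord_fit.json` when the phasor stage ran,
#' `cv_result.json` when classification ran, and a `run_report.json`
#' recording counts, seeds and parameters. All lifetimes are in ns;
#' numbers are fixed to 6 significant digits so reruns are byte-identical.
#'
#' @param run a [run_pipeline()] result
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv6(run$cohort_table, file.path(dir, "cohort_table.csv"))
  report <- list(seed = run$seed, counts = run$counts,
                 unusable_samples = run$unusable_samples,
                 calibration = list(
                   instrument_phase_rad = run$calibration$instrument_phase_rad,
                   instrument_modulation = run$calibration$instrument_modulation),
                 stages = character(0))
  if (!is.null(run$sample_summaries)) {
    report$stages <- c(report$stages, "stats")
    write_csv6(run$sample_summaries, file.path(dir, "sample_summaries.csv"))
    for (k in names(run$group_summaries)) {
      write_csv6(run$group_summaries[[k]],
                 file.path(dir, sprintf("group_summaries_%s.csv", k)))
      write_csv6(run$tests[[k]],
                 file.path(dir, sprintf("pairwise_tests_%s.csv", k)))
    }
  }
  if (!is.null(run$classification)) {
    report$stages <- c(report$stages, "classify")
    cv <- lapply(run$classification, function(task)
      lapply(task, function(r) list(
        accuracy = r$accuracy,
        confusion = as.data.frame.matrix(unclass(r$confusion)),
        confusion_rate_pct = as.data.frame.matrix(round(unclass(r$confusion_rate), 2)),
        n = r$n, seed = r$seed)))
    jsonlite::write_json(cv, file.path(dir, "cv_result.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$chord)) {
    report$stages <- c(report$stages, "phasor")
    write_csv6(as.data.frame(run$phasor_cloud),
               file.path(dir, "phasors.csv"))
    ch <- run$chord
    jsonlite::write_json(
      list(fit_ok = ch$fit_ok, ill_conditioned = ch$ill_conditioned,
           tau_short_ns = fmt_num(ch$tau_short_ns),
           tau_long_ns = fmt_num(ch$tau_long_ns),
           residual_rms = fmt_num(ch$residual_rms),
           axis_ratio = fmt_num(ch$axis_ratio)),
      file.path(dir, "chord_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
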