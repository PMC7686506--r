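#' Run the full analysis pipeline on a cohort
#'
#' Executes the post-acquisition chain on a (synthetic or loaded) cohort:
#' calibrate against the reference stack, reconstruct both channels'
#' lifetime maps per sample, apply the segmentation and outlier masks,
#' draw the colocalized random pixels, and — per stage toggles — compute
#' group statistics, cross-validated classification, and the pooled PPIX
#' phasor chord fit.
#'
#' @param cohort a [generate_cohort()] result
#' @param mask_cfg a [mask_config()]
#' @param n_points sampled pixels per sample (default 100)
#' @param seed seed for pixel sampling and classification
#' @param stages character subset of `c("stats", "classify", "phasor")`
#' @param classifier_cfg a [classifier_config()] (used when `"classify"`
#'   is toggled)
#' @param keys grouping keys for the statistics stage
#' @return object of class `flim_run` with fields `calibration`,
#'   `cohort_table`, `sample_summaries`, `group_summaries` (list by key),
#'   `tests` (list by key, PPIX and NADH), `classification` (list by task
#'   and feature set), `chord` / `phasor_cloud`, `unusable_samples`,
#'   `counts`, `seed`
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(image_size = 48), seed = 3)
#' run <- run_pipeline(coh, seed = 3)
#' run$group_summaries$ala
#' }
run_pipeline <- function(cohort, mask_cfg = mask_config(), n_points = 100L,
                         seed = 1L, stages = c("stats", "phasor"),
                         classifier_cfg = classifier_config(),
                         keys = c("tissue", "grade", "ala")) {
  stopifnot(inherits(cohort, "flim_cohort"))
  stages <- match.arg(stages, c("stats", "classify", "phasor"),
                      several.ok = TRUE)
  calibration <- calibrate(cohort$reference, known_lifetime_ns = 0)
  sampled <- list()
  unusable <- character(0)
  for (i in seq_along(cohort$samples)) {
    smp <- cohort$samples[[i]]
    nadh <- apply_mask(reconstruct_map(smp$stacks$NADH, calibration),
                       smp$mask, mask_cfg)
    ppix <- apply_mask(reconstruct_map(smp$stacks$PPIX, calibration),
                       smp$mask, mask_cfg)
    if (!isTRUE(attr(nadh, "usable")) || !isTRUE(attr(ppix, "usable"))) {
      unusable <- c(unusable, smp$sample_id)
      next
    }
    sampled[[smp$sample_id]] <-
      sample_joint_pixels(nadh, ppix, n_points,
                          seed = mix_seed(seed, 1000L + i))
  }
  info <- cohort$manifest[cohort$manifest$sample_id %in% names(sampled), ]
  tab <- build_cohort_table(info, sampled)
  out <- list(calibration = calibration, cohort_table = tab,
              unusable_samples = unusable, seed = seed,
              counts = list(n_samples = length(sampled),
                            n_rows = nrow(tab), n_points = n_points))
  if ("stats" %in% stages) {
    out$sample_summaries <- summarize_samples(tab)
    out$group_summaries <- lapply(stats::setNames(keys, keys), function(k)
      summarize_groups(out$sample_summaries, k))
    out$tests <- lapply(stats::setNames(keys, keys), function(k)
      rbind(pairwise_comparisons(out$sample_summaries, k, "ppix"),
            pairwise_comparisons(out$sample_summaries, k, "nadh")))
  }
  if ("classify" %in% stages) {
    ds <- build_datasets(tab)
    out$classification <- list(
      grade = list(
        ppix_only = cross_validate(label ~ tau_ppix_ns, ds$grade,
                                   classifier_cfg, seed = mix_seed(seed, 21L)),
        nadh_ppix = cross_validate(label ~ tau_nadh_ns + tau_ppix_ns,
                                   ds$grade, classifier_cfg,
                                   seed = mix_seed(seed, 21L))),
      tissue = list(
        ppix_only = cross_validate(label ~ tau_ppix_ns, ds$tissue,
                                   classifier_cfg, seed = mix_seed(seed, 22L)),
        nadh_ppix = cross_validate(label ~ tau_nadh_ns + tau_ppix_ns,
                                   ds$tissue, classifier_cfg,
                                   seed = mix_seed(seed, 22L))))
  }
  if ("phasor" %in% stages) {
    coords <- lapply(sampled, function(p) p[, c("row", "col")])
    out$phasor_cloud <- phasor_cloud(cohort, calibration, "PPIX", coords)
    out$chord <- fit_chord(out$phasor_cloud)
  }
  structure(out, class = "flim_run")
}

#' @export
print.flim_run <- function(x, ...) {
  cat(sprintf("FLIM pipeline run: %d samples, %d table rows (seed %d)\n",
              x$counts$n_samples, x$counts$n_rows, x$seed))
  if (length(x$unusable_samples))
    cat("  unusable samples:", paste(x$unusable_samples, collapse = ", "), "\n")
  if (!is.null(x$group_summaries$ala)) {
    cat("Group medians by ALA status (ns):\n")
    print(x$group_summaries$ala[, c("group", "n_samples", "nadh_median_ns",
                                    "ppix_median_ns")])
  }
  if (!is.null(x$chord) && isTRUE(x$chord$fit_ok))
    cat(sprintf("PPIX phasor chord: tau_short = %.2f ns, tau_long = %.2f ns\n",
                x$chord$tau_short_ns, x$chord$tau_long_ns))
  invisible(x)
}
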