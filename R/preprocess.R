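#' Outlier-mask configuration
#'
#' Lifetime thresholds restrict maps to physically meaningful values:
#' NADH is always a free/bound mixture shorter than pure bound NADH
#' (1-4 ns), so values at or above 5 ns (vessels) are discarded; pure PPIX
#' in solvent decays at ~16 ns, so PPIX values at or above 17 ns are
#' discarded. Pixels with intensity below the background noise floor are
#' discarded as well; the floor is either `dark mean + k * dark SD`
#' (`"dark_stats"`) or a fixed count level (`"fixed"`, the natural choice
#' for synthetic data without dark frames).
#'
#' @param nadh_max_ns,ppix_max_ns upper lifetime thresholds in ns
#' @param noise_floor_mode `"fixed"` or `"dark_stats"`
#' @param noise_floor_k dark-frame SD multiplier in `"dark_stats"` mode
#' @param fixed_floor fixed intensity floor in counts
#' @return object of class `mask_config`
#' @export
mask_config <- function(nadh_max_ns = 5, ppix_max_ns = 17,
                        noise_floor_mode = c("fixed", "dark_stats"),
                        noise_floor_k = 2, fixed_floor = 20) {
  noise_floor_mode <- match.arg(noise_floor_mode)
  stopifnot(nadh_max_ns > 0, ppix_max_ns > 0, fixed_floor >= 0)
  structure(list(nadh_max_ns = nadh_max_ns, ppix_max_ns = ppix_max_ns,
                 noise_floor_mode = noise_floor_mode,
                 noise_floor_k = noise_floor_k, fixed_floor = fixed_floor),
            class = "mask_config")
}

#' Apply segmentation and outlier masks to a lifetime map
#'
#' A pixel survives if it is inside the segmented tissue area, was validly
#' reconstructed, its lifetime is below the channel threshold, and its
#' intensity is at or above the noise floor. Everything else is excluded
#' from all downstream computation. Masking is idempotent and monotone in
#' the thresholds. An empty surviving mask flags the sample as unusable
#' (attribute `usable = FALSE`) with a warning rather than an error.
#'
#' @param map a [lifetime_map()]
#' @param segmentation logical matrix (inside-tissue mask); `NULL` keeps
#'   all pixels
#' @param config a [mask_config()]
#' @param dark_stats optional `list(mean =, sd =)` of dark-frame statistics
#'   for `"dark_stats"` mode
#' @return the masked [lifetime_map()]
#' @export
apply_mask <- function(map, segmentation = NULL, config = mask_config(),
                       dark_stats = NULL) {
  stopifnot(inherits(map, "lifetime_map"), inherits(config, "mask_config"))
  if (is.null(segmentation))
    segmentation <- matrix(TRUE, nrow(map$tau_ns), ncol(map$tau_ns))
  segmentation <- segmentation != 0
  if (!identical(dim(segmentation), dim(map$tau_ns)))
    stop("segmentation mask shape does not match the map")
  thr <- switch(map$channel, NADH = config$nadh_max_ns,
                PPIX = config$ppix_max_ns,
                stop("channel must be NADH or PPIX for masking"))
  floor <- if (config$noise_floor_mode == "dark_stats") {
    if (is.null(dark_stats))
      stop("dark_stats required in 'dark_stats' noise-floor mode")
    dark_stats$mean + config$noise_floor_k * dark_stats$sd
  } else config$fixed_floor
  valid <- map$valid & segmentation & !is.na(map$tau_ns) &
    map$tau_ns < thr & map$dc >= floor
  out <- map
  out$valid <- valid
  out$tau_ns[!valid] <- NA_real_
  attr(out, "usable") <- any(valid)
  if (!any(valid))
    warning(sprintf("sample unusable: no %s pixels survive masking",
                    map$channel))
  out
}

#' Randomly sample valid pixels from a masked lifetime map
#'
#' Uniform draw without replacement of `n_points` valid pixels; every
#' sample contributes the same number of lifetime values regardless of its
#' physical size. If fewer valid pixels exist than requested, the shortfall
#' policy either draws with replacement (with a warning) or raises.
#'
#' @param map a masked [lifetime_map()]
#' @param n_points number of pixels to draw (default 100)
#' @param seed RNG seed for the draw
#' @param replacement_policy `"with_replacement_warn"` or `"error"`
#' @return data.frame with 0-based `row`, `col` and `tau_ns`
#' @export
sample_pixels <- function(map, n_points = 100L, seed = NULL,
                          replacement_policy = c("with_replacement_warn",
                                                 "error")) {
  replacement_policy <- match.arg(replacement_policy)
  stopifnot(inherits(map, "lifetime_map"), n_points >= 1L)
  idx <- which(map$valid)
  if (length(idx) == 0L) stop("no valid pixels to sample")
  pick <- with_seed(seed, function() {
    if (length(idx) >= n_points) sample(idx, n_points)
    else if (replacement_policy == "with_replacement_warn") {
      warning(sprintf("only %d valid pixels for %d requested; sampling with replacement",
                      length(idx), n_points))
      sample(idx, n_points, replace = TRUE)
    } else stop(sprintf("only %d valid pixels for %d requested",
                        length(idx), n_points))
  })
  rc <- arrayInd(pick, dim(map$tau_ns))
  data.frame(row = rc[, 1] - 1L, col = rc[, 2] - 1L,
             tau_ns = map$tau_ns[pick])
}

#' Sample colocalized pixel pairs from both channels
#'
#' The classifier uses colocalized NADH/PPIX lifetime pairs, so one
#' coordinate set per sample is drawn from the intersection of the two
#' channels' valid masks and reused for both channels.
#'
#' @param nadh_map,ppix_map masked [lifetime_map()]s of the two channels
#' @inheritParams sample_pixels
#' @return data.frame with 0-based `row`, `col`, `tau_nadh_ns`,
#'   `tau_ppix_ns`
#' @export
sample_joint_pixels <- function(nadh_map, ppix_map, n_points = 100L,
                                seed = NULL,
                                replacement_policy = c("with_replacement_warn",
                                                       "error")) {
  replacement_policy <- match.arg(replacement_policy)
  stopifnot(identical(dim(nadh_map$tau_ns), dim(ppix_map$tau_ns)))
  joint <- nadh_map
  joint$valid <- nadh_map$valid & ppix_map$valid
  joint$tau_ns[!joint$valid] <- NA_real_
  pts <- sample_pixels(joint, n_points, seed, replacement_policy)
  lin <- pts$row + 1L + nrow(nadh_map$tau_ns) * pts$col
  data.frame(row = pts$row, col = pts$col,
             tau_nadh_ns = nadh_map$tau_ns[lin],
             tau_ppix_ns = ppix_map$tau_ns[lin])
}

#' Assemble the long-format cohort table
#'
#' One row per sampled pixel, carrying the sample's labels and the
#' colocalized NADH/PPIX lifetime pair. With the default 42-sample
#' inventory and 100 pixels per sample this yields 4200 rows.
#'
#' @param sample_info data.frame of sample metadata (`patient_id`,
#'   `sample_id`, `diagnosis`, `grade`, `tissue`, `ala`)
#' @param sampled_points named list (by `sample_id`) of data.frames from
#'   [sample_joint_pixels()]
#' @return data.frame of class `cohort_table`
#' @export
build_cohort_table <- function(sample_info, sampled_points) {
  missing <- setdiff(sample_info$sample_id, names(sampled_points))
  if (length(missing))
    stop("missing sampled points for: ", paste(missing, collapse = ", "))
  tab <- do.call(rbind, lapply(seq_len(nrow(sample_info)), function(i) {
    si <- sample_info[i, ]
    pts <- sampled_points[[si$sample_id]]
    if (is.null(pts$tau_nadh_ns) || is.null(pts$tau_ppix_ns))
      stop("sampled points for ", si$sample_id, " lack a channel")
    data.frame(patient_id = si$patient_id, sample_id = si$sample_id,
               diagnosis = si$diagnosis, grade = si$grade,
               tissue = si$tissue, ala = si$ala,
               row = pts$row, col = pts$col,
               tau_nadh_ns = pts$tau_nadh_ns,
               tau_ppix_ns = pts$tau_ppix_ns,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
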