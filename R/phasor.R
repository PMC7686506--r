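#' Calibrated phasor points of one sample
#'
#' Demodulates a raw stack and converts each selected pixel to phasor
#' coordinates after instrument correction: `g = m cos(phi)`,
#' `s = m sin(phi)` with the instrument phase subtracted and the
#' modulation divided by the instrument gain. Mono-exponential decays land
#' on the universal semicircle; mixtures land on chords inside it.
#'
#' @param stack a [raw_frame_stack()]
#' @param calibration a [calibrate()] result
#' @param coords optional data.frame with 0-based `row`, `col` restricting
#'   the pixels (typically the sampled coordinates from preprocessing);
#'   `NULL` uses all pixels with positive intensity
#' @return data.frame with columns `g`, `s`
#' @export
phasor_points <- function(stack, calibration, coords = NULL) {
  dem <- demodulate(stack)
  phi <- dem$phase_rad - calibration$instrument_phase_rad
  m <- dem$modulation / calibration$instrument_modulation
  g <- m * cos(phi)
  s <- m * sin(phi)
  if (is.null(coords)) {
    keep <- which(dem$valid)
  } else {
    keep <- (coords$row + 1L) + nrow(dem$dc) * coords$col
  }
  data.frame(g = g[keep], s = s[keep])
}

#' Pooled phasor cloud over a cohort
#'
#' Collects calibrated per-pixel phasors of one channel across samples,
#' with sample provenance.
#'
#' @param cohort a [generate_cohort()] result (or any list of
#'   `flim_sample` objects under `$samples`)
#' @param calibration a [calibrate()] result
#' @param channel `"PPIX"` or `"NADH"`
#' @param coords_list optional named list (by sample id) of coordinate
#'   data.frames, e.g. the sampled pixels reused from preprocessing
#' @return data.frame of class `phasor_cloud` with `sample_id`, `g`, `s`
#'   and attribute `frequency_hz`
#' @export
phasor_cloud <- function(cohort, calibration, channel = c("PPIX", "NADH"),
                         coords_list = NULL) {
  channel <- match.arg(channel)
  pts <- do.call(rbind, lapply(cohort$samples, function(smp) {
    co <- if (is.null(coords_list)) NULL else coords_list[[smp$sample_id]]
    p <- phasor_points(smp$stacks[[channel]], calibration, co)
    if (nrow(p) == 0L) return(NULL)
    cbind(sample_id = smp$sample_id, p, stringsAsFactors = FALSE)
  }))
  rownames(pts) <- NULL
  attr(pts, "frequency_hz") <- calibration$config$frequency_hz
  class(pts) <- c("phasor_cloud", "data.frame")
  pts
}

#' Fit the bi-exponential chord through a phasor cloud
#'
#' A two-component decay constrains all mixture phasors to the chord whose
#' intersections with the universal semicircle are the two component
#' lifetimes. The chord is fitted by total least squares (principal axis
#' of the 2x2 covariance of `(g, s)` — both coordinates are noisy), the
#' line is intersected with `(g - 1/2)^2 + s^2 = 1/4`, and each
#' intersection is converted via `tau = s / (g * w)`. A near-isotropic
#' cloud (principal-axis ratio < 1.5) is flagged ill-conditioned; a line
#' missing the circle yields a failed fit with residual diagnostics rather
#' than an error.
#'
#' @param cloud a [phasor_cloud()] or any data.frame with `g`, `s`
#' @param frequency_hz modulation frequency; defaults to the cloud's
#'   `frequency_hz` attribute
#' @return object of class `chord_fit`: `tau_short_ns`, `tau_long_ns`,
#'   `intersections`, `centroid`, `direction`, `residual_rms`,
#'   `axis_ratio`, `ill_conditioned`, `fit_ok`
#' @export
fit_chord <- function(cloud, frequency_hz = attr(cloud, "frequency_hz")) {
  stopifnot(!is.null(frequency_hz))
  pts <- unique(cbind(cloud$g, cloud$s))
  if (nrow(pts) < 2L) {
    return(structure(list(fit_ok = FALSE, ill_conditioned = TRUE,
                          tau_short_ns = NA_real_, tau_long_ns = NA_real_,
                          residual_rms = NA_real_, axis_ratio = 1,
                          centroid = colMeans(pts), direction = c(NA, NA),
                          intersections = NULL,
                          frequency_hz = frequency_hz),
                     class = "chord_fit"))
  }
  P <- cbind(cloud$g, cloud$s)
  ctr <- colMeans(P)
  V <- cov(P)
  ev <- eigen(V, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  lam <- pmax(ev$values, 0)
  axis_ratio <- sqrt(lam[1] / max(lam[2], 1e-300))
  residual_rms <- sqrt(lam[2])
  ill <- is.finite(axis_ratio) && axis_ratio < 1.5
  # intersect centroid + t * dir with the universal semicircle
  o <- c(0.5, 0)
  co <- ctr - o
  b <- sum(dir * co)
  cc <- sum(co^2) - 0.25
  disc <- b^2 - cc
  if (disc <= 0 || ill) {
    return(structure(list(fit_ok = disc > 0, ill_conditioned = ill,
                          tau_short_ns = NA_real_, tau_long_ns = NA_real_,
                          residual_rms = residual_rms,
                          axis_ratio = axis_ratio, centroid = ctr,
                          direction = dir, intersections = NULL,
                          frequency_hz = frequency_hz),
                     class = "chord_fit"))
  }
  t12 <- c(-b - sqrt(disc), -b + sqrt(disc))
  inter <- rbind(ctr + t12[1] * dir, ctr + t12[2] * dir)
  colnames(inter) <- c("g", "s")
  w <- omega_ns(frequency_hz)
  tau <- ifelse(inter[, "g"] > 1e-12,
                inter[, "s"] / (inter[, "g"] * w), Inf)
  ord <- order(tau)
  structure(list(fit_ok = TRUE, ill_conditioned = FALSE,
                 tau_short_ns = tau[ord[1]], tau_long_ns = tau[ord[2]],
                 intersections = inter[ord, , drop = FALSE],
                 centroid = ctr, direction = dir,
                 residual_rms = residual_rms, axis_ratio = axis_ratio,
                 frequency_hz = frequency_hz),
            class = "chord_fit")
}

#' @export
print.chord_fit <- function(x, ...) {
  if (!isTRUE(x$fit_ok)) {
    cat("Phasor chord fit: FAILED",
        if (x$ill_conditioned) "(ill-conditioned cloud)", "\n")
    cat(sprintf("  residual RMS = %.4g, axis ratio = %.3g\n",
                x$residual_rms, x$axis_ratio))
    return(invisible(x))
  }
  cat(sprintf(
    "Phasor chord fit: tau_short = %.3g ns, tau_long = %.3g ns\n",
    x$tau_short_ns, x$tau_long_ns))
  cat(sprintf("  residual RMS = %.4g, axis ratio = %.3g\n",
              x$residual_rms, x$axis_ratio))
  invisible(x)
}

#' Plot a phasor cloud with the universal semicircle and fitted chord
#'
#' @param x a [fit_chord()] result
#' @param cloud optional phasor cloud to draw beneath the chord
#' @param ... passed to [graphics::plot()]
#' @export
plot.chord_fit <- function(x, cloud = NULL, ...) {
  th <- seq(0, pi, length.out = 200)
  graphics::plot(0.5 + 0.5 * cos(th), 0.5 * sin(th), type = "l",
                 xlab = "g", ylab = "s", asp = 1,
                 xlim = c(0, 1), ylim = c(0, 0.6), ...)
  if (!is.null(cloud))
    graphics::points(cloud$g, cloud$s, pch = ".",
                     col = grDevices::adjustcolor("steelblue", 0.3))
  if (isTRUE(x$fit_ok) && !is.null(x$intersections)) {
    graphics::segments(x$intersections[1, "g"], x$intersections[1, "s"],
                       x$intersections[2, "g"], x$intersections[2, "s"],
                       col = "firebrick", lwd = 2)
    graphics::points(x$intersections[, "g"], x$intersections[, "s"],
                     pch = 19, col = "firebrick")
  }
  invisible(x)
}

#' Classify a decay as mono- or multi-exponential from its phasor cloud
#'
#' Points on the universal semicircle indicate a mono-exponential decay;
#' an elongated cloud strictly inside the circle indicates a
#' multi-exponential mixture. The decision uses the RMS distance of the
#' cloud from the semicircle, the cloud spread, the principal-axis ratio
#' and the centroid position; clouds matching neither pattern (for
#' instance small, noisy ones) are `indeterminate`.
#'
#' @param cloud a [phasor_cloud()] or data.frame with `g`, `s`
#' @param tolerance RMS distance tolerance from the semicircle
#' @return one of `"mono_exponential"`, `"multi_exponential"`,
#'   `"indeterminate"`
#' @export
classify_decay <- function(cloud, tolerance = 0.02) {
  stopifnot(nrow(cloud) >= 1L)
  r <- sqrt((cloud$g - 0.5)^2 + cloud$s^2)
  rms_circle <- sqrt(mean((r - 0.5)^2))
  ctr_inside <- sqrt((mean(cloud$g) - 0.5)^2 + mean(cloud$s)^2) <
    0.5 - tolerance
  V <- if (nrow(cloud) < 2L) matrix(0, 2, 2)
       else cov(cbind(cloud$g, cloud$s))
  lam <- pmax(eigen(V, symmetric = TRUE, only.values = TRUE)$values, 0)
  spread <- sqrt(lam[1])
  axis_ratio <- sqrt(lam[1] / max(lam[2], 1e-300))
  if (rms_circle <= tolerance && spread <= 5 * tolerance)
    return("mono_exponential")
  if (axis_ratio >= 1.5 && ctr_inside)
    return("multi_exponential")
  "indeterminate"
}
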