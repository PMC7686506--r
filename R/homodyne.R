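#' Raw homodyne frame stack
#'
#' Container for one channel's K phase-stepped homodyne frames. `frames` is
#' a `height x width x K` array of non-negative photon-count-scaled
#' intensities.
#'
#' @param frames numeric array `H x W x K`, all values >= 0
#' @param config [flim_config()]; `K` must equal `config$n_phase_steps`
#' @param channel channel label, one of `"NADH"`, `"PPIX"`, `"REF"`
#' @param exposure_ms exposure time per frame in ms (> 0)
#' @return object of class `raw_frame_stack`
#' @export
raw_frame_stack <- function(frames, config, channel = c("PPIX", "NADH", "REF"),
                            exposure_ms = 100) {
  channel <- match.arg(channel)
  stopifnot(inherits(config, "flim_config"), is.numeric(exposure_ms),
            exposure_ms > 0)
  if (length(dim(frames)) == 2L)
    dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L)
    stop("frames must be an H x W x K array")
  if (dim(frames)[3] != config$n_phase_steps)
    stop("frame count does not match config$n_phase_steps")
  if (any(frames < 0))
    stop("frame intensities must be non-negative")
  structure(list(frames = frames, config = config, channel = channel,
                 exposure_ms = exposure_ms),
            class = "raw_frame_stack")
}

#' @export
print.raw_frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Raw homodyne stack [%s]: %d x %d pixels, %d phase frames, %g ms\n",
              x$channel, d[1], d[2], d[3], x$exposure_ms))
  invisible(x)
}

# low-level forward model: frames from per-pixel total phase and modulation
homodyne_frames <- function(phase_rad, modulation, dc, config,
                            noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  theta <- config$phase_offsets_rad
  hw <- length(dc)
  expected <- vapply(theta, function(th)
    dc * (1 + modulation * cos(th - phase_rad)), numeric(hw))
  expected[expected < 0] <- 0 # guard tiny negatives when m*m_inst > 1
  if (noise == "poisson")
    expected <- with_seed(seed, function()
      array(rpois(length(expected), expected), dim = dim(expected)))
  dims <- if (is.null(dim(dc))) c(hw, 1L) else dim(dc)
  array(expected, dim = c(dims, config$n_phase_steps))
}

#' Simulate a homodyne frame stack for a decay model
#'
#' Forward model of the homodyne camera: the modulated excitation makes a
#' fluorophore population with mixture phasor `(g, s)` emit at the same
#' frequency with phase delay `phi = atan2(s, g)` and modulation depth
#' `m = sqrt(g^2 + s^2)`; the instrument adds a phase offset and a
#' modulation gain. Frame `k` then has expectation
#' `dc * (1 + m_tot * cos(theta_k - phi_tot))`, optionally Poisson-drawn.
#'
#' @param decay a [decay_model()]
#' @param dc mean (DC) intensity, scalar or image matrix, >= 0
#' @param config [flim_config()]
#' @param instrument_phase_rad instrument phase offset (rad)
#' @param instrument_modulation instrument modulation gain (> 0)
#' @param noise `"none"` or `"poisson"` (shot noise)
#' @param seed RNG seed for the Poisson draw (optional)
#' @param channel,exposure_ms stack metadata, see [raw_frame_stack()]
#' @return a [raw_frame_stack()]
#' @export
#' @examples
#' st <- simulate_frames(decay_model(5, 1), 1000, flim_config())
#' demodulate(st)$phase_rad[1, 1]
simulate_frames <- function(decay, dc, config = flim_config(),
                            instrument_phase_rad = 0,
                            instrument_modulation = 1,
                            noise = c("none", "poisson"), seed = NULL,
                            channel = "PPIX", exposure_ms = 100) {
  stopifnot(inherits(decay, "decay_model"))
  if (!is.numeric(instrument_modulation) || instrument_modulation <= 0)
    stop("instrument_modulation must be > 0")
  if (any(dc < 0)) stop("dc must be non-negative")
  dc <- if (is.null(dim(dc))) matrix(dc, 1L, length(dc)) else as.matrix(dc)
  ph <- mixture_phasor(decay, config$frequency_hz)
  phi_tot <- atan2(ph$s, ph$g) + instrument_phase_rad
  m_tot <- sqrt(ph$g^2 + ph$s^2) * instrument_modulation
  frames <- homodyne_frames(phi_tot, m_tot, dc, config, noise, seed)
  raw_frame_stack(frames, config, channel = channel, exposure_ms = exposure_ms)
}

#' Demodulate a homodyne frame stack
#'
#' Single-bin DFT estimator over the K phase-stepped frames: per pixel,
#' `C = (2/K) sum_k I_k cos(theta_k)`, `S = (2/K) sum_k I_k sin(theta_k)`,
#' `dc = mean(I_k)`, phase `phi = atan2(S, C)` wrapped to `[0, 2*pi)` and
#' modulation `m = sqrt(C^2 + S^2)/dc`. For uniformly spaced phase steps
#' the estimator is exact on noiseless sinusoids (discrete orthogonality).
#' Pixels with `dc = 0` are flagged invalid, not raised as errors.
#'
#' @param stack a [raw_frame_stack()]
#' @return list of class `demodulation` with image fields `phase_rad`,
#'   `modulation`, `dc`, `valid`
#' @export
demodulate <- function(stack) {
  stopifnot(inherits(stack, "raw_frame_stack"))
  theta <- stack$config$phase_offsets_rad
  K <- length(theta)
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = d[1] * d[2], ncol = K)
  C <- as.vector(flat %*% cos(theta)) * (2 / K)
  S <- as.vector(flat %*% sin(theta)) * (2 / K)
  dc <- rowMeans(flat)
  valid <- dc > 0
  phase <- rep(NA_real_, length(dc))
  m <- rep(NA_real_, length(dc))
  phase[valid] <- wrap_2pi(atan2(S[valid], C[valid]))
  m[valid] <- sqrt(C[valid]^2 + S[valid]^2) / dc[valid]
  shape <- function(x) { dim(x) <- d[1:2]; x }
  structure(list(phase_rad = shape(phase), modulation = shape(m),
                 dc = shape(dc), valid = shape(valid)),
            class = "demodulation")
}

#' Calibrate the instrument against a reference target
#'
#' A target of known lifetime `tau_ref` is measured to separate the
#' instrument response from the fluorescence signal: the instrument phase
#' is the (circular) mean measured phase minus `atan(w * tau_ref)`, and
#' the instrument modulation gain is the mean measured modulation times
#' `sqrt(1 + (w * tau_ref)^2)`. Calibration is global (one offset/gain per
#' system), matching macroscopic homodyne practice. The default reference
#' is an ideal scatterer (`tau_ref = 0`).
#'
#' @param reference a [raw_frame_stack()] of the reference target
#' @param known_lifetime_ns reference lifetime in ns (>= 0)
#' @return object of class `flim_calibration` with `instrument_phase_rad`,
#'   `instrument_modulation`, `known_lifetime_ns`, `config`
#' @export
calibrate <- function(reference, known_lifetime_ns = 0) {
  stopifnot(inherits(reference, "raw_frame_stack"), known_lifetime_ns >= 0)
  dem <- demodulate(reference)
  ok <- dem$valid & is.finite(dem$modulation) & dem$modulation > 0
  if (!any(ok))
    stop("calibration failure: reference has no pixels with modulation > 0")
  w <- omega_ns(reference$config$frequency_hz)
  wt <- w * known_lifetime_ns
  phi_meas <- atan2(mean(sin(dem$phase_rad[ok])), mean(cos(dem$phase_rad[ok])))
  structure(list(
    instrument_phase_rad = wrap_pi(phi_meas - atan(wt)),
    instrument_modulation = mean(dem$modulation[ok]) * sqrt(1 + wt^2),
    known_lifetime_ns = known_lifetime_ns,
    config = reference$config
  ), class = "flim_calibration")
}

#' @export
print.flim_calibration <- function(x, ...) {
  cat(sprintf(
    "FLIM calibration: phi_inst = %.4f rad, m_inst = %.4f (tau_ref = %g ns)\n",
    x$instrument_phase_rad, x$instrument_modulation, x$known_lifetime_ns))
  invisible(x)
}

#' Per-pixel lifetime map
#'
#' @param tau_ns matrix of phase lifetimes in ns (`NA` where invalid)
#' @param valid logical matrix of pixel validity
#' @param dc matrix of mean intensities
#' @param channel channel label
#' @param frequency_hz modulation frequency
#' @param phase_rad,modulation optional calibrated demodulation images,
#'   carried through for phasor analysis
#' @return object of class `lifetime_map`
#' @export
lifetime_map <- function(tau_ns, valid, dc, channel, frequency_hz,
                         phase_rad = NULL, modulation = NULL) {
  stopifnot(identical(dim(tau_ns), dim(valid)),
            identical(dim(tau_ns), dim(dc)))
  if (any(valid & !is.finite(tau_ns)))
    stop("tau_ns must be finite wherever valid")
  structure(list(tau_ns = tau_ns, valid = valid, dc = dc, channel = channel,
                 frequency_hz = frequency_hz, phase_rad = phase_rad,
                 modulation = modulation),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  v <- x$tau_ns[x$valid]
  cat(sprintf(
    "Lifetime map [%s]: %d x %d px, %d valid (%.1f%%), median %.2f ns\n",
    x$channel, nrow(x$tau_ns), ncol(x$tau_ns), sum(x$valid),
    100 * mean(x$valid),
    if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

#' Reconstruct a calibrated lifetime map from raw frames
#'
#' Demodulates the stack, subtracts the instrument phase, and converts the
#' calibrated phase to the phase lifetime `tan(phi)/(2*pi*f)`. Calibrated
#' phases falling outside `[0, pi/2)` (negative from noise around zero
#' lifetime, or beyond the tangent pole) are marked invalid rather than
#' wrapped, which avoids spurious huge lifetimes. The calibrated modulation
#' is carried through for phasor analysis; it does not enter the lifetime.
#'
#' @param stack a [raw_frame_stack()]
#' @param calibration a [calibrate()] result with matching configuration
#' @return a [lifetime_map()]
#' @export
reconstruct_map <- function(stack, calibration) {
  stopifnot(inherits(stack, "raw_frame_stack"),
            inherits(calibration, "flim_calibration"))
  if (!isTRUE(all.equal(stack$config$frequency_hz,
                        calibration$config$frequency_hz)) ||
      stack$config$n_phase_steps != calibration$config$n_phase_steps)
    stop("stack and calibration have different modulation configurations")
  dem <- demodulate(stack)
  phi <- wrap_pi(dem$phase_rad - calibration$instrument_phase_rad)
  valid <- dem$valid & is.finite(phi) & phi >= 0 & phi < pi / 2
  tau <- matrix(NA_real_, nrow(phi), ncol(phi))
  tau[valid] <- tan(phi[valid]) / omega_ns(stack$config$frequency_hz)
  m_cal <- dem$modulation / calibration$instrument_modulation
  lifetime_map(tau, valid, dem$dc, stack$channel, stack$config$frequency_hz,
               phase_rad = phi, modulation = m_cal)
}
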