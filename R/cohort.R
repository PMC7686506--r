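#' Per-tissue lifetime parameters (study descriptive statistics)
#'
#' Median and quartiles (ns) of the per-sample NADH and PPIX phase
#' lifetimes for each tissue class: NPL non-pathological parenchyma, REA
#' reactive parenchyma, INF infiltration zone, NEC necrotic area, TUM
#' compact tumor. These are the targets the synthetic generator realizes
#' in `mode = "tissue"`.
#'
#' @return data.frame with one row per tissue label
#' @export
tissue_lifetime_params <- function() {
  data.frame(
    label         = c("NPL", "REA", "INF", "NEC", "TUM"),
    nadh_median_ns = c(1.2, 2.5, 1.7, 2.4, 1.8),
    nadh_q25_ns    = c(1.2, 1.8, 1.4, 1.4, 1.7),
    nadh_q75_ns    = c(1.3, 3.0, 2.1, 2.6, 2.1),
    ppix_median_ns = c(1.9, 8.2, 3.2, 6.3, 11.3),
    ppix_q25_ns    = c(1.6, 7.4, 2.3, 3.6, 6.6),
    ppix_q75_ns    = c(2.1, 9.1, 5.7, 6.8, 12.9),
    stringsAsFactors = FALSE
  )
}

#' Per-ALA-status PPIX lifetime parameters
#'
#' Median and quartiles (ns) of the per-sample PPIX phase lifetime
#' conditioned on intraoperative fluorescence visibility: samples with
#' surgeon-visible PPIX fluorescence (ALA+) versus non-fluorescent samples
#' (ALA-). Used in `mode = "ala"`.
#'
#' @return data.frame with one row per status
#' @export
ala_lifetime_params <- function() {
  data.frame(
    status = c("ALA_POS", "ALA_NEG"),
    ppix_median_ns = c(11.0, 3.0),
    ppix_q25_ns = c(8.2, 2.3),
    ppix_q75_ns = c(12.9, 5.0),
    stringsAsFactors = FALSE
  )
}

#' Default cohort inventory (42 samples from 21 patients)
#'
#' Replicates the study's sample inventory: per-sample patient id,
#' diagnosis, tumor grade (LGG low-grade glioma, HGG high-grade glioma,
#' MET brain metastasis), histological tissue type and intraoperative ALA
#' fluorescence status. Totals: 42 samples over 21 patients; tissue
#' NPL 2 / REA 5 / INF 12 / NEC 7 / TUM 16; 21 ALA+ and 21 ALA-;
#' grade partition LGG 7, HGG 24, MET 11 samples.
#'
#' @return data.frame with columns `patient_id`, `sample_id`, `diagnosis`,
#'   `grade`, `tissue`, `ala`
#' @export
default_inventory <- function() {
  # patient, diagnosis, grade, tissue sequence, ala sequence ("P"/"N")
  rows <- list(
    list(1,  "Diffuse astrocytoma",          "LGG", c("TUM","TUM","TUM"), c("N","N","N")),
    list(2,  "Diffuse astrocytoma",          "LGG", c("INF","INF"),       c("N","N")),
    list(3,  "Oligodendroglioma",            "LGG", c("INF","INF"),       c("N","N")),
    list(4,  "Anaplastic astrocytoma",       "HGG", c("TUM","TUM"),       c("N","P")),
    list(5,  "Anaplastic oligodendroglioma", "HGG", "NPL",                "N"),
    list(6,  "Glioblastoma",                 "HGG", c("INF","TUM"),       c("N","P")),
    list(7,  "Glioblastoma",                 "HGG", c("INF","NEC"),       c("N","P")),
    list(8,  "Glioblastoma",                 "HGG", c("INF","TUM"),       c("N","P")),
    list(9,  "Glioblastoma",                 "HGG", c("INF","NEC"),       c("P","P")),
    list(10, "Glioblastoma",                 "HGG", c("NEC","TUM"),       c("N","P")),
    list(11, "Glioblastoma",                 "HGG", c("NEC","TUM"),       c("N","P")),
    list(12, "Glioblastoma",                 "HGG", c("INF","TUM"),       c("N","P")),
    list(13, "Glioblastoma",                 "HGG", "INF",                "P"),
    list(14, "Glioblastoma",                 "HGG", "TUM",                "P"),
    list(15, "Glioblastoma",                 "HGG", "TUM",                "P"),
    list(16, "Glioblastoma",                 "HGG", c("INF","TUM"),       c("P","P")),
    list(17, "Glioblastoma",                 "HGG", c("NPL","TUM"),       c("N","P")),
    list(18, "Metastasis (lung)",            "MET", c("REA","INF","TUM"), c("P","N","P")),
    list(19, "Metastasis (lung)",            "MET", c("REA","NEC"),       c("P","N")),
    list(20, "Metastasis (lung)",            "MET", c("REA","REA","NEC"), c("N","P","N")),
    list(21, "Metastasis (heart)",           "MET", c("REA","NEC","TUM"), c("P","N","P"))
  )
  inv <- do.call(rbind, lapply(rows, function(r) {
    k <- length(r[[4]])
    data.frame(patient_id = sprintf("P%02d", r[[1]]),
               sample_id = sprintf("P%02d_S%d", r[[1]], seq_len(k)),
               diagnosis = r[[2]], grade = r[[3]],
               tissue = r[[4]],
               ala = ifelse(r[[5]] == "P", "ALA_POS", "ALA_NEG"),
               stringsAsFactors = FALSE)
  }))
  rownames(inv) <- NULL
  inv
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic study generator. The two conditioning modes
#' reflect the two marginal summaries the generator can match: in
#' `mode = "tissue"` the per-sample PPIX lifetime is drawn from the tissue
#' class distribution; in `mode = "ala"` from the ALA-status distribution
#' (NADH always follows the tissue class; non-pathological samples always
#' use NPL parameters for both channels). Apparent lifetimes are realized
#' as two-component decays — PPIX mixes 16 ns (pure PPIX) with 1.9 ns
#' autofluorescence; NADH mixes bound (4.0 ns) and free (0.4 ns) NADH.
#' Vessels appear as mono-exponential ~5.5 ns NADH streaks and necrotic
#' cores push NADH below 1 ns with a 40% PPIX reduction.
#'
#' @param mode `"tissue"` or `"ala"`: which conditioning drives the PPIX
#'   sample lifetimes
#' @param inventory sample inventory, default [default_inventory()]
#' @param image_size image side length in pixels
#' @param photon_budget mean DC counts per frame inside the sample
#' @param pixel_jitter_cv per-pixel lognormal coefficient of variation of
#'   the lifetime within a sample
#' @param ppix_components,nadh_components `c(tau_long, tau_short)` in ns
#' @param vessel_tau_ns NADH lifetime of vessel artifacts (mono-exponential)
#' @param vessel_fraction fraction of samples carrying a vessel streak
#' @param necrotic_tau_ns NADH lifetime inside a necrotic core
#' @param necrotic_ppix_factor multiplicative PPIX lifetime reduction
#'   inside the core
#' @param instrument_phase_rad,instrument_modulation simulated instrument
#'   response (recovered by calibration downstream)
#' @param background_dc DC counts outside the sample region
#' @param frequency_hz,n_phase_steps modulation settings
#' @param noise `"poisson"` or `"none"`
#' @param seed default cohort seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(mode = c("tissue", "ala"),
                          inventory = default_inventory(),
                          image_size = 256L,
                          photon_budget = 2000,
                          pixel_jitter_cv = 0.05,
                          ppix_components = c(16, 1.9),
                          nadh_components = c(4.0, 0.4),
                          vessel_tau_ns = 5.5,
                          vessel_fraction = 0.3,
                          necrotic_tau_ns = 0.7,
                          necrotic_ppix_factor = 0.6,
                          instrument_phase_rad = 0.2,
                          instrument_modulation = 0.9,
                          background_dc = 5,
                          frequency_hz = 1e7,
                          n_phase_steps = 16L,
                          noise = c("poisson", "none"),
                          seed = 1L) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  stopifnot(nrow(inventory) >= 1L, photon_budget > 0,
            ppix_components[1] > ppix_components[2],
            nadh_components[1] > nadh_components[2],
            image_size >= 16L)
  structure(list(
    mode = mode, inventory = inventory, image_size = as.integer(image_size),
    photon_budget = photon_budget, pixel_jitter_cv = pixel_jitter_cv,
    ppix_components = ppix_components, nadh_components = nadh_components,
    vessel_tau_ns = vessel_tau_ns, vessel_fraction = vessel_fraction,
    necrotic_tau_ns = necrotic_tau_ns,
    necrotic_ppix_factor = necrotic_ppix_factor,
    instrument_phase_rad = instrument_phase_rad,
    instrument_modulation = instrument_modulation,
    background_dc = background_dc,
    flim = flim_config(frequency_hz, n_phase_steps),
    noise = noise, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Draw one per-sample apparent lifetime from median/quartile targets
#'
#' Samples from the lognormal distribution whose median equals the target
#' median and whose quartile ratio matches the target interquartile range:
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`. Draws are clipped to the
#' feasible apparent-lifetime range of the channel's two-component mixture;
#' because clipping acts only in the tails, the distribution median is
#' preserved.
#'
#' @param median_ns,q25_ns,q75_ns distribution targets in ns
#' @param n number of draws
#' @param range feasible `c(lower, upper)` clip range in ns
#' @return numeric vector of `n` lifetimes (uses the current RNG stream)
#' @export
draw_sample_lifetime <- function(median_ns, q25_ns, q75_ns, n = 1L,
                                 range = c(0, Inf)) {
  stopifnot(q25_ns <= median_ns, median_ns <= q75_ns, median_ns > 0)
  sdlog <- log(q75_ns / q25_ns) / (2 * qnorm(0.75))
  x <- if (sdlog == 0) rep(median_ns, n)
       else rlnorm(n, meanlog = log(median_ns), sdlog = sdlog)
  pmin(pmax(x, range[1]), range[2])
}

# random filled ellipse mask; axes as fractions of the field
ellipse_mask <- function(size, center, semi_axes, angle) {
  xy <- expand.grid(row = seq_len(size), col = seq_len(size))
  dx <- xy$col - center[2]
  dy <- xy$row - center[1]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  m <- (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
  matrix(m, size, size)
}

#' Generate one synthetic tissue sample
#'
#' Draws the sample's apparent NADH and PPIX lifetimes from the group
#' parameters selected by the conditioning mode, converts them to
#' two-component decay mixtures, renders per-pixel lifetime maps (lognormal
#' pixel jitter inside a random elliptical sample region, plus necrotic
#' core and vessel artifacts where applicable), and synthesizes
#' Poisson-noised homodyne stacks for both channels through the simulated
#' instrument response.
#'
#' @param record one row of the inventory (list or single-row data.frame)
#' @param config a [cohort_config()]
#' @param seed per-sample RNG seed
#' @return object of class `flim_sample`: labels, ground-truth lifetimes,
#'   `stacks$NADH` / `stacks$PPIX`, segmentation `mask`
#' @export
generate_sample <- function(record, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  record <- as.list(record)
  with_seed(seed, function() {
    tp <- tissue_lifetime_params()
    ap <- ala_lifetime_params()
    trow <- tp[tp$label == record$tissue, ]
    if (nrow(trow) != 1L)
      stop(sprintf("unknown tissue label '%s' in sample %s",
                   record$tissue, record$sample_id))
    eps <- 0.05
    nadh_rng <- c(config$nadh_components[2] + eps,
                  config$nadh_components[1] - eps)
    ppix_rng <- c(config$ppix_components[2] + eps,
                  config$ppix_components[1] - eps)
    tau_nadh <- draw_sample_lifetime(trow$nadh_median_ns, trow$nadh_q25_ns,
                                     trow$nadh_q75_ns, range = nadh_rng)
    if (record$tissue != "NPL" && config$mode == "ala") {
      arow <- ap[ap$status == record$ala, ]
      tau_ppix <- draw_sample_lifetime(arow$ppix_median_ns, arow$ppix_q25_ns,
                                       arow$ppix_q75_ns, range = ppix_rng)
    } else {
      tau_ppix <- draw_sample_lifetime(trow$ppix_median_ns, trow$ppix_q25_ns,
                                       trow$ppix_q75_ns, range = ppix_rng)
    }

    n <- config$image_size
    center <- runif(2, 0.4 * n, 0.6 * n)
    axes <- runif(2, 0.22 * n, 0.42 * n)
    angle <- runif(1, 0, pi)
    mask <- ellipse_mask(n, center, axes, angle)

    jit <- function(base) {
      m <- matrix(base, n, n)
      if (config$pixel_jitter_cv > 0) {
        sdlog <- sqrt(log(1 + config$pixel_jitter_cv^2))
        m <- m * matrix(rlnorm(n * n, 0, sdlog), n, n)
      }
      m
    }
    nadh_map <- jit(tau_nadh)
    ppix_map <- jit(tau_ppix)

    # necrotic core: NADH below 1 ns, PPIX reduced relative to rim
    if (record$tissue == "NEC") {
      core <- ellipse_mask(n, center, axes * 0.4, angle)
      core <- core & mask
      core_tau <- config$necrotic_tau_ns *
        exp(rnorm(sum(core), 0, sqrt(log(1 + config$pixel_jitter_cv^2))))
      nadh_map[core] <- pmin(core_tau, 0.99)
      ppix_map[core] <- pmax(ppix_map[core] * config$necrotic_ppix_factor,
                             ppix_rng[1])
    }
    # vessel streak: mono-exponential high-lifetime NADH, removed later by
    # the 5 ns threshold mask
    has_vessel <- runif(1) < config$vessel_fraction
    if (has_vessel) {
      r0 <- round(runif(1, 0.35 * n, 0.65 * n))
      rows <- pmax(1L, pmin(n, r0 + c(0L, 1L)))
      vessel <- matrix(FALSE, n, n)
      vessel[rows, ] <- TRUE
      vessel <- vessel & mask
      nadh_map[vessel] <- config$vessel_tau_ns
    }

    nadh_map <- pmin(pmax(nadh_map, 0.05), 60)
    ppix_map <- pmin(pmax(ppix_map, ppix_rng[1]), 60)

    dc <- matrix(config$background_dc, n, n)
    dc[mask] <- config$photon_budget

    render <- function(tau_map, comps, channel) {
      ph <- tau_map_to_phasor(tau_map, comps[1], comps[2],
                              config$flim$frequency_hz)
      phi <- atan2(ph$s, ph$g) + config$instrument_phase_rad
      m <- sqrt(ph$g^2 + ph$s^2) * config$instrument_modulation
      frames <- homodyne_frames(phi, m, dc, config$flim, config$noise,
                                seed = NULL)
      raw_frame_stack(frames, config$flim, channel = channel,
                      exposure_ms = 100)
    }
    structure(list(
      patient_id = record$patient_id, sample_id = record$sample_id,
      diagnosis = record$diagnosis, grade = record$grade,
      tissue = record$tissue, ala = record$ala,
      true_tau_nadh_ns = tau_nadh, true_tau_ppix_ns = tau_ppix,
      has_vessel = has_vessel,
      stacks = list(NADH = render(nadh_map, config$nadh_components, "NADH"),
                    PPIX = render(ppix_map, config$ppix_components, "PPIX")),
      mask = mask
    ), class = "flim_sample")
  })
}

#' Generate a full synthetic cohort
#'
#' One [generate_sample()] per inventory row plus a shared calibration
#' reference stack (ideal scatterer, `tau_ref = 0`). Each sample uses an
#' independent RNG stream derived from `(seed, row index)`, so cohorts are
#' reproducible independently of generation order.
#'
#' @param config a [cohort_config()]
#' @param seed cohort seed (defaults to `config$seed`)
#' @return object of class `flim_cohort`: `samples` (list of
#'   `flim_sample`), `reference` stack, `manifest` data.frame, `config`
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(image_size = 32), seed = 7)
#' nrow(coh$manifest)
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  inv <- config$inventory
  if (anyDuplicated(inv$sample_id))
    stop("duplicate sample ids in inventory")
  samples <- lapply(seq_len(nrow(inv)), function(i)
    generate_sample(inv[i, ], config, seed = mix_seed(seed, i)))
  names(samples) <- inv$sample_id
  ref_dc <- matrix(config$photon_budget, config$image_size, config$image_size)
  ref_frames <- with_seed(mix_seed(seed, 0L), function()
    homodyne_frames(config$instrument_phase_rad,
                    config$instrument_modulation, ref_dc, config$flim,
                    config$noise))
  reference <- raw_frame_stack(ref_frames, config$flim, channel = "REF",
                               exposure_ms = 100)
  manifest <- cbind(inv,
    true_tau_nadh_ns = vapply(samples, `[[`, 0, "true_tau_nadh_ns"),
    true_tau_ppix_ns = vapply(samples, `[[`, 0, "true_tau_ppix_ns"))
  rownames(manifest) <- NULL
  structure(list(samples = samples, reference = reference,
                 manifest = manifest, config = config, seed = seed),
            class = "flim_cohort")
}

#' @export
print.flim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic FLIM cohort: %d samples / %d patients (mode = %s, seed = %d)\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              x$config$mode, x$seed))
  print(table(x$manifest$tissue))
  invisible(x)
}
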