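# Synthetic spectrometer cohort: a broadband LED envelope, dark/white
# references, and tissue reflectance with Gaussian oxyhemoglobin absorption
# troughs at 543 and 578 nm flanking the 561 nm peak. The generator defines
# the study conditions every pipeline test runs under; defaults reproduce the
# qualitative contrast between a pronounced tracheal trough-peak-trough
# signature and a less pronounced esophageal one.

#' Configuration of the synthetic spectra generator
#'
#' Defaults emulate the acquisition design (9 organ pairs, 50 spectra per
#' organ, 470-850 nm source) and a class contrast in which tracheal trough
#' depths clearly exceed esophageal ones, so the default cohort is linearly
#' separable in the (r543, r578) plane. Depth and noise defaults are generator
#' calibration choices, not measured values.
#'
#' @param n_pairs number of organ pairs (default 9).
#' @param n_per_organ spectra per organ (default 50).
#' @param seed RNG seed; the whole cohort is a pure function of the config.
#' @param grid_start,grid_stop,grid_step wavelength grid, nm (470/850/0.5).
#' @param grid optional explicit (possibly non-uniform) grid overriding the
#'   regular one; must cover 535-585 nm.
#' @param trough_centers absorption trough centers, nm (543, 578).
#' @param trough_widths Gaussian sigma of each trough, nm (9, 11).
#' @param depth_trachea,depth_esophagus mean fractional trough depths at
#'   (543, 578); trachea (0.35, 0.40), esophagus (0.12, 0.15).
#' @param organ_depth_sd between-organ lognormal sigma on depth (0.10).
#' @param spectrum_depth_sd per-spectrum lognormal depth jitter (0.02),
#'   emulating contact and anatomical variation along the organ.
#' @param noise_rel within-spectrum multiplicative noise SD (0.01).
#' @param dark_level,dark_noise_sd dark reference level and noise, counts
#'   (100, 2).
#' @param white_peak peak of the LED envelope above dark, counts (50000).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 9L, n_per_organ = 50L, seed = 1L,
                              grid_start = 470, grid_stop = 850, grid_step = 0.5,
                              grid = NULL,
                              trough_centers = c(543, 578),
                              trough_widths = c(9, 11),
                              depth_trachea = c(0.35, 0.40),
                              depth_esophagus = c(0.12, 0.15),
                              organ_depth_sd = 0.10,
                              spectrum_depth_sd = 0.02,
                              noise_rel = 0.01,
                              dark_level = 100, dark_noise_sd = 2,
                              white_peak = 50000) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_per_organ = as.integer(n_per_organ),
              seed = as.integer(seed), grid_start = grid_start,
              grid_stop = grid_stop, grid_step = grid_step, grid = grid,
              trough_centers = trough_centers, trough_widths = trough_widths,
              depth_trachea = depth_trachea, depth_esophagus = depth_esophagus,
              organ_depth_sd = organ_depth_sd,
              spectrum_depth_sd = spectrum_depth_sd,
              noise_rel = noise_rel, dark_level = dark_level,
              dark_noise_sd = dark_noise_sd, white_peak = white_peak)
  if (cfg$n_pairs < 1L || cfg$n_per_organ < 1L) {
    abort_parameter("n_pairs and n_per_organ must be >= 1")
  }
  depths <- c(cfg$depth_trachea, cfg$depth_esophagus)
  if (length(cfg$depth_trachea) != 2L || length(cfg$depth_esophagus) != 2L ||
      any(depths < 0) || any(depths >= 1)) {
    abort_parameter("class trough depths must be pairs in [0, 1)")
  }
  if (length(cfg$trough_widths) != 2L || any(cfg$trough_widths <= 0)) {
    abort_parameter("trough widths must be positive")
  }
  if (any(c(cfg$organ_depth_sd, cfg$spectrum_depth_sd, cfg$noise_rel,
            cfg$dark_noise_sd) < 0)) {
    abort_parameter("all noise SDs must be >= 0")
  }
  if (cfg$white_peak <= 0) abort_parameter("white_peak must be positive")
  check_grid(sim_grid(cfg))
  structure(cfg, class = "simulation_config")
}

sim_grid <- function(cfg) {
  if (!is.null(cfg$grid)) return(as.numeric(cfg$grid))
  seq(cfg$grid_start, cfg$grid_stop, by = cfg$grid_step)
}

#' Slowly varying tissue baseline
#'
#' Gentle order-1 polynomial multiplying the trough model, emulating the broad
#' scattering background of mucosa: `1 + 2e-5 (l - 561) - 1.5e-7 (l - 561)^2`.
#' Its variation across the 543-578 nm feature window is below 1e-3 after
#' peak normalization, so a zero-depth tissue maps to features (1, 1) up to
#' that curvature.
#'
#' @param lambda wavelength(s), nm.
#' @return Baseline value(s), dimensionless, positive over 470-850 nm.
#' @export
spectral_baseline <- function(lambda) {
  dl <- lambda - PEAK_NM
  1 + 2e-5 * dl - 1.5e-7 * dl^2
}

#' Model reflectance of a tissue with given trough depths
#'
#' `R(l) = B(l) * (1 - d543 * G(l; c1, s1) - d578 * G(l; c2, s2))` with
#' [spectral_baseline] `B` and unit-height Gaussians `G`. This closed form is
#' what [make_tissue_spectrum] samples around, and what parameter-recovery
#' inversions use.
#'
#' @param lambda wavelength(s), nm.
#' @param d543,d578 fractional trough depths at the configured centers.
#' @param cfg a [simulation_config] supplying centers and widths.
#' @return Reflectance value(s), dimensionless.
#' @export
model_reflectance <- function(lambda, d543, d578, cfg = simulation_config()) {
  g1 <- exp(-(lambda - cfg$trough_centers[1L])^2 / (2 * cfg$trough_widths[1L]^2))
  g2 <- exp(-(lambda - cfg$trough_centers[2L])^2 / (2 * cfg$trough_widths[2L]^2))
  spectral_baseline(lambda) * (1 - d543 * g1 - d578 * g2)
}

# Broadband LED envelope: sum of two wide Gaussians spanning the grid,
# rescaled so its maximum over the grid equals white_peak. Strictly positive.
led_envelope <- function(lambda, white_peak) {
  f <- exp(-(lambda - 600)^2 / (2 * 100^2)) +
    0.5 * exp(-(lambda - 500)^2 / (2 * 35^2))
  white_peak * f / max(f)
}

#' Generate dark and white reference spectra
#'
#' `dark = dark_level + N(0, dark_noise_sd)` per grid point; `white = dark +
#' LED envelope` with peak `white_peak`, so white strictly exceeds dark
#' everywhere. Draws from the current RNG state (seed management happens in
#' [simulate_cohort]).
#'
#' @param cfg a [simulation_config].
#' @return A [reference_set].
#' @export
make_references <- function(cfg) {
  grid <- sim_grid(cfg)
  dark <- cfg$dark_level + rnorm(length(grid), 0, cfg$dark_noise_sd)
  white <- dark + led_envelope(grid, cfg$white_peak)
  reference_set(grid, dark, white)
}

#' Generate one tissue acquisition
#'
#' Realized trough depths are the organ's class means (`depth_trachea` or
#' `depth_esophagus`) times the per-organ lognormal factors in
#' `organ_factors`, times a per-spectrum lognormal jitter
#' (`spectrum_depth_sd`). Raw counts follow the detector model
#' `dark + (white - dark) * R * (1 + N(0, noise_rel))`, clipped at zero.
#' Draws from the current RNG state.
#'
#' @param cfg a [simulation_config].
#' @param organ "trachea" or "esophagus".
#' @param refs the cohort's [reference_set].
#' @param organ_factors length-2 multiplicative depth factors for this organ
#'   (drawn once per organ by [simulate_cohort]).
#' @return List with `counts` (numeric vector on the grid) and `depths`
#'   (realized `c(d543, d578)`).
#' @export
make_tissue_spectrum <- function(cfg, organ, refs, organ_factors = c(1, 1)) {
  organ <- match.arg(organ, ORGANS)
  class_mean <- if (organ == "trachea") cfg$depth_trachea else cfg$depth_esophagus
  jitter <- exp(rnorm(2L, 0, cfg$spectrum_depth_sd))
  depths <- pmin(class_mean * organ_factors * jitter, 0.99)
  grid <- refs$wavelength
  R <- model_reflectance(grid, depths[1L], depths[2L], cfg)
  noise <- if (cfg$noise_rel > 0) rnorm(length(grid), 0, cfg$noise_rel) else 0
  counts <- refs$dark + (refs$white - refs$dark) * R * (1 + noise)
  list(counts = pmax(counts, 0), depths = depths)
}

#' Simulate a full acquisition cohort
#'
#' Generates references, then `n_pairs x 2 organs x n_per_organ` spectra with
#' unique metadata, all sharing the references' grid. Between-organ depth
#' variability is one lognormal factor pair per (pair_id, organ). The result
#' is a pure function of the config: equal seeds give bit-identical datasets.
#' The caller's RNG state is left untouched.
#'
#' @param cfg a [simulation_config].
#' @return List with `dataset` (a [spectra_dataset]) and `ground_truth`
#'   (data.frame: pair_id, organ, acq_index, d543, d578).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config")) {
    cfg <- do.call(simulation_config, as.list(cfg))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  refs <- make_references(cfg)
  n_total <- cfg$n_pairs * 2L * cfg$n_per_organ
  grid <- refs$wavelength
  values <- matrix(NA_real_, nrow = length(grid), ncol = n_total)
  meta <- data.frame(pair_id = integer(n_total), organ = character(n_total),
                     acq_index = integer(n_total))
  gt <- data.frame(pair_id = integer(n_total), organ = character(n_total),
                   acq_index = integer(n_total), d543 = numeric(n_total),
                   d578 = numeric(n_total))
  j <- 0L
  for (pair in seq_len(cfg$n_pairs)) {
    for (organ in c("trachea", "esophagus")) {
      organ_factors <- exp(rnorm(2L, 0, cfg$organ_depth_sd))
      for (acq in seq_len(cfg$n_per_organ)) {
        j <- j + 1L
        sp <- make_tissue_spectrum(cfg, organ, refs, organ_factors)
        values[, j] <- sp$counts
        meta[j, ] <- list(pair, organ, acq)
        gt[j, ] <- list(pair, organ, acq, sp$depths[1L], sp$depths[2L])
      }
    }
  }
  provenance <- list(
    text = sprintf("synthetic cohort: %d pairs x 2 organs x %d spectra",
                   cfg$n_pairs, cfg$n_per_organ),
    seed = cfg$seed,
    generator = "airwayspec::simulate_cohort")
  ds <- spectra_dataset(spectra_set(grid, values, meta), refs, provenance)
  list(dataset = ds, ground_truth = gt)
}
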