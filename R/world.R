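# The synthetic world: six ladybird-like species archetypes with
# parametric elytra/spot/background spectra, a known honesty rule linking
# conspicuousness to toxicity, and a known conspicuousness-survival rule
# for field predation. Every downstream stage recovers parameters that
# are explicit here.

#' Default species archetypes
#'
#' Six archetypes mirroring the study community: red (2-spot), its black
#' morph, orange, black (pine), yellow (14-spot) and brown (larch), with
#' mean body sizes matching the studied species and toxicity ordered
#' orange > red = black morph > black > yellow > brown via the honesty
#' rule (more contrasting species are more toxic) plus species baselines.
#'
#' @return Named list of archetype descriptions. Each holds parametric
#'   spectra generators for elytra, spot and background plus `size_mm`.
#' @export
default_archetypes <- function() {
  list(
    red = list(size_mm = 4.87, background = "nettle",
               elytra = list(kind = "sigmoid", mid = 595, high = 0.65, low = 0.04),
               spot = list(kind = "flat", level = 0.05)),
    black_morph = list(size_mm = 4.87, background = "nettle",
                       elytra = list(kind = "flat", level = 0.06),
                       spot = list(kind = "sigmoid", mid = 595, high = 0.55,
                                   low = 0.04)),
    orange = list(size_mm = 5.83, background = "sycamore", tox_offset = 0.3,
                  elytra = list(kind = "sigmoid", mid = 565, high = 0.70,
                                low = 0.05),
                  spot = list(kind = "flat", level = 0.80)),
    black = list(size_mm = 4.05, background = "pine",
                 elytra = list(kind = "flat", level = 0.05),
                 spot = list(kind = "sigmoid", mid = 595, high = 0.50,
                             low = 0.04)),
    yellow = list(size_mm = 4.06, background = "nettle",
                  elytra = list(kind = "sigmoid", mid = 515, high = 0.72,
                                low = 0.06),
                  spot = list(kind = "flat", level = 0.05)),
    brown = list(size_mm = 4.25, background = "larch",
                 elytra = list(kind = "sigmoid", mid = 580, high = 0.35,
                               low = 0.08, slope = 0.015),
                 spot = list(kind = "sigmoid", mid = 580, high = 0.25,
                             low = 0.06, slope = 0.015))
  )
}

# background (plant) spectra by name
.background_spectrum <- function(name, wl, jitter = 0) {
  switch(name,
    nettle = gaussian_reflectance(wl, peak = 550 + jitter * 4, width = 35,
                                  height = 0.10 + jitter * 0.01, base = 0.05),
    sycamore = gaussian_reflectance(wl, peak = 552 + jitter * 4, width = 38,
                                    height = 0.12 + jitter * 0.01, base = 0.05),
    pine = sigmoid_reflectance(wl, midpoint = 610 + jitter * 5, slope = 0.012,
                               low = 0.05, high = 0.28 + jitter * 0.01),
    larch = sigmoid_reflectance(wl, midpoint = 600 + jitter * 5, slope = 0.012,
                                low = 0.06, high = 0.30 + jitter * 0.01),
    stop("unknown background '", name, "'")
  )
}

# realise one surface spectrum from an archetype patch description
.patch_spectrum <- function(desc, wl, mid_jit = 0, amp_jit = 0) {
  if (desc$kind == "flat") {
    flat_reflectance(wl, min(max(desc$level * exp(amp_jit), 0.01), 0.98))
  } else {
    sl <- if (!is.null(desc$slope)) desc$slope else 0.08
    sigmoid_reflectance(wl, midpoint = desc$mid + mid_jit, slope = sl,
                        low = desc$low,
                        high = min(max(desc$high + amp_jit * desc$high, 0.05), 0.98))
  }
}

#' Synthetic world configuration
#'
#' Bundles every ground-truth parameter of the generator. The honesty
#' rule is `log-toxicity = honesty_intercept + honesty_slope * JND +
#' noise`, with JND the specimen's true chromatic contrast against its
#' species' background; the predation rule is
#' `log hazard = log(baseline_hazard) - hazard_coefficient * JND`.
#'
#' @param seed Integer seed; a fixed seed reproduces the world exactly.
#' @param species_archetypes Archetype list (default
#'   [default_archetypes()]).
#' @param honesty_slope Change in log-toxicity per JND of chromatic
#'   contrast (default 0.07: spans the 0--10 dead-Daphnia assay range over
#'   the ~1--27 JND contrast range of the archetypes).
#' @param honesty_intercept Baseline log-toxicity at JND 0 (default 0).
#' @param toxicity_noise_sd SD of specimen-level log-toxicity noise
#'   (default 0.3).
#' @param camera_gamma Sensor gamma (default 2.2).
#' @param camera_noise_sd Read noise in counts (default 0.5).
#' @param hazard_coefficient Log-hazard decrease per JND in the field
#'   (default 0.065: reproduces pairwise log-hazard contrasts of ~1.6
#'   between the dullest and brightest colours, the magnitude reported in
#'   field experiments of this design, across the ~25 JND archetype
#'   range).
#' @param baseline_hazard Attack hazard per hour at JND 0 (default 0.003).
#' @param admin_censor_time Field exposure in hours (default 48).
#' @param check_interval Field check interval in hours (default 4).
#' @param censor_fraction Early non-predator loss fraction (default 0.05).
#' @param n_per_species Specimens per species (default 36, the study
#'   scale).
#' @param n_leaves Background samples per species (default 10).
#' @param background_mortality Daphnia background hazard per hour
#'   (default 0.02).
#' @param jitter_mid_sd,jitter_amp_sd Specimen-level spectral jitter: SD
#'   of the sigmoid midpoint (nm) and relative amplitude.
#' @return List of class `world_config`.
#' @export
world_config <- function(seed = 1, species_archetypes = default_archetypes(),
                         honesty_slope = 0.07, honesty_intercept = 0,
                         toxicity_noise_sd = 0.3, camera_gamma = 2.2,
                         camera_noise_sd = 0.5, hazard_coefficient = 0.065,
                         baseline_hazard = 0.003, admin_censor_time = 48,
                         check_interval = 4, censor_fraction = 0.05,
                         n_per_species = 36, n_leaves = 10,
                         background_mortality = 0.02,
                         jitter_mid_sd = 8, jitter_amp_sd = 0.08) {
  if (camera_gamma <= 0) stop("camera_gamma must be > 0")
  structure(as.list(environment()), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf(paste0("<world_config> seed=%d, %d species x %d specimens, ",
                     "honesty_slope=%.3g, hazard_coefficient=%.3g\n"),
              x$seed, length(x$species_archetypes), x$n_per_species,
              x$honesty_slope, x$hazard_coefficient))
  invisible(x)
}

#' Study-family calibration spectra
#'
#' Draws jittered surface spectra from the archetype families (elytra,
#' spots, backgrounds) for use in the cone-catch mapping training
#' library. Mirrors standard practice: the camera-to-cone mapping is
#' calibrated against spectrometer measurements of the kinds of surfaces
#' actually photographed, with the family jitter deliberately wider than
#' specimen-level variation so the library over-covers the study colours.
#'
#' @param n Number of spectra.
#' @param archetypes Archetype list (default [default_archetypes()]).
#' @param mid_sd,amp_sd Family jitter (nm; relative amplitude).
#' @param step Wavelength step (nm).
#' @return List of [reflectance_spectrum()] objects.
#' @export
surface_family_library <- function(n, archetypes = default_archetypes(),
                                   mid_sd = 12, amp_sd = 0.12, step = 5) {
  wl <- wl_grid(step)
  lapply(seq_len(n), function(i) {
    a <- archetypes[[sample(length(archetypes), 1)]]
    part <- sample(3, 1)
    if (part == 1) {
      .patch_spectrum(a$elytra, wl, rnorm(1, 0, mid_sd), rnorm(1, 0, amp_sd))
    } else if (part == 2) {
      .patch_spectrum(a$spot, wl, rnorm(1, 0, mid_sd), rnorm(1, 0, amp_sd))
    } else {
      .background_spectrum(a$background, wl, rnorm(1))
    }
  })
}

#' Simulate the specimen-level world (spectra and ground truth)
#'
#' Draws per-specimen elytra/spot spectra (jittered archetypes),
#' per-species background leaf spectra, true cone catches, true chromatic
#' JND against the species' mean background, and the true log-toxicity
#' assigned by the honesty rule. Consumes the current RNG stream (callers
#' seed via `set.seed` or [run_honesty_pipeline()]).
#'
#' @param config A [world_config()].
#' @return List of class `synthetic_world`: `specimens` (data frame of
#'   ground truth), `spectra` (per-specimen list), `leaves` (per-species
#'   list of spectra), `leaf_catches`, `config`.
#' @export
simulate_world <- function(config) {
  wl <- wl_grid()
  viewer <- blue_tit_sensitivities(wl)
  noise <- receptor_noise()
  arch <- config$species_archetypes
  leaves <- list(); leaf_catches <- list()
  for (sp in names(arch)) {
    bg <- arch[[sp]]$background
    leaves[[sp]] <- lapply(seq_len(config$n_leaves), function(i)
      .background_spectrum(bg, wl, jitter = rnorm(1)))
    leaf_catches[[sp]] <- lapply(leaves[[sp]], compute_cone_catch,
                                 sensitivities = viewer)
  }
  n_total <- length(arch) * config$n_per_species
  specs <- vector("list", n_total)
  ids <- species_col <- character(n_total)
  size_v <- weight_v <- jnd_v <- ltox_v <- sat_v <- lum_v <- numeric(n_total)
  k <- 0
  for (sp in names(arch)) {
    a <- arch[[sp]]
    mean_leaf <- colMeans(do.call(rbind, lapply(leaf_catches[[sp]], unclass)))
    class(mean_leaf) <- "cone_catch"
    for (i in seq_len(config$n_per_species)) {
      k <- k + 1
      el <- .patch_spectrum(a$elytra, wl, rnorm(1, 0, config$jitter_mid_sd),
                            rnorm(1, 0, config$jitter_amp_sd))
      spt <- .patch_spectrum(a$spot, wl, rnorm(1, 0, config$jitter_mid_sd),
                             rnorm(1, 0, config$jitter_amp_sd))
      q_el <- compute_cone_catch(el, viewer)
      jnd_true <- chromatic_jnd(q_el, mean_leaf, noise)
      off <- if (!is.null(a$tox_offset)) a$tox_offset else 0
      log_tox <- config$honesty_intercept + off +
        config$honesty_slope * jnd_true +
        rnorm(1, 0, config$toxicity_noise_sd)
      size_mm <- a$size_mm + rnorm(1, 0, 0.25)
      id <- sprintf("%s_%02d", sp, i)
      specs[[k]] <- list(elytra = el, spot = spt)
      ids[k] <- id; species_col[k] <- sp
      size_v[k] <- size_mm
      weight_v[k] <- 0.012 * (size_mm / 4.5)^3 * exp(rnorm(1, 0, 0.1))
      jnd_v[k] <- jnd_true
      ltox_v[k] <- max(log_tox, 0)
      sat_v[k] <- saturation(to_tetrahedral(q_el))
      lum_v[k] <- luminance(q_el)
    }
  }
  names(specs) <- ids
  specimens <- data.frame(
    specimen_id = ids, species = species_col, size_mm = size_v,
    weight_g = weight_v, true_jnd = jnd_v, true_log_toxicity = ltox_v,
    true_saturation = sat_v, true_luminance = lum_v)
  structure(list(specimens = specimens, spectra = specs, leaves = leaves,
                 leaf_catches = leaf_catches, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d specimens, %d species\n",
              nrow(x$specimens), length(x$leaves)))
  invisible(x)
}
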