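# End-to-end measurement pipeline on a synthetic world:
# photograph -> calibrate -> map to cone catches -> colour metrics ->
# JNDs -> bioassays -> specimen table.

#' Photograph and measure a synthetic world
#'
#' Renders one raw frame per specimen (elytra + spot patches with
#' embedded grey standards) and per background leaf, calibrates each
#' frame (linearisation from its own standards, normalisation to the 40%
#' standard), fits the polynomial cone-catch mapping on a fresh spectral
#' library, and assembles the measured specimen table.
#'
#' @param world A [simulate_world()] result.
#' @param n_library Spectra in the mapping training library (default 800);
#'   half generic ([generate_calibration_library()]), half study-family
#'   surfaces ([surface_family_library()]), mirroring calibration against
#'   spectrometry of the surfaces actually photographed.
#' @param degree Mapping polynomial degree (default 3: the cubic family is
#'   needed for accurate catches of highly saturated surfaces, where the
#'   quadratic systematically distorts the MW/LW corner).
#' @param patch,std_patch Frame patch sizes in pixels (small defaults
#'   keep full pipeline simulations fast).
#' @return List of class `world_measurement`: `table` (the specimen table
#'   columns `specimen_id, species, size_mm, weight_g, luminance,
#'   saturation, area_cm2, background_chromatic_jnd,
#'   background_achromatic_jnd, internal_dl`), `mapping` (with per-
#'   receptor R-squared), `background_catches` (per species, predicted).
#' @export
measure_world <- function(world, n_library = 800, degree = 3,
                          patch = 10, std_patch = 8) {
  config <- world$config
  camera <- camera_sensitivities()
  noise <- receptor_noise()
  # mapping model trained on an independent mixed library: generic smooth
  # and parametric spectra plus study-family surfaces
  lib <- c(generate_calibration_library(ceiling(n_library / 2)),
           surface_family_library(floor(n_library / 2),
                                  archetypes = config$species_archetypes))
  ts <- mapping_training_set(lib, camera = camera)
  mapping <- fit_polynomial_mapping(ts$camera_values, ts$cone_catches,
                                    degree = degree)
  lay_spec <- image_layout(c("elytra", "spot"), patch = patch,
                           std_patch = std_patch)
  lay_leaf <- image_layout("leaf", patch = patch, std_patch = std_patch)

  # photograph -> linearise (region pixels only) -> normalise -> map;
  # numerically identical to calibrate_image() + apply_mapping() but
  # skips transforming pixels outside the measured regions
  shoot <- function(spectra, layout) {
    img <- simulate_camera_image(spectra, camera_gamma = config$camera_gamma,
                                 noise_sd = config$camera_noise_sd,
                                 layout = layout, sensitivities = camera)
    npx <- layout$height * layout$width
    nch <- length(img$channels)
    # grey-standard means per channel, straight off the mask indices
    std_names <- names(layout$standard_regions)
    meas <- matrix(0, length(std_names), nch,
                   dimnames = list(NULL, img$channels))
    for (si in seq_along(std_names)) {
      idx <- layout$mask_idx[[std_names[si]]]
      for (ch in seq_len(nch)) {
        meas[si, ch] <- mean(img$raw[idx + (ch - 1L) * npx])
      }
    }
    model <- fit_linearisation(grey_standard_set(layout$grey_standards, meas))
    std_idx <- layout$mask_idx[["std_0.4"]]
    nms <- names(spectra)
    camvals <- matrix(0, length(nms), nch,
                      dimnames = list(nms, img$channels))
    for (ri in seq_along(nms)) {
      idx <- layout$mask_idx[[nms[ri]]]
      for (ch in seq_len(nch)) {
        off <- (ch - 1L) * npx
        lin <- mean(.linearise_counts(img$raw[idx + off],
                                      model$a[ch], model$b[ch]))
        std <- mean(.linearise_counts(img$raw[std_idx + off],
                                      model$a[ch], model$b[ch]))
        camvals[ri, ch] <- lin / std * 0.40
      }
    }
    pred <- suppressWarnings(apply_mapping(mapping, camvals))
    vals <- lapply(seq_along(nms), function(ri) {
      q <- pred[ri, ]
      class(q) <- "cone_catch"
      q
    })
    names(vals) <- nms
    vals
  }

  bg_catches <- list()
  for (sp in names(world$leaves)) {
    per_leaf <- lapply(world$leaves[[sp]], function(leaf)
      shoot(list(leaf = leaf), lay_leaf)$leaf)
    mb <- colMeans(do.call(rbind, lapply(per_leaf, unclass)))
    class(mb) <- "cone_catch"
    bg_catches[[sp]] <- list(mean = mb, per_leaf = per_leaf)
  }

  nsp <- nrow(world$specimens)
  lum_v <- sat_v <- area_v <- cj_v <- aj_v <- dl_v <- numeric(nsp)
  for (i in seq_len(nsp)) {
    info <- world$specimens[i, ]
    q <- shoot(world$spectra[[info$specimen_id]], lay_spec)
    bc <- background_contrast(q$elytra,
                              bg_catches[[info$species]]$per_leaf, noise)
    # beetle fills the elytra patch; pixels-per-cm follows body size
    px_per_cm <- patch / (0.08 * info$size_mm)
    lum_v[i] <- luminance(q$elytra)
    sat_v[i] <- saturation(to_tetrahedral(q$elytra))
    area_v[i] <- pattern_area(lay_spec$regions$elytra, px_per_cm)
    cj_v[i] <- bc$chromatic_jnd
    aj_v[i] <- bc$achromatic_jnd
    dl_v[i] <- internal_contrast(q$elytra, q$spot, noise)
  }
  table <- data.frame(
    specimen_id = world$specimens$specimen_id,
    species = world$specimens$species,
    size_mm = world$specimens$size_mm,
    weight_g = world$specimens$weight_g,
    luminance = lum_v, saturation = sat_v, area_cm2 = area_v,
    background_chromatic_jnd = cj_v, background_achromatic_jnd = aj_v,
    internal_dl = dl_v)
  structure(list(table = table, mapping = mapping,
                 background_catches = bg_catches),
            class = "world_measurement")
}

#' Run the full signal-honesty pipeline on a synthetic world
#'
#' One self-contained replicate of the whole study: simulate the world,
#' photograph and measure it, run the Daphnia bioassays implied by the
#' honesty rule, summarise toxicity, join everything into the specimen
#' table and fit the honesty model.
#'
#' @param config A [world_config()] (its `seed` seeds the run).
#' @param ... Passed to [measure_world()].
#' @return List of class `honesty_run`: `table` (specimen table including
#'   `log_toxicity`), `fit` (the [fit_honesty_model()] report), `world`,
#'   `measurement`, `config_digest` (seed and key parameters for replay).
#' @export
run_honesty_pipeline <- function(config = world_config(), ...) {
  set.seed(as.integer(config$seed))
  world <- simulate_world(config)
  meas <- measure_world(world, ...)
  tox_rows <- lapply(seq_len(nrow(world$specimens)), function(i) {
    info <- world$specimens[i, ]
    rec <- simulate_bioassay(
      true_toxicity = exp(info$true_log_toxicity) - 1,
      background_rate = config$background_mortality,
      specimen_id = info$specimen_id)
    # LC50 skipped here: the honesty stage consumes log_toxicity only
    summarise_toxicity(rec, lc50 = FALSE)
  })
  tox <- do.call(rbind, tox_rows)
  table <- merge(meas$table, tox[, c("specimen_id", "mean_dead_3h",
                                     "log_toxicity")],
                 by = "specimen_id", sort = FALSE)
  fit <- fit_honesty_model(table)
  structure(list(table = table, fit = fit, world = world,
                 measurement = meas,
                 config_digest = list(
                   seed = config$seed,
                   honesty_slope = config$honesty_slope,
                   camera_gamma = config$camera_gamma,
                   n_per_species = config$n_per_species)),
            class = "honesty_run")
}

#' @export
print.honesty_run <- function(x, ...) {
  cat(sprintf("<honesty_run> seed=%d, n=%d specimens\n",
              x$config_digest$seed, nrow(x$table)))
  ce <- x$fit$contrast_effect
  cat(sprintf("contrast effect: %.4f (se %.4f, p %.3g)\n",
              ce$estimate, ce$se, ce$p_value))
  invisible(x)
}
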