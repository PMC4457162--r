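# Synthetic multispectral camera.
#
# The simulated camera mirrors the study setup: a UV-converted SLR whose
# four channels (uv, sw, mw, lw) have known passbands; a VIS exposure
# carries sw/mw/lw and a UV exposure carries uv. The sensor response is a
# power law: raw = 255 * linear^(1/gamma), where `linear` is the channel
# quantum catch of the surface relative to a perfect reflector. Images are
# 8-bit (rounded, clipped). Every frame embeds a row of Spectralon-like
# grey standards including the 40% standard used for normalisation.

#' Lay out a synthetic photo frame
#'
#' Builds the pixel geometry for one frame: a top row of grey-standard
#' patches and a grid of content-region patches below. Masks are
#' rasterised once so repeated simulations with the same layout are cheap.
#'
#' @param region_names Character vector of content region names.
#' @param grey_standards Nominal reflectances of the embedded standards.
#' @param patch Side of a content patch in pixels.
#' @param std_patch Side of a standard patch in pixels.
#' @return A list of class `frame_layout`: dimensions, polygons and
#'   logical masks for every region and standard.
#' @export
image_layout <- function(region_names,
                         grey_standards = c(0.02, 0.05, 0.1, 0.2, 0.4,
                                            0.6, 0.8, 0.99),
                         patch = 10, std_patch = 8) {
  if (length(region_names) < 1) stop("empty region map")
  if (!any(abs(grey_standards - 0.40) < 1e-9)) {
    stop("grey standards must include the 40% normalisation standard")
  }
  ns <- length(grey_standards)
  per_row <- max(ns, 4L)
  width <- per_row * (patch + 2L) + 2L
  nrows <- ceiling(length(region_names) / per_row)
  height <- std_patch + 4L + nrows * (patch + 2L) + 2L

  std_regions <- list()
  for (i in seq_len(ns)) {
    x0 <- 2L + (i - 1L) * (std_patch + 2L)
    std_regions[[sprintf("std_%g", grey_standards[i])]] <-
      rect_polygon(x0, 2L, std_patch, std_patch)
  }
  regions <- list()
  for (i in seq_along(region_names)) {
    r <- (i - 1L) %/% per_row
    c0 <- (i - 1L) %% per_row
    x0 <- 2L + c0 * (patch + 2L)
    y0 <- std_patch + 6L + r * (patch + 2L)
    regions[[region_names[i]]] <- rect_polygon(x0, y0, patch, patch)
  }
  all_polys <- c(regions, std_regions)
  masks <- lapply(all_polys, polygon_mask, width = width, height = height)
  structure(list(width = width, height = height,
                 regions = regions, standard_regions = std_regions,
                 grey_standards = grey_standards,
                 masks = masks,
                 mask_idx = lapply(masks, which)),
            class = "frame_layout")
}

#' Simulate a raw camera image pair
#'
#' Renders an 8-bit VIS+UV frame: each content region is filled with its
#' spectrum's camera-channel catch passed through the sensor power law,
#' grey standards are embedded in-frame, and optional Gaussian read noise
#' is added before quantisation. Unassigned pixels get a dark (4%
#' reflectance) EVA-like background.
#'
#' @param spectra_by_region Named list of [reflectance_spectrum()], one
#'   per content region.
#' @param camera_gamma Sensor gamma (> 0); raw = 255 * linear^(1/gamma).
#' @param grey_standards Nominal reflectances of embedded standards (must
#'   include 0.40).
#' @param noise_sd Read-noise standard deviation in digital counts.
#' @param seed Optional integer seed.
#' @param layout Optional precomputed [image_layout()] whose region names
#'   match; built on the fly otherwise.
#' @param sensitivities Camera channel sensitivities
#'   (default [camera_sensitivities()]).
#' @param illuminant Illuminant on the sensitivity grid (default D65).
#' @param illumination Overall light-level scale factor (default 1);
#'   normalisation against the 40% standard removes it.
#' @param quantise Round to 8-bit integer counts (default TRUE). Disable
#'   to study the response model in isolation from quantisation error.
#' @return An object of class `aposcan_image`: list with `raw` (array
#'   height x width x 4, channels uv/sw/mw/lw), the layout, gamma, and the
#'   true linear signals per region (ground truth for tests).
#' @export
simulate_camera_image <- function(spectra_by_region, camera_gamma = 2.2,
                                  grey_standards = c(0.02, 0.05, 0.1, 0.2,
                                                     0.4, 0.6, 0.8, 0.99),
                                  noise_sd = 0, seed = NULL, layout = NULL,
                                  sensitivities = NULL, illuminant = NULL,
                                  illumination = 1, quantise = TRUE) {
  if (length(spectra_by_region) < 1) stop("empty region map")
  if (camera_gamma <= 0) stop("camera_gamma must be > 0")
  if (!any(abs(grey_standards - 0.40) < 1e-9)) {
    stop("grey standards must include the 40% normalisation standard")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(sensitivities)) sensitivities <- camera_sensitivities()
  channels <- colnames(sensitivities)
  if (is.null(layout)) {
    layout <- image_layout(names(spectra_by_region), grey_standards)
  } else {
    if (!all(names(spectra_by_region) %in% names(layout$regions))) {
      stop("layout regions do not cover the supplied spectra")
    }
  }

  # linear signal per region x channel
  lin <- t(vapply(spectra_by_region, function(sp) {
    unname(compute_cone_catch(sp, sensitivities, illuminant))
  }, numeric(length(channels))))
  colnames(lin) <- channels
  lin <- lin * illumination

  h <- layout$height; w <- layout$width
  npx <- h * w
  # dark background everywhere first
  bg_lin <- 0.04 * illumination
  raw <- array(rep(255 * bg_lin^(1 / camera_gamma), npx * length(channels)),
               dim = c(h, w, length(channels)),
               dimnames = list(NULL, NULL, channels))
  fill <- function(idx, linear) {
    for (ch in seq_along(channels)) {
      raw[idx + (ch - 1L) * npx] <<- 255 * max(linear[ch], 0)^(1 / camera_gamma)
    }
  }
  for (nm in names(spectra_by_region)) {
    fill(layout$mask_idx[[nm]], lin[nm, ])
  }
  for (i in seq_along(layout$standard_regions)) {
    nm <- names(layout$standard_regions)[i]
    fill(layout$mask_idx[[nm]], rep(layout$grey_standards[i] * illumination,
                                    length(channels)))
  }
  if (noise_sd > 0) {
    raw <- raw + array(rnorm(length(raw), 0, noise_sd), dim = dim(raw))
  }
  raw <- pmin(pmax(raw, 0), 255)
  if (quantise) raw <- round(raw)
  structure(list(raw = raw, layout = layout, gamma = camera_gamma,
                 channels = channels, true_linear = lin / illumination,
                 illumination = illumination, bit_depth = 8L),
            class = "aposcan_image")
}

#' @export
print.aposcan_image <- function(x, ...) {
  cat(sprintf("<aposcan_image> %dx%d, %d channels, %d regions, gamma %.2f\n",
              x$layout$height, x$layout$width, length(x$channels),
              length(x$layout$regions), x$gamma))
  invisible(x)
}

#' Export an image pair as portable greymaps plus a region-mask JSON
#'
#' Writes one plain-text PGM (P2) per channel grouped into the VIS
#' (`*_vis_<ch>.pgm`) and UV (`*_uv.pgm`) exposures, and a JSON file of
#' region polygons in 0-based pixel coordinates (row-major).
#'
#' @param image An `aposcan_image`.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_image_pnm <- function(image, prefix) {
  files <- character(0)
  write_pgm <- function(mat, path) {
    con <- file(path, "w")
    on.exit(close(con))
    cat("P2\n", ncol(mat), " ", nrow(mat), "\n255\n", sep = "", file = con)
    write(t(mat), file = con, ncolumns = ncol(mat))
  }
  for (ch in image$channels) {
    suffix <- if (ch == "uv") "_uv.pgm" else paste0("_vis_", ch, ".pgm")
    path <- paste0(prefix, suffix)
    write_pgm(image$raw[, , ch], path)
    files <- c(files, path)
  }
  polys0 <- lapply(c(image$layout$regions, image$layout$standard_regions),
                   function(p) unname(p - 1))   # 0-based for interchange
  json <- paste0(prefix, "_regions.json")
  jsonlite::write_json(polys0, json, digits = NA)
  invisible(c(files, json))
}
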