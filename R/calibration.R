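# Image calibration: linearisation against grey standards and
# normalisation to the 40% standard, reimplementing the ImageJ-plugin
# stage of the workflow.

#' Grey-standard measurements
#'
#' Pairs the nominal reflectances of the Spectralon standards (2--99%)
#' with their measured mean raw counts per channel.
#'
#' @param nominal Numeric vector of nominal reflectances, strictly
#'   increasing, in (0, 1]; must include 0.40.
#' @param measured Matrix of mean raw digital counts,
#'   `length(nominal) x n_channels`, with channel column names.
#' @return Object of class `grey_standard_set`.
#' @export
grey_standard_set <- function(nominal, measured) {
  measured <- as.matrix(measured)
  if (length(nominal) != nrow(measured)) {
    stop("one row of measured values per nominal standard required")
  }
  if (any(diff(nominal) <= 0)) stop("nominal reflectances must be strictly increasing")
  if (any(nominal <= 0) || any(nominal > 1)) stop("nominal reflectances must lie in (0, 1]")
  if (!any(abs(nominal - 0.40) < 1e-9)) {
    stop("the 40% standard must be present")
  }
  structure(list(nominal = nominal, measured = measured,
                 channels = colnames(measured)),
            class = "grey_standard_set")
}

#' Measure the embedded grey standards of a raw frame
#'
#' @param image An `aposcan_image` (raw frame).
#' @return A [grey_standard_set()].
#' @export
measure_grey_standards <- function(image) {
  lay <- image$layout
  meas <- t(vapply(names(lay$standard_regions), function(nm) {
    measure_region(image, lay$masks[[nm]])$mean
  }, numeric(length(image$channels))))
  colnames(meas) <- image$channels
  grey_standard_set(lay$grey_standards, meas)
}

#' Fit the camera linearisation model
#'
#' Fits, per channel, the inverse sensor response as a power law
#' `raw = a * linear^b` by ordinary least squares on logs of the
#' grey-standard measurements (for a grey standard the linear signal
#' equals its nominal reflectance). The fitted transfer is strictly
#' monotone on (0, 255] by construction.
#'
#' @param standards A [grey_standard_set()] with at least 3 standards.
#' @return Object of class `linearisation_model`: per-channel `a`, `b`,
#'   log-scale residuals and RMS residual.
#' @export
fit_linearisation <- function(standards) {
  stopifnot(inherits(standards, "grey_standard_set"))
  if (length(standards$nominal) < 3) stop("need at least 3 grey standards")
  x <- log(standards$nominal)
  fits <- lapply(seq_len(ncol(standards$measured)), function(ch) {
    yraw <- standards$measured[, ch]
    if (any(diff(yraw) <= 0)) {
      stop("measured standard values are not strictly increasing in channel '",
           colnames(standards$measured)[ch],
           "': cannot fit a monotone response")
    }
    y <- log(pmax(yraw, 1e-6))
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    loga <- mean(y) - b * mean(x)
    res <- y - (loga + b * x)
    list(a = exp(loga), b = b, residuals = res,
         rms = sqrt(mean(res^2)))
  })
  names(fits) <- colnames(standards$measured)
  structure(list(channels = colnames(standards$measured),
                 a = vapply(fits, `[[`, 0, "a"),
                 b = vapply(fits, `[[`, 0, "b"),
                 residuals = lapply(fits, `[[`, "residuals"),
                 rms = vapply(fits, `[[`, 0, "rms")),
            class = "linearisation_model")
}

#' @export
print.linearisation_model <- function(x, ...) {
  cat("<linearisation_model> raw = a * linear^b\n")
  print(round(rbind(a = x$a, b = x$b, rms = x$rms), 4))
  invisible(x)
}

# raw counts -> linear signal for one channel
.linearise_counts <- function(raw, a, b) (pmax(raw, 0) / a)^(1 / b)

#' Linearise a raw frame and normalise to the 40% standard
#'
#' Applies the inverse response per channel, then scales each channel by
#' the linearised value of the 40% standard region so that the output is
#' reflectance (1.0 = 100%); this removes overall illumination
#' differences between frames.
#'
#' @param image Raw `aposcan_image`.
#' @param model A [fit_linearisation()] model (fitted from this frame's
#'   standards when `NULL`).
#' @param standard_reflectance Nominal reflectance of the normalisation
#'   standard (default 0.40).
#' @return Object of class `reflectance_image`: `refl` array (height x
#'   width x channels, reflectance fractions) plus the layout and the
#'   fraction of clipped (255) raw pixels per channel.
#' @export
linearise_and_normalise <- function(image, model = NULL,
                                    standard_reflectance = 0.40) {
  stopifnot(inherits(image, "aposcan_image"))
  if (is.null(model)) model <- fit_linearisation(measure_grey_standards(image))
  std_name <- sprintf("std_%g", standard_reflectance)
  if (!std_name %in% names(image$layout$standard_regions)) {
    stop("normalisation standard ", standard_reflectance, " not in frame")
  }
  std_mask <- image$layout$masks[[std_name]]
  out <- image$raw * 0
  clipped <- numeric(length(image$channels))
  for (ch in seq_along(image$channels)) {
    plane <- image$raw[, , ch]
    std_raw <- plane[std_mask]
    if (mean(std_raw >= 255) > 0.05) {
      stop("normalisation standard saturated in channel '",
           image$channels[ch], "'")
    }
    lin <- .linearise_counts(plane, model$a[ch], model$b[ch])
    std_lin <- mean(.linearise_counts(std_raw, model$a[ch], model$b[ch]))
    if (std_lin <= 0) stop("degenerate standard measurement")
    out[, , ch] <- lin / std_lin * standard_reflectance
    clipped[ch] <- mean(plane >= 255)
  }
  names(clipped) <- image$channels
  structure(list(refl = pmax(out, 0), layout = image$layout,
                 channels = image$channels, clipped_fraction = clipped),
            class = "reflectance_image")
}

#' @export
print.reflectance_image <- function(x, ...) {
  cat(sprintf("<reflectance_image> %dx%d, %d channels\n",
              dim(x$refl)[1], dim(x$refl)[2], length(x$channels)))
  invisible(x)
}

#' Measure a region of an image
#'
#' Per-channel arithmetic mean over the pixels of a region, with the
#' pixel count for quality control. Optionally trims the brightest pixels
#' within the mask (a stand-in for manual exclusion of specular
#' highlights on curved elytra).
#'
#' @param image An `aposcan_image` (raw) or `reflectance_image`.
#' @param mask Logical pixel mask, a polygon vertex matrix, or the name of
#'   a layout region.
#' @param trim_top Fraction (0--0.5) of the brightest pixels (by channel
#'   mean) to exclude; default 0 (off).
#' @return List with `mean` (named per-channel vector) and `n_pixels`.
#' @export
measure_region <- function(image, mask, trim_top = 0) {
  arr <- if (inherits(image, "reflectance_image")) image$refl else image$raw
  lay <- image$layout
  if (is.character(mask)) {
    if (!mask %in% names(lay$masks)) stop("unknown region '", mask, "'")
    mask <- lay$masks[[mask]]
  } else if (is.matrix(mask) && !is.logical(mask)) {
    mask <- polygon_mask(mask, dim(arr)[2], dim(arr)[1])
  }
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  npx <- dim(arr)[1] * dim(arr)[2]
  vals <- vapply(seq_len(dim(arr)[3]),
                 function(ch) arr[idx + (ch - 1L) * npx],
                 numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx))
  if (trim_top > 0) {
    stopifnot(trim_top < 0.5)
    bright <- rowMeans(vals)
    keep <- bright <= quantile(bright, 1 - trim_top)
    vals <- vals[keep, , drop = FALSE]
  }
  m <- colMeans(vals)
  names(m) <- image$channels
  list(mean = m, n_pixels = nrow(vals))
}

#' One-call calibration of a raw frame
#'
#' Measures the embedded standards, fits the linearisation and returns
#' the normalised reflectance image together with per-region means.
#'
#' @param image Raw `aposcan_image`.
#' @param trim_top Passed to [measure_region()].
#' @return List: `reflectance` image, `model`, and `regions` data frame
#'   (`region, channel, mean_reflectance, n_pixels`).
#' @export
calibrate_image <- function(image, trim_top = 0) {
  model <- fit_linearisation(measure_grey_standards(image))
  refl <- linearise_and_normalise(image, model)
  rows <- list()
  for (nm in names(image$layout$regions)) {
    mr <- measure_region(refl, nm, trim_top = trim_top)
    rows[[nm]] <- data.frame(region = nm, channel = image$channels,
                             mean_reflectance = unname(mr$mean),
                             n_pixels = mr$n_pixels)
  }
  list(reflectance = refl, model = model,
       regions = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
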