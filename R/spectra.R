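#' Reflectance spectra
#'
#' A reflectance spectrum is a surface's reflectance (fraction of incident
#' light returned, in `[0, 1]`) on a uniform wavelength grid covering the
#' avian-visible range 300--700 nm.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, uniformly spaced (1 or 5 nm step typical).
#' @param reflectance Numeric vector of reflectance fractions in `[0, 1]`,
#'   same length as `wavelengths`.
#' @return An object of class `reflectance_spectrum`: a list with elements
#'   `wl` and `refl`.
#' @export
#' @examples
#' s <- reflectance_spectrum(seq(300, 700, 5), rep(0.4, 81))
reflectance_spectrum <- function(wavelengths, reflectance) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance must have equal length")
  }
  if (length(wavelengths) < 2L) stop("need at least two wavelengths")
  d <- diff(wavelengths)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (diff(range(d)) > 1e-8) stop("wavelength grid must be uniform")
  if (any(!is.finite(reflectance)) ||
      any(reflectance < -1e-12) || any(reflectance > 1 + 1e-12)) {
    stop("reflectance must lie within [0, 1]")
  }
  structure(list(wl = wavelengths, refl = pmin(pmax(reflectance, 0), 1)),
            class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %g-%g nm (step %g), mean %.3f\n",
              min(x$wl), max(x$wl), x$wl[2] - x$wl[1], mean(x$refl)))
  invisible(x)
}

#' Standard wavelength grid
#'
#' @param step Grid step in nm (default 5).
#' @param from,to Range endpoints in nm.
#' @return Numeric vector of wavelengths.
#' @export
wl_grid <- function(step = 5, from = 300, to = 700) seq(from, to, by = step)

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; requested wavelengths must be covered by the
#' spectrum's range (no extrapolation).
#'
#' @param spectrum A [reflectance_spectrum()].
#' @param wavelengths Target grid (nm).
#' @return A `reflectance_spectrum` on the new grid.
#' @export
resample_spectrum <- function(spectrum, wavelengths) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  if (min(wavelengths) < min(spectrum$wl) - 1e-9 ||
      max(wavelengths) > max(spectrum$wl) + 1e-9) {
    stop("requested wavelengths outside the spectrum's range")
  }
  r <- approx(spectrum$wl, spectrum$refl, xout = wavelengths)$y
  reflectance_spectrum(wavelengths, r)
}

#' Generate a library of smooth random reflectance spectra
#'
#' Draws band-limited random curves: white noise on the wavelength grid is
#' smoothed with a normal kernel of the given bandwidth and squashed into
#' `[0, 1]` through a logistic, around a random per-spectrum base level.
#' As `smoothness` grows the curves approach flat lines. These stand in
#' for natural matte surfaces (elytra, leaves, bark), whose reflectance
#' varies on scales of tens of nanometres.
#'
#' @param n Number of spectra (>= 1).
#' @param smoothness Kernel bandwidth in nm (default 60).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param step Wavelength step in nm.
#' @param amplitude Logit-scale gain applied to the smoothed noise
#'   (controls chromatic variation; default 4).
#' @return A list of `n` [reflectance_spectrum()] objects.
#' @export
#' @examples
#' lib <- generate_reflectance_library(5, seed = 1)
generate_reflectance_library <- function(n, smoothness = 60, seed = NULL,
                                         step = 5, amplitude = 4) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("n must be a positive count")
  }
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  wl <- wl_grid(step)
  m <- length(wl)
  # normal kernel weights on the grid; bandwidth = kernel sd in nm
  half <- min(m - 1L, max(1L, ceiling(3 * smoothness / step)))
  kw <- dnorm(seq(-half, half) * step, sd = smoothness)
  kw <- kw / sum(kw)
  lapply(seq_len(n), function(i) {
    z <- rnorm(m + 2L * half)
    zs <- vapply(seq_len(m), function(j) sum(kw * z[j:(j + 2L * half)]), 0)
    base <- rnorm(1, 0, 0.8)
    reflectance_spectrum(wl, plogis(base + amplitude * zs))
  })
}

#' Generate a calibration library of mixed spectral families
#'
#' Training library for the cone-catch mapping: half band-limited smooth
#' random curves ([generate_reflectance_library()]), half parametric
#' shapes spanning the surfaces actually measured -- long-pass sigmoids
#' (carotenoid reds through yellows), Gaussian bumps (foliage greens) and
#' flats (greys, melanised blacks). Real calibration libraries include
#' saturated natural colours; a purely smooth-random library
#' under-represents them and degrades mapping accuracy exactly where the
#' signals live.
#'
#' @inheritParams generate_reflectance_library
#' @return List of `n` [reflectance_spectrum()] objects.
#' @export
generate_calibration_library <- function(n, smoothness = 60, seed = NULL,
                                         step = 5) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be a positive count")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n)
  n_smooth <- n %/% 2L
  out <- generate_reflectance_library(n_smooth, smoothness = smoothness,
                                      step = step)
  wl <- wl_grid(step)
  kinds <- sample(c("sigmoid", "gauss", "flat"), n - n_smooth,
                  replace = TRUE, prob = c(0.5, 0.3, 0.2))
  out <- c(out, lapply(kinds, function(k) {
    switch(k,
      sigmoid = sigmoid_reflectance(wl, midpoint = runif(1, 420, 660),
                                    slope = runif(1, 0.02, 0.12),
                                    low = runif(1, 0.02, 0.10),
                                    high = runif(1, 0.20, 0.95)),
      gauss = gaussian_reflectance(wl, peak = runif(1, 380, 650),
                                   width = runif(1, 25, 60),
                                   height = runif(1, 0.05, 0.5),
                                   base = runif(1, 0.02, 0.2)),
      flat = flat_reflectance(wl, runif(1, 0.02, 0.95)))
  }))
  out[sample.int(length(out))]
}

#' Parametric surface spectra
#'
#' Closed-form reflectance archetypes used by the synthetic world:
#' long-pass sigmoids for carotenoid-like reds/oranges/yellows, flat dark
#' curves for melanised surfaces, and a green leaf curve with a 550 nm
#' bump.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param midpoint Sigmoid midpoint (nm) for long-pass shapes.
#' @param slope Sigmoid steepness (1/nm).
#' @param low,high Reflectance floor and ceiling.
#' @return A [reflectance_spectrum()].
#' @export
sigmoid_reflectance <- function(wavelengths, midpoint, slope = 0.08,
                                low = 0.05, high = 0.65) {
  r <- low + (high - low) * plogis(slope * (wavelengths - midpoint))
  reflectance_spectrum(wavelengths, pmin(pmax(r, 0), 1))
}

#' @rdname sigmoid_reflectance
#' @param peak Gaussian peak position (nm).
#' @param width Gaussian width (sd, nm).
#' @param height Peak height above the base.
#' @param base Baseline reflectance.
#' @export
gaussian_reflectance <- function(wavelengths, peak, width, height, base) {
  r <- base + height * exp(-0.5 * ((wavelengths - peak) / width)^2)
  reflectance_spectrum(wavelengths, pmin(pmax(r, 0), 1))
}

#' @rdname sigmoid_reflectance
#' @param level Constant reflectance level.
#' @export
flat_reflectance <- function(wavelengths, level) {
  reflectance_spectrum(wavelengths, rep(level, length(wavelengths)))
}

#' Write / read spectra as CSV
#'
#' Format: first column `wavelength_nm`, one column per sample.
#'
#' @param spectra Named list of [reflectance_spectrum()] on a common grid.
#' @param path File path.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  wl <- spectra[[1]]$wl
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wl, wl))) stop("spectra must share one grid")
  }
  df <- data.frame(wavelength_nm = wl)
  nm <- names(spectra)
  if (is.null(nm)) nm <- paste0("s", seq_along(spectra))
  for (i in seq_along(spectra)) df[[nm[i]]] <- spectra[[i]]$refl
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stop("first column must be 'wavelength_nm'")
  }
  wl <- df[[1]]
  out <- lapply(df[-1], function(col) reflectance_spectrum(wl, col))
  out
}
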