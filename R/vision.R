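# Photoreceptor sensitivities, illuminants and quantum catches.

# CIE standard illuminant D65, relative spectral power 300-700 nm at 10 nm.
.d65_wl <- seq(300, 700, by = 10)
.d65_power <- c(
  0.03, 3.29, 20.24, 37.05, 39.95, 44.91, 46.64, 52.09, 50.00, 54.65,
  82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86, 115.92,
  108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05, 100.00, 96.33,
  95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70, 80.03, 80.21, 82.28,
  78.28, 69.72, 71.61
)

#' Standard daylight (D65) irradiance spectrum
#'
#' Relative spectral power of CIE illuminant D65, linearly interpolated
#' from the 10 nm tabulation onto the requested grid.
#'
#' @param wavelengths Wavelength grid in nm, within 300--700.
#' @return Numeric vector of relative power.
#' @export
d65_spectrum <- function(wavelengths = wl_grid()) {
  if (min(wavelengths) < 300 || max(wavelengths) > 700) {
    stop("D65 table covers 300-700 nm")
  }
  approx(.d65_wl, .d65_power, xout = wavelengths)$y
}

#' Visual pigment absorbance template
#'
#' Govardovskii et al. (2000) A1 template: alpha band plus beta band,
#' parameterised only by the wavelength of peak absorbance.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param lambda_max Peak absorbance wavelength (nm).
#' @return Absorbance, peak-normalised to 1.
#' @export
pigment_template <- function(wavelengths, lambda_max) {
  x <- lambda_max / wavelengths
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lm_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((wavelengths - lm_beta) / b_beta)^2)
  s <- alpha + beta
  s <- pmax(s, 0)
  s / max(s)
}

#' Cone oil-droplet transmission
#'
#' Simple logistic long-pass filter standing in for carotenoid oil
#' droplets; `cut` is the wavelength of 50% transmission.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param cut Cut wavelength (nm); `NA` means no droplet (T-type).
#' @param steepness Logistic steepness (1/nm).
#' @return Transmission in `[0, 1]`.
#' @export
oil_droplet_filter <- function(wavelengths, cut, steepness = 0.11) {
  if (is.na(cut)) return(rep(1, length(wavelengths)))
  plogis(steepness * (wavelengths - cut))
}

#' Blue tit photoreceptor sensitivities
#'
#' Spectral sensitivities of the blue tit's four single cones (UVS, SWS,
#' MWS, LWS) and the double cone, built from the pigment template with
#' published peak wavelengths (371, 448, 503, 563 nm; double cone uses the
#' LWS pigment) and logistic oil-droplet filters. These are
#' template-generated curves, not digitised measurements; any column can
#' be replaced via [read_sensitivities_csv()].
#'
#' @param wavelengths Wavelength grid (nm).
#' @param droplets Apply oil-droplet filtering (default TRUE).
#' @return Matrix `length(wavelengths) x 5`, columns
#'   `uv, sw, mw, lw, dbl`, each peak-normalised.
#' @export
blue_tit_sensitivities <- function(wavelengths = wl_grid(), droplets = TRUE) {
  peaks <- c(uv = 371, sw = 448, mw = 503, lw = 563, dbl = 563)
  cuts <- c(uv = NA, sw = 455, mw = 505, lw = 560, dbl = 415)
  s <- sapply(names(peaks), function(ch) {
    v <- pigment_template(wavelengths, peaks[[ch]])
    if (droplets) v <- v * oil_droplet_filter(wavelengths, cuts[[ch]])
    v / max(v)
  })
  rownames(s) <- wavelengths
  s
}

#' Camera channel sensitivities
#'
#' The UV-converted camera's four channels as truncated Gaussians with the
#' stated passbands and peaks: UV 360--400 nm (peak 366), SW 400--550
#' (peak 465), MW 420--620 (peak 522), LW 560--700 (peak 667).
#'
#' @param wavelengths Wavelength grid (nm).
#' @param peaks Named numeric vector of channel peaks (nm).
#' @param bands Named list of `c(lo, hi)` passbands (nm).
#' @return Matrix `length(wavelengths) x 4`, columns `uv, sw, mw, lw`.
#' @export
camera_sensitivities <- function(wavelengths = wl_grid(),
                                 peaks = c(uv = 366, sw = 465,
                                           mw = 522, lw = 667),
                                 bands = list(uv = c(360, 400),
                                              sw = c(400, 550),
                                              mw = c(420, 620),
                                              lw = c(560, 700))) {
  s <- sapply(names(peaks), function(ch) {
    b <- bands[[ch]]
    width <- (b[2] - b[1]) / 4
    v <- exp(-0.5 * ((wavelengths - peaks[[ch]]) / width)^2)
    v[wavelengths < b[1] | wavelengths > b[2]] <- 0
    v / max(v)
  })
  rownames(s) <- wavelengths
  s
}

#' Cone-catch container
#'
#' Quantum catches of the four avian single cones plus the double cone,
#' normalised so a perfect (flat 100%) reflector has catch 1 in every
#' channel.
#'
#' @param uv,sw,mw,lw Single-cone catches (>= 0).
#' @param dbl Double-cone catch (>= 0), `NA` if not computed.
#' @return Named numeric vector of class `cone_catch`.
#' @export
cone_catch <- function(uv, sw, mw, lw, dbl = NA_real_) {
  q <- c(uv = uv, sw = sw, mw = mw, lw = lw, dbl = dbl)
  if (any(!is.finite(q[1:4])) || any(q[1:4] < 0)) {
    stop("single-cone catches must be finite and >= 0")
  }
  if (!is.na(q[["dbl"]]) && q[["dbl"]] < 0) stop("double-cone catch must be >= 0")
  structure(q, class = "cone_catch")
}

#' @export
print.cone_catch <- function(x, ...) {
  cat("<cone_catch>", paste(sprintf("%s=%.4g", names(x), unclass(x)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Compute quantum catches of a spectrum
#'
#' Trapezoidal integration of reflectance x illuminant x sensitivity,
#' normalised by the catch of a perfect reflector (von-Kries style), so a
#' flat spectrum at reflectance r yields catch r in every channel and the
#' result is linear in reflectance.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @param sensitivities Matrix of receptor sensitivities (rows = the
#'   wavelengths in `wavelengths`), e.g. [blue_tit_sensitivities()].
#' @param illuminant Illuminant spectral power on the same grid
#'   (default D65).
#' @param wavelengths Common wavelength grid; the spectrum is resampled
#'   onto it (error if its range does not cover the grid).
#' @return Named numeric vector of catches (class `cone_catch` when the
#'   sensitivity columns are the five avian receptors).
#' @export
compute_cone_catch <- function(spectrum, sensitivities,
                               illuminant = NULL,
                               wavelengths = as.numeric(rownames(sensitivities))) {
  if (is.null(wavelengths) || any(is.na(wavelengths))) {
    stop("sensitivities must carry wavelengths as rownames or pass `wavelengths`")
  }
  if (is.null(illuminant)) illuminant <- d65_spectrum(wavelengths)
  sp <- resample_spectrum(spectrum, wavelengths)
  # trapezoid weights on a (possibly non-uniform) grid
  d <- diff(wavelengths)
  w <- c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  q <- vapply(seq_len(ncol(sensitivities)), function(j) {
    s <- sensitivities[, j]
    num <- sum(w * sp$refl * illuminant * s)
    den <- sum(w * illuminant * s)
    if (den <= 0) stop("sensitivity column ", j, " has zero integral")
    num / den
  }, 0)
  names(q) <- colnames(sensitivities)
  if (identical(colnames(sensitivities), c("uv", "sw", "mw", "lw", "dbl"))) {
    class(q) <- "cone_catch"
  }
  q
}

#' Read / write sensitivity curves as CSV
#'
#' Format: `wavelength_nm` column plus one named column per receptor or
#' channel.
#'
#' @param path File path.
#' @export
read_sensitivities_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") stop("first column must be 'wavelength_nm'")
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_sensitivities_csv
#' @param sensitivities Matrix with wavelength rownames.
#' @export
write_sensitivities_csv <- function(sensitivities, path) {
  df <- data.frame(wavelength_nm = as.numeric(rownames(sensitivities)))
  df <- cbind(df, as.data.frame(sensitivities))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
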