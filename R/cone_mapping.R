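# Polynomial mapping from calibrated camera channel values to predicted
# avian cone quantum catches. Trained on a spectral library for which both
# the camera's and the viewer's catches can be computed exactly.

# All monomial exponent combinations of `k` variables up to total degree d.
.monomial_exponents <- function(k, degree, intercept = TRUE) {
  grid <- expand.grid(rep(list(0:degree), k))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  grid <- grid[order(rowSums(grid), apply(grid, 1, paste, collapse = "")), ,
               drop = FALSE]
  if (!intercept) grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  m <- as.matrix(grid)
  dimnames(m) <- NULL
  m
}

.design_matrix <- function(X, exponents) {
  n <- nrow(X)
  D <- matrix(1, n, nrow(exponents))
  for (t in seq_len(nrow(exponents))) {
    for (j in seq_len(ncol(exponents))) {
      e <- exponents[t, j]
      if (e > 0) D[, t] <- D[, t] * X[, j]^e
    }
  }
  colnames(D) <- apply(exponents, 1, function(e) {
    if (all(e == 0)) return("1")
    paste0(colnames(X)[e > 0], ifelse(e[e > 0] > 1, paste0("^", e[e > 0]), ""),
           collapse = "*")
  })
  D
}

#' Fit a polynomial cone-catch mapping
#'
#' Least-squares fit, per receptor, of the true quantum catches on all
#' monomials of the camera channel values up to the given degree
#' (including cross-channel interaction terms). The degree-2 default is
#' the smallest family that reaches the 0.96--0.98 R-squared band typical
#' of this calibration technique.
#'
#' @param camera_values Matrix `n x n_channels` of calibrated camera
#'   reflectances with channel column names (training inputs).
#' @param cone_catches Matrix `n x n_receptors` of true catches with
#'   receptor column names (training targets).
#' @param degree Polynomial degree (1, 2 or 3).
#' @param intercept Include the constant term (default TRUE).
#' @return Object of class `mapping_model`: exponent table, coefficient
#'   matrix, per-receptor R-squared, channel/receptor names.
#' @export
fit_polynomial_mapping <- function(camera_values, cone_catches, degree = 2,
                                   intercept = TRUE) {
  camera_values <- as.matrix(camera_values)
  cone_catches <- as.matrix(cone_catches)
  stopifnot(degree %in% 1:3, nrow(camera_values) == nrow(cone_catches))
  if (is.null(colnames(camera_values))) {
    colnames(camera_values) <- paste0("c", seq_len(ncol(camera_values)))
  }
  exponents <- .monomial_exponents(ncol(camera_values), degree, intercept)
  D <- .design_matrix(camera_values, exponents)
  if (nrow(D) < 10 * ncol(D)) {
    stop("need at least 10x more training spectra (", nrow(D),
         ") than polynomial terms (", ncol(D), ")")
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("rank-deficient polynomial design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrD, cone_catches)
  fitted <- D %*% coefs
  r2 <- vapply(seq_len(ncol(cone_catches)), function(j) {
    y <- cone_catches[, j]
    1 - sum((y - fitted[, j])^2) / sum((y - mean(y))^2)
  }, 0)
  names(r2) <- colnames(cone_catches)
  structure(list(exponents = exponents, coefficients = coefs,
                 r_squared = r2, channels = colnames(camera_values),
                 receptors = colnames(cone_catches), degree = degree,
                 intercept = intercept, n_training = nrow(D)),
            class = "mapping_model")
}

#' @export
print.mapping_model <- function(x, ...) {
  cat(sprintf("<mapping_model> degree %d, %d terms, %d training spectra\n",
              x$degree, nrow(x$exponents), x$n_training))
  cat("R-squared:", paste(sprintf("%s=%.4f", names(x$r_squared), x$r_squared),
                          collapse = " "), "\n")
  invisible(x)
}

#' Apply a fitted mapping to camera values
#'
#' Evaluates the polynomial per receptor. Non-positive predictions are
#' floored at a small epsilon (with a warning) because downstream
#' discriminability works on log catches.
#'
#' @param model A [fit_polynomial_mapping()] model.
#' @param camera_values Named per-channel vector, or matrix with channel
#'   columns, of calibrated camera reflectances.
#' @param epsilon Floor for non-positive predictions (default 1e-6).
#' @return `cone_catch` vector (single input) or matrix (multiple rows).
#' @export
apply_mapping <- function(model, camera_values, epsilon = 1e-6) {
  single <- is.null(dim(camera_values))
  X <- if (single) matrix(camera_values, 1,
                          dimnames = list(NULL, names(camera_values)))
       else as.matrix(camera_values)
  if (!all(model$channels %in% colnames(X))) {
    stop("missing camera channel(s): ",
         paste(setdiff(model$channels, colnames(X)), collapse = ", "))
  }
  X <- X[, model$channels, drop = FALSE]
  D <- .design_matrix(X, model$exponents)
  pred <- D %*% model$coefficients
  if (any(pred <= 0)) {
    warning("non-positive predicted catches floored at ", epsilon)
    pred[pred <= 0] <- epsilon
  }
  if (single) {
    q <- pred[1, ]
    names(q) <- model$receptors
    if (identical(model$receptors, c("uv", "sw", "mw", "lw", "dbl"))) {
      class(q) <- "cone_catch"
    }
    q
  } else {
    colnames(pred) <- model$receptors
    pred
  }
}

#' Build a mapping training set from a spectral library
#'
#' Computes, for every library spectrum, the camera channel catches and
#' the viewer's cone catches under a shared illuminant.
#'
#' @param library List of [reflectance_spectrum()].
#' @param camera Camera sensitivity matrix (default
#'   [camera_sensitivities()]).
#' @param viewer Viewer sensitivity matrix (default
#'   [blue_tit_sensitivities()]).
#' @param illuminant Illuminant on each grid (default D65).
#' @return List with matrices `camera_values` and `cone_catches`.
#' @export
mapping_training_set <- function(library, camera = NULL, viewer = NULL,
                                 illuminant = NULL) {
  if (is.null(camera)) camera <- camera_sensitivities()
  if (is.null(viewer)) viewer <- blue_tit_sensitivities()
  X <- t(vapply(library, function(sp)
    unname(compute_cone_catch(sp, camera, illuminant)),
    numeric(ncol(camera))))
  Q <- t(vapply(library, function(sp)
    unname(compute_cone_catch(sp, viewer, illuminant)),
    numeric(ncol(viewer))))
  colnames(X) <- colnames(camera)
  colnames(Q) <- colnames(viewer)
  list(camera_values = X, cone_catches = Q)
}

#' Serialise / restore a mapping model as JSON
#'
#' @param model A `mapping_model`.
#' @param path File path.
#' @export
write_mapping_json <- function(model, path) {
  jsonlite::write_json(
    list(degree = model$degree, intercept = model$intercept,
         channels = model$channels, receptors = model$receptors,
         exponents = model$exponents,
         coefficients = model$coefficients,
         r_squared = as.list(model$r_squared),
         n_training = model$n_training),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mapping_json
#' @export
read_mapping_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.matrix(x$coefficients)
  colnames(coefs) <- x$receptors
  structure(list(exponents = as.matrix(x$exponents), coefficients = coefs,
                 r_squared = unlist(x$r_squared), channels = x$channels,
                 receptors = x$receptors, degree = x$degree,
                 intercept = x$intercept, n_training = x$n_training),
            class = "mapping_model")
}
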