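# Designing printable artificial-prey colours matched to a target species
# under the modelled predator's vision. The print device's colour space is
# an opaque payload; matching operates purely on measured cone catches.

#' Generate a grid of candidate model colours around a target
#'
#' Deterministic multiplicative grid over the four single-cone catches:
#' each channel spans `target * (1 +/- spread)` in `n_steps` steps, and
#' the double-cone catch scales with the mean channel factor (glossy PVA
#' coating affects all channels together). Candidate count is
#' `n_steps^4`.
#'
#' @param target Target [cone_catch()] (species mean).
#' @param n_steps Steps per channel (>= 2).
#' @param spread Half-width of the grid as a fraction of the target
#'   (> 0, e.g. 0.2).
#' @return Data frame: `candidate_id`, device payload placeholder, and
#'   measured catches `uv, sw, mw, lw, dbl`.
#' @export
generate_colour_grid <- function(target, n_steps = 3, spread = 0.2) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (spread < 0) stop("spread must be non-negative")
  q <- unclass(target)
  channels <- c("uv", "sw", "mw", "lw")
  if (spread == 0) {
    factors <- rep(list(1), 4)
  } else {
    factors <- rep(list(seq(1 - spread, 1 + spread,
                            length.out = n_steps)), 4)
  }
  names(factors) <- channels
  grid <- expand.grid(factors)
  out <- data.frame(candidate_id = sprintf("c%04d", seq_len(nrow(grid))))
  for (ch in channels) out[[ch]] <- q[[ch]] * grid[[ch]]
  out$dbl <- q[["dbl"]] * rowMeans(grid)
  out$device_payload <- apply(round(grid, 4), 1, paste, collapse = "/")
  out
}

#' Select the candidate that best matches the target
#'
#' Minimises the chromatic JND to the target; ties are broken by
#' achromatic JND, then by candidate id. The report carries the winner's
#' and runner-up's JNDs and flags a winner above 3 JND (no adequate
#' match in the grid).
#'
#' @param candidates Data frame from [generate_colour_grid()] (or any
#'   with `candidate_id, uv, sw, mw, lw, dbl`).
#' @param target Target [cone_catch()].
#' @param noise A [receptor_noise()].
#' @return List of class `match_report`: `best` (row), `chromatic_jnd`,
#'   `achromatic_jnd`, `runner_up_jnd`, `adequate`.
#' @export
select_best_match <- function(candidates, target, noise = receptor_noise()) {
  if (!nrow(candidates)) stop("empty candidate list")
  ds <- vapply(seq_len(nrow(candidates)), function(i) {
    q <- cone_catch(candidates$uv[i], candidates$sw[i], candidates$mw[i],
                    candidates$lw[i], candidates$dbl[i])
    chromatic_jnd(q, target, noise)
  }, 0)
  dl <- vapply(seq_len(nrow(candidates)), function(i) {
    q <- cone_catch(candidates$uv[i], candidates$sw[i], candidates$mw[i],
                    candidates$lw[i], candidates$dbl[i])
    achromatic_jnd(q, target, noise)
  }, 0)
  ord <- order(ds, dl, candidates$candidate_id)
  best <- ord[1]
  runner <- if (length(ord) > 1) ds[ord[2]] else NA_real_
  structure(list(best = candidates[best, ], chromatic_jnd = ds[best],
                 achromatic_jnd = dl[best], runner_up_jnd = runner,
                 all_jnd = ds, adequate = ds[best] <= 3),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> best %s at %.3f JND (dL %.3f)%s\n",
              x$best$candidate_id, x$chromatic_jnd, x$achromatic_jnd,
              if (x$adequate) "" else " [WARNING: no match within 3 JND]"))
  invisible(x)
}

#' UV-policy advisory for printed models
#'
#' Printed models omit UV-matched pigments by design (the mimicked
#' species all have very low UV reflectance); this check warns when the
#' target's relative UV catch exceeds the threshold, i.e. when a
#' UV-blind print would misrepresent the signal.
#'
#' @param target Target [cone_catch()].
#' @param threshold Maximum acceptable relative UV catch (default 0.05).
#' @return List of class `uv_advisory`: `relative_uv`, `pass`,
#'   `threshold`; warns when failing.
#' @export
uv_policy_check <- function(target, threshold = 0.05) {
  q <- unclass(target)[c("uv", "sw", "mw", "lw")]
  rel <- q[["uv"]] / sum(q)
  pass <- rel <= threshold
  if (!pass) {
    warning(sprintf(paste0("target UV relative catch %.3f exceeds %.3f: ",
                           "a UV-blind print will misrepresent this signal"),
                    rel, threshold))
  }
  structure(list(relative_uv = rel, pass = pass, threshold = threshold),
            class = "uv_advisory")
}

#' @export
print.uv_advisory <- function(x, ...) {
  cat(sprintf("<uv_advisory> relative UV %.4f vs threshold %.2f: %s\n",
              x$relative_uv, x$threshold, if (x$pass) "pass" else "WARN"))
  invisible(x)
}
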