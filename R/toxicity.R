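# Toxicity summaries: mean 3 h mortality (the honesty response) and LC50.

#' Summarise one specimen's bioassay
#'
#' The toxicity response is the mean number of dead Daphnia across the
#' dilution series at the 3 h check, log-transformed as `ln(mean + 1)`
#' (the +1 keeps zero-mortality specimens finite). The LC50 is estimated
#' as a side product but is not consumed by the honesty analysis.
#'
#' @param records Data frame with columns `specimen_id, dilution, time_h,
#'   dead, n` for a single specimen.
#' @param time Summary time point in hours (default 3).
#' @param lc50 Also estimate the LC50 (default TRUE).
#' @return One-row data frame: `specimen_id, mean_dead_3h, log_toxicity,
#'   lc50, lc50_defined`.
#' @export
summarise_toxicity <- function(records, time = 3, lc50 = TRUE) {
  stopifnot(all(c("specimen_id", "dilution", "time_h", "dead", "n")
                %in% names(records)))
  ids <- unique(records$specimen_id)
  if (length(ids) != 1) stop("records must belong to one specimen")
  at_t <- records[records$time_h == time, ]
  if (!nrow(at_t)) stop("no records at the ", time, " h time point")
  if (any(at_t$dead < 0 | at_t$dead > at_t$n)) {
    stop("dead counts must lie in [0, n]")
  }
  m <- mean(at_t$dead)
  lc <- if (lc50) tryCatch(estimate_lc50(at_t), error = function(e) NULL)
        else NULL
  data.frame(specimen_id = ids, mean_dead_3h = m,
             log_toxicity = log(m + 1),
             lc50 = if (is.null(lc) || !lc$defined) NA_real_ else lc$lc50,
             lc50_defined = !is.null(lc) && lc$defined)
}

#' Summarise a whole bioassay table
#'
#' @param records Bioassay records for one or more specimens.
#' @param time Summary time point (default 3 h).
#' @return Data frame with one row per specimen (see
#'   [summarise_toxicity()]).
#' @export
summarise_toxicity_table <- function(records, time = 3) {
  out <- lapply(split(records, records$specimen_id),
                summarise_toxicity, time = time)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the LC50 from dose-mortality data
#'
#' Maximum-likelihood logistic (or probit) regression of mortality on
#' log-dose at a fixed time point; the LC50 is the dose at which the
#' fitted mortality is 50%, with a delta-method confidence interval on
#' the log-dose scale. Degenerate patterns (all dead, none dead, or a
#' non-increasing dose response) yield `defined = FALSE` rather than a
#' fabricated value.
#'
#' @param records Data frame with `dilution, dead, n` (zero-dose rows are
#'   excluded from the fit); pass one time point's data.
#' @param link `"logit"` (default) or `"probit"`.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return List of class `lc50_fit`: `lc50`, `ci`, `defined`, `slope`,
#'   `fit` (the glm object or NULL).
#' @export
estimate_lc50 <- function(records, link = c("logit", "probit"),
                          conf_level = 0.95) {
  link <- match.arg(link)
  stopifnot(all(c("dilution", "dead", "n") %in% names(records)))
  d <- records[records$dilution > 0, ]
  if (length(unique(d$dilution)) < 3) stop("need >= 3 distinct positive doses")
  tot_dead <- sum(d$dead); tot <- sum(d$n)
  undefined <- function(reason) {
    structure(list(lc50 = NA_real_, ci = c(NA_real_, NA_real_),
                   defined = FALSE, reason = reason, slope = NA_real_,
                   fit = NULL), class = "lc50_fit")
  }
  if (tot_dead == 0) return(undefined("no mortality at any dose"))
  if (tot_dead == tot) return(undefined("complete mortality at every dose"))
  fit <- suppressWarnings(
    glm(cbind(dead, n - dead) ~ log(dilution), family = binomial(link),
        data = d)
  )
  b <- coef(fit)
  if (any(!is.finite(b)) || b[2] <= 0) {
    return(undefined("non-increasing dose response"))
  }
  log_lc50 <- -b[1] / b[2]
  if (log_lc50 > 0) {
    # a defined LC50 must lie within the tested dilution range (0, 1]
    return(undefined("LC50 beyond the tested dilution range"))
  }
  V <- vcov(fit)
  g <- c(-1 / b[2], b[1] / b[2]^2)   # d(log LC50)/d(b0, b1)
  se <- sqrt(drop(t(g) %*% V %*% g))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(lc50 = exp(log_lc50),
                 ci = exp(log_lc50 + c(-1, 1) * zq * se),
                 defined = TRUE, reason = NULL,
                 slope = unname(b[2]), fit = fit),
            class = "lc50_fit")
}

#' @export
print.lc50_fit <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<lc50_fit> LC50 = %.4f (CI %.4f-%.4f), slope %.2f\n",
                x$lc50, x$ci[1], x$ci[2], x$slope))
  } else {
    cat("<lc50_fit> undefined:", x$reason, "\n")
  }
  invisible(x)
}

#' Compare water, methanol-blank and extract mortality
#'
#' Pools 3 h mortality within each group, reports group means, orders
#' them, and tests each pair with a two-sample proportion test. An
#' ordering is only claimed between groups whose difference is
#' significant at `alpha`.
#'
#' @param water,methanol,extract Bioassay record data frames (all three
#'   required).
#' @param time Time point in hours (default 3).
#' @param alpha Significance level for claimed orderings (default 0.05).
#' @return List of class `control_comparison`: `means`, `tests` (pairwise
#'   data frame), `ordering` (character, possibly empty).
#' @export
compare_controls <- function(water, methanol, extract, time = 3,
                             alpha = 0.05) {
  groups <- list(water = water, methanol = methanol, extract = extract)
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (is.null(g) || !nrow(g)) stop("missing group: ", nm)
    if (!all(c("dead", "n", "time_h") %in% names(g))) {
      stop("group '", nm, "' lacks dead/n/time_h columns")
    }
  }
  tally <- lapply(groups, function(g) {
    gt <- g[g$time_h == time, ]
    c(dead = sum(gt$dead), n = sum(gt$n))
  })
  means <- vapply(tally, function(x) x[["dead"]] / x[["n"]], 0)
  pairs <- utils::combn(names(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- tally[[pairs[1, k]]]; b <- tally[[pairs[2, k]]]
    pt <- suppressWarnings(stats::prop.test(c(a["dead"], b["dead"]),
                                            c(a["n"], b["n"])))
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               mortality_a = a[["dead"]] / a[["n"]],
               mortality_b = b[["dead"]] / b[["n"]],
               p_value = pt$p.value)
  }))
  sig <- tests$p_value < alpha
  ordering <- if (all(sig) && !any(duplicated(means))) {
    paste(names(sort(means)), collapse = " < ")
  } else if (any(sig)) {
    paste(apply(tests[sig, , drop = FALSE], 1, function(r) {
      lo <- if (as.numeric(r["mortality_a"]) < as.numeric(r["mortality_b"]))
        c(r["group_a"], r["group_b"]) else c(r["group_b"], r["group_a"])
      paste(lo, collapse = " < ")
    }), collapse = "; ")
  } else {
    ""
  }
  structure(list(means = means, tests = tests, ordering = ordering,
                 alpha = alpha), class = "control_comparison")
}

#' @export
print.control_comparison <- function(x, ...) {
  cat("<control_comparison> mortality:",
      paste(sprintf("%s=%.3f", names(x$means), x$means), collapse = " "), "\n")
  if (nzchar(x$ordering)) cat("ordering:", x$ordering, "\n")
  else cat("no ordering claimed\n")
  invisible(x)
}
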