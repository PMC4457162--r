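# The headline analyses: does conspicuousness predict toxicity among and
# within species, and does it predict survival in the field?

.honesty_predictors <- c("size_mm", "weight_g", "luminance", "saturation",
                         "area_cm2", "background_chromatic_jnd",
                         "background_achromatic_jnd", "internal_dl")

# z-score numeric predictors; constant columns are reported and left out
.standardise <- function(table, predictors) {
  dropped <- character(0)
  for (p in predictors) {
    s <- sd(table[[p]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, p)
      next
    }
    table[[p]] <- (table[[p]] - mean(table[[p]], na.rm = TRUE)) / s
  }
  list(table = table, dropped = dropped)
}

#' Fit the signal-honesty model
#'
#' Linear model of log-toxicity on species plus the standardised signal
#' attributes (size, weight, luminance, saturation, pattern area,
#' chromatic and achromatic background contrast, internal luminance
#' contrast), with the biologically motivated two-way interactions
#' (species x chromatic contrast, species x saturation, saturation x
#' chromatic contrast) and backward simplification by AIC. The full
#' additive fit is always reported alongside, and the headline
#' `contrast_effect` (coefficient, SE, two-sided p of chromatic
#' background contrast in a species-adjusted model on the raw JND scale)
#' is returned explicitly: the signal attributes are strongly collinear
#' (they share the same underlying pigmentation), so the full-model
#' partial coefficient is reported but not treated as "the" honesty
#' slope.
#'
#' @param table Specimen table: one row per specimen with columns
#'   `species`, `log_toxicity` and the predictors above; rows with
#'   missing values are dropped with an explicit report.
#' @param response Response column (default `"log_toxicity"`).
#' @param interactions `"reported"` (default, the three interactions
#'   above), `"none"`, or `"all"` (every two-way interaction; needs many
#'   specimens).
#' @param select Simplify by backward AIC (default TRUE); species is
#'   always retained.
#' @return List of class `honesty_fit`: `full` and `selected` lm fits,
#'   `additive` fit, `headline` fit (species + chromatic contrast),
#'   `contrast_effect`, `saturation_effect`, `retained_terms`,
#'   `na_report`, `dropped_constant`.
#' @export
fit_honesty_model <- function(table, response = "log_toxicity",
                              interactions = c("reported", "none", "all"),
                              select = TRUE) {
  interactions <- match.arg(interactions)
  stopifnot(response %in% names(table), "species" %in% names(table))
  if (length(unique(table$species)) < 2) stop("need >= 2 species")
  preds <- intersect(.honesty_predictors, names(table))
  keep <- complete.cases(table[, c(response, "species", preds)])
  na_report <- table$specimen_id[!keep]
  tab <- table[keep, ]
  raw_tab <- tab
  std <- .standardise(tab, preds)
  tab <- std$table
  preds_used <- setdiff(preds, std$dropped)
  tab$species <- factor(tab$species)

  additive_terms <- c("species", preds_used)
  inter_terms <- switch(interactions,
    none = character(0),
    reported = intersect(
      c("species:background_chromatic_jnd", "species:saturation",
        "saturation:background_chromatic_jnd"),
      c(outer(additive_terms, additive_terms, paste, sep = ":"))),
    all = {
      cmb <- utils::combn(additive_terms, 2)
      paste(cmb[1, ], cmb[2, ], sep = ":")
    })
  full_formula <- reformulate(c(additive_terms, inter_terms),
                              response = response)
  full <- lm(full_formula, data = tab)
  additive <- lm(reformulate(additive_terms, response = response), data = tab)
  selected <- if (select) {
    tryCatch(
      step(full,
           scope = list(lower = reformulate("species", response = response)),
           direction = "backward", trace = 0),
      error = function(e) {
        warning("AIC simplification failed (", conditionMessage(e),
                "); reporting the full model")
        full
      })
  } else {
    full
  }
  effect_of <- function(fit, term) {
    cf <- summary(fit)$coefficients
    if (!term %in% rownames(cf)) {
      return(list(estimate = NA_real_, se = NA_real_, p_value = NA_real_,
                  present = FALSE))
    }
    list(estimate = cf[term, 1], se = cf[term, 2], p_value = cf[term, 4],
         present = TRUE)
  }
  retained <- attr(terms(selected), "term.labels")
  # headline: species-adjusted contrast slope on the raw JND scale
  headline <- if ("background_chromatic_jnd" %in% preds_used) {
    lm(reformulate(c("species", "background_chromatic_jnd"),
                   response = response), data = raw_tab)
  } else {
    NULL
  }
  structure(list(
    full = full, selected = selected, additive = additive,
    headline = headline,
    contrast_effect = if (is.null(headline))
      list(estimate = NA_real_, se = NA_real_, p_value = NA_real_,
           present = FALSE)
      else effect_of(headline, "background_chromatic_jnd"),
    saturation_effect = effect_of(additive, "saturation"),
    retained_terms = retained,
    contrast_retained = any(grepl("background_chromatic_jnd", retained)),
    na_report = na_report, dropped_constant = std$dropped,
    n = nrow(tab)), class = "honesty_fit")
}

#' @export
print.honesty_fit <- function(x, ...) {
  cat(sprintf("<honesty_fit> n=%d; retained: %s\n", x$n,
              paste(x$retained_terms, collapse = ", ")))
  ce <- x$contrast_effect
  cat(sprintf("chromatic contrast (species-adjusted): %.4f +/- %.4f, p=%.3g\n",
              ce$estimate, ce$se, ce$p_value))
  invisible(x)
}

#' Within-species saturation-toxicity association
#'
#' Centres saturation and log-toxicity within species (removing all
#' between-species differences) and regresses centred saturation on
#' centred log-toxicity, pooling specimens; per-species slopes are also
#' reported. Species with fewer than `min_n` specimens are excluded with
#' a warning.
#'
#' @param table Specimen table with `species`, `saturation`,
#'   `log_toxicity`.
#' @param min_n Minimum specimens per species (default 5).
#' @return List of class `within_species_test`: `pooled_slope`, `se`,
#'   `p_value`, `per_species` data frame, `n_species`.
#' @export
within_species_saturation_test <- function(table, min_n = 5) {
  stopifnot(all(c("species", "saturation", "log_toxicity") %in% names(table)))
  counts <- table(table$species)
  small <- names(counts)[counts < min_n]
  if (length(small)) {
    warning("excluding species with < ", min_n, " specimens: ",
            paste(small, collapse = ", "))
    table <- table[!table$species %in% small, ]
  }
  if (!nrow(table)) stop("no species with enough specimens")
  centred <- do.call(rbind, lapply(split(table, table$species), function(d) {
    d$sat_c <- d$saturation - mean(d$saturation)
    d$tox_c <- d$log_toxicity - mean(d$log_toxicity)
    d
  }))
  pooled <- lm(sat_c ~ tox_c, data = centred)
  cf <- summary(pooled)$coefficients
  per <- do.call(rbind, lapply(split(centred, centred$species), function(d) {
    f <- lm(sat_c ~ tox_c, data = d)
    data.frame(species = d$species[1], slope = coef(f)[["tox_c"]],
               n = nrow(d))
  }))
  rownames(per) <- NULL
  structure(list(pooled_slope = cf["tox_c", 1], se = cf["tox_c", 2],
                 p_value = cf["tox_c", 4], per_species = per,
                 n_species = length(unique(centred$species)),
                 fit = pooled),
            class = "within_species_test")
}

#' @export
print.within_species_test <- function(x, ...) {
  cat(sprintf("<within_species_test> pooled slope %.4f +/- %.4f (p=%.3g), %d species\n",
              x$pooled_slope, x$se, x$p_value, x$n_species))
  invisible(x)
}

#' Leave-one-species-out robustness check
#'
#' Refits the honesty model dropping each species in turn and reports
#' whether the chromatic-contrast and saturation effects keep their sign
#' and significance; flags the analysis as unstable when a single
#' exclusion changes the conclusion.
#'
#' @param table Specimen table (>= 3 species).
#' @param alpha Significance level used for the stability flags.
#' @param ... Passed to [fit_honesty_model()].
#' @return List of class `loso_report`: `per_exclusion` data frame,
#'   `contrast_stable`, `saturation_stable`.
#' @export
leave_one_species_out <- function(table, alpha = 0.05, ...) {
  species <- unique(table$species)
  if (length(species) < 3) stop("need >= 3 species")
  base <- fit_honesty_model(table, ...)
  base_sign <- sign(base$contrast_effect$estimate)
  rows <- lapply(species, function(sp) {
    fit <- fit_honesty_model(table[table$species != sp, ], ...)
    data.frame(excluded = sp,
               contrast_coef = fit$contrast_effect$estimate,
               contrast_p = fit$contrast_effect$p_value,
               contrast_retained = fit$contrast_retained,
               saturation_coef = fit$saturation_effect$estimate,
               saturation_p = fit$saturation_effect$p_value)
  })
  per <- do.call(rbind, rows)
  contrast_stable <- all(sign(per$contrast_coef) == base_sign) &&
    all(per$contrast_p < alpha) && base$contrast_effect$p_value < alpha
  saturation_stable <- all(sign(per$saturation_coef) ==
                             sign(base$saturation_effect$estimate))
  structure(list(per_exclusion = per, contrast_stable = contrast_stable,
                 saturation_stable = saturation_stable, base = base),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat("<loso_report> contrast effect stable:", x$contrast_stable, "\n")
  print(x$per_exclusion, row.names = FALSE)
  invisible(x)
}

#' Relate field survival to conspicuousness
#'
#' Tests whether less conspicuous models are attacked more: a logistic
#' regression of the 48 h attack indicator on the model's measured
#' chromatic JND (with transect as a fixed block when present), with the
#' stratified Cox fit as a cross-check.
#'
#' @param records Predation records with a `jnd` column (per-model
#'   measured contrast) plus `time_h`/`status` and optional `transect`.
#' @return List of class `conspicuousness_report`: `defined`, `logistic`
#'   (coef/se/p for jnd), `cox` (coef/se/p for jnd), `direction`.
#' @export
survival_vs_conspicuousness <- function(records) {
  rec <- as.data.frame(records)
  if (!"jnd" %in% names(rec)) stop("records need a 'jnd' column")
  if (!all(complete.cases(rec$jnd))) stop("unmatched model ids: missing jnd")
  if (sd(rec$jnd) == 0) {
    warning("constant JND across models: association undefined")
    return(structure(list(defined = FALSE), class = "conspicuousness_report"))
  }
  rec$event <- if ("event" %in% names(rec)) as.logical(rec$event) else
    rec$status == "attacked"
  has_blocks <- "transect" %in% names(rec) &&
    length(unique(rec$transect)) > 1
  f <- if (has_blocks) event ~ jnd + factor(transect) else event ~ jnd
  lg <- suppressWarnings(glm(f, family = binomial(), data = rec))
  cf <- summary(lg)$coefficients["jnd", ]
  cox <- fit_cox(rec, ~ jnd, strata = if (has_blocks) "transect" else NULL)
  structure(list(
    defined = TRUE,
    logistic = list(estimate = cf[[1]], se = cf[[2]], p_value = cf[[4]]),
    cox = list(estimate = unname(cox$coef["jnd"]), se = unname(cox$se["jnd"]),
               p_value = unname(cox$p_value["jnd"])),
    direction = if (cf[[1]] < 0) "higher contrast, fewer attacks"
                else "higher contrast, more attacks"),
    class = "conspicuousness_report")
}

#' @export
print.conspicuousness_report <- function(x, ...) {
  if (!x$defined) {
    cat("<conspicuousness_report> undefined (no JND variation)\n")
    return(invisible(x))
  }
  cat(sprintf("<conspicuousness_report> logistic: %.4f (p=%.3g); cox: %.4f (p=%.3g)\n",
              x$logistic$estimate, x$logistic$p_value,
              x$cox$estimate, x$cox$p_value))
  cat(x$direction, "\n")
  invisible(x)
}
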