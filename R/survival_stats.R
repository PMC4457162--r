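# Survival analysis from first principles: product-limit estimation with
# Greenwood variance, Cox proportional hazards by Breslow partial
# likelihood (with strata), pairwise contrasts, and attack rates.

#' Kaplan-Meier product-limit estimator
#'
#' Standard convention: subjects censored at an event time are counted as
#' at risk through that event. Greenwood's formula supplies the variance.
#'
#' @param time Positive observation times.
#' @param event Logical (or 0/1): TRUE if the event (attack) occurred,
#'   FALSE if right-censored.
#' @return Object of class `survival_curve`: data frame `time, n_risk,
#'   n_event, n_censor, surv, std_err` (one row per distinct event time),
#'   with `S(0) = 1` implicit.
#' @export
kaplan_meier <- function(time, event) {
  event <- as.logical(event)
  if (!length(time)) stop("need at least one record")
  if (any(time <= 0) || any(!is.finite(time))) stop("times must be positive")
  ev_times <- sort(unique(time[event]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), 0)
  n_event <- vapply(ev_times, function(t) sum(event & time == t), 0)
  n_censor <- vapply(ev_times, function(t) sum(!event & time == t), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  std_err <- surv * sqrt(ifelse(is.finite(gw), gw, NA))
  structure(list(table = data.frame(time = ev_times, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv, std_err = std_err),
                 n = length(time), n_events = sum(event)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n=%d, events=%d\n", x$n, x$n_events))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#'
#' @param curve A [kaplan_meier()] curve.
#' @param t Times at which to evaluate `S(t)` (step function, right
#'   continuous).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv <- function(curve, t) {
  tab <- curve$table
  vapply(t, function(ti) {
    past <- tab$surv[tab$time <= ti]
    if (length(past)) past[length(past)] else 1
  }, 0)
}

#' Cox proportional-hazards fit (Breslow partial likelihood)
#'
#' Newton-Raphson maximisation of the stratified Breslow partial
#' likelihood. Block (transect) enters as a stratum: each stratum has its
#' own baseline hazard and contributes its own risk sets, targeting the
#' same confounding as a random block intercept without frailty
#' machinery.
#'
#' @param records Data frame with columns `time_h` and `status`
#'   (`"attacked"` = event) -- or `time`/`event` columns -- plus
#'   covariates.
#' @param formula RHS formula for the covariates, e.g. `~ colour` or
#'   `~ colour + jnd`.
#' @param strata Optional name of a column (e.g. `"transect"`) defining
#'   strata.
#' @param include_ambiguous Keep records censored for non-predator
#'   reasons, treating them as right-censored (default TRUE); `FALSE`
#'   drops them, mirroring an analysis without ambiguous predation cases.
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `cox_fit`: `coef`, `vcov`, `se`, `z`,
#'   `p_value`, `loglik` (c(null, fitted)), `n`, `n_events`, `xlevels`.
#' @export
fit_cox <- function(records, formula = ~ colour, strata = NULL,
                    include_ambiguous = TRUE, max_iter = 25, tol = 1e-9) {
  rec <- as.data.frame(records)
  if ("status" %in% names(rec) && !"event" %in% names(rec)) {
    rec$event <- rec$status == "attacked"
  }
  if ("time_h" %in% names(rec) && !"time" %in% names(rec)) {
    rec$time <- rec$time_h
  }
  stopifnot(all(c("time", "event") %in% names(rec)))
  if (!include_ambiguous && "reason" %in% names(rec)) {
    rec <- rec[rec$event | rec$reason %in% c("none", "administrative"), ]
  }
  if (any(rec$time <= 0)) stop("non-positive times")
  mf <- stats::model.frame(formula, rec)
  for (v in names(mf)) if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  X <- model.matrix(formula, mf)
  asgn <- attr(X, "assign")
  X <- X[, asgn != 0, drop = FALSE]   # drop intercept
  xlevels <- lapply(Filter(is.factor, mf), levels)
  # events per factor level check
  for (v in names(xlevels)) {
    ev_by <- tapply(rec$event, mf[[v]], sum)
    if (any(ev_by == 0)) {
      stop("no events in level(s) ", paste(names(ev_by)[ev_by == 0],
                                           collapse = ", "),
           " of ", v, ": coefficients are not identifiable")
    }
  }
  st <- if (is.null(strata)) rep(1L, nrow(rec)) else factor(rec[[strata]])
  p <- ncol(X)
  beta <- rep(0, p)

  # stratified Breslow partial likelihood with analytic score and
  # information; risk-set sums via cumulative sums on descending times
  pl_fast <- function(beta) {
    ll <- 0; U <- rep(0, p); H <- matrix(0, p, p)
    for (s in split(seq_len(nrow(rec)), st)) {
      ti <- rec$time[s]; ev <- rec$event[s]; Xs <- X[s, , drop = FALSE]
      if (!any(ev)) next
      ord <- order(-ti)
      ti <- ti[ord]; ev <- ev[ord]; Xs <- Xs[ord, , drop = FALSE]
      eta <- drop(Xs %*% beta)
      r <- exp(eta)
      S0 <- cumsum(r)
      S1 <- apply(Xs * r, 2, cumsum)
      if (p == 1) S1 <- matrix(S1, ncol = 1)
      S2 <- array(0, c(length(ti), p, p))
      for (a in seq_len(p)) {
        for (b in a:p) {
          cs <- cumsum(Xs[, a] * Xs[, b] * r)
          S2[, a, b] <- cs
          S2[, b, a] <- cs
        }
      }
      last <- ave(seq_along(ti), ti, FUN = max)
      for (i in which(ev)) {
        j <- last[i]
        s0 <- S0[j]; s1 <- S1[j, ] / s0
        ll <- ll + eta[i] - log(s0)
        U <- U + Xs[i, ] - s1
        H <- H - (S2[j, , ] / s0 - tcrossprod(s1))
      }
    }
    list(ll = ll, U = U, H = H)
  }

  cur <- pl_fast(beta)
  ll_null <- cur$ll
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(-cur$H, cur$U), error = function(e)
      stop("singular information matrix: separation or collinearity"))
    # step halving
    new_beta <- beta + step
    new <- pl_fast(new_beta)
    halvings <- 0
    while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new <- pl_fast(new_beta)
      halvings <- halvings + 1
    }
    done <- max(abs(new$ll - cur$ll), max(abs(step))) < tol
    beta <- new_beta; cur <- new
    if (max(abs(beta)) > 15) {
      stop("monotone likelihood (complete separation): a covariate ",
           "perfectly orders the events")
    }
    if (done) break
  }
  vc <- solve(-cur$H)
  se <- sqrt(diag(vc))
  z <- beta / se
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, vcov = vc, se = setNames(se, colnames(X)),
                 z = setNames(z, colnames(X)),
                 p_value = setNames(2 * pnorm(-abs(z)), colnames(X)),
                 loglik = c(null = ll_null, fitted = cur$ll),
                 n = nrow(rec), n_events = sum(rec$event),
                 xlevels = xlevels, formula = formula, strata = strata,
                 iterations = it),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, loglik %.2f -> %.2f\n",
              x$n, x$n_events, x$loglik[1], x$loglik[2]))
  print(round(data.frame(coef = x$coef, se = x$se, z = x$z,
                         p = x$p_value), 4))
  invisible(x)
}

#' Pairwise survival contrasts between factor levels
#'
#' Contrasts of the fitted log-hazard coefficients between every pair of
#' levels of a factor covariate, with variances from the coefficient
#' covariance (the reference level has coefficient 0). P-values are
#' unadjusted by default; `p_adjust` applies a multiplicity correction.
#'
#' @param fit A [fit_cox()] model containing the factor.
#' @param factor_name Name of the factor covariate (default the first
#'   factor in the model).
#' @param pairs Optional 2-column character matrix of level pairs; all
#'   pairs by default.
#' @param p_adjust Method for [stats::p.adjust()] (default `"none"`).
#' @return Data frame `level_a, level_b, coef, se, z, p`.
#' @export
pairwise_survival <- function(fit, factor_name = NULL, pairs = NULL,
                              p_adjust = "none") {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(factor_name)) {
    if (!length(fit$xlevels)) stop("model has no factor covariate")
    factor_name <- names(fit$xlevels)[1]
  }
  levs <- fit$xlevels[[factor_name]]
  if (is.null(levs)) stop("unknown factor '", factor_name, "'")
  cname <- function(l) paste0(factor_name, l)
  getc <- function(l) if (l == levs[1]) 0 else fit$coef[[cname(l)]]
  getv <- function(la, lb) {
    va <- if (la == levs[1]) 0 else fit$vcov[cname(la), cname(la)]
    vb <- if (lb == levs[1]) 0 else fit$vcov[cname(lb), cname(lb)]
    vab <- if (la == levs[1] || lb == levs[1]) 0 else
      fit$vcov[cname(la), cname(lb)]
    va + vb - 2 * vab
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(levs, 2))
  } else {
    pairs <- matrix(as.character(pairs), ncol = 2)
    if (!all(pairs %in% levs)) {
      stop("unknown level(s): ",
           paste(setdiff(unique(as.vector(pairs)), levs), collapse = ", "))
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    la <- pairs[k, 1]; lb <- pairs[k, 2]
    cf <- getc(la) - getc(lb)
    v <- getv(la, lb)
    se <- sqrt(max(v, 0))
    z <- if (se > 0) cf / se else 0
    data.frame(level_a = la, level_b = lb, coef = cf, se = se, z = z,
               p = if (se > 0) 2 * pnorm(-abs(z)) else 1)
  }))
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Attack rate with exact binomial confidence interval
#'
#' @param records Predation records (see [fit_cox()] for accepted
#'   columns).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `rate`, `n_attacked`, `n`, `ci`.
#' @export
attack_rate <- function(records, conf_level = 0.95) {
  rec <- as.data.frame(records)
  if (!nrow(rec)) stop("no records")
  ev <- if ("event" %in% names(rec)) as.logical(rec$event) else
    rec$status == "attacked"
  k <- sum(ev); n <- length(ev)
  bt <- binom.test(k, n, conf.level = conf_level)
  list(rate = k / n, n_attacked = k, n = n,
       ci = as.numeric(bt$conf.int))
}
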