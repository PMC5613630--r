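#' Fit a proportional-odds cumulative-logit model by maximum likelihood
#'
#' The single-level ordinal regression engine beneath the OLR DIF tests:
#' `logit P(Y <= k) = zeta_k - x' beta` with common slopes across cutpoints.
#' Intercept-only models use the closed form (cutpoints = empirical cumulative
#' logits); models with predictors are maximized via [MASS::polr()] with a
#' tight convergence tolerance.
#'
#' Response categories not observed in `y` are collapsed to consecutive codes
#' before fitting (recorded in the result); nested models fitted on the same
#' `y` therefore share the same collapse, so likelihood-ratio tests are
#' unaffected.
#'
#' @param y integer (or factor) ordinal response with at least 2 observed
#'   categories.
#' @param X numeric design matrix (no intercept column), or `NULL` for an
#'   intercept-only model.
#' @return an object of class `po_fit`: list with `loglik`, `coefficients`
#'   (named: cutpoints `alpha_1..alpha_{K-1}` then slopes), `se`,
#'   `converged`, `n_iter`, `n_obs`, `n_levels`, `collapsed` (logical),
#'   `levels` (original codes retained), `y_hash` (for nesting checks).
#' @export
fit_proportional_odds <- function(y, X = NULL) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (anyNA(y)) stop("'y' contains missing values")
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("response has fewer than 2 observed categories")
  yf <- factor(y, levels = lev)
  n <- length(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("'X' and 'y' sizes differ")
    if (ncol(X) == 0L) X <- NULL
  }
  K <- length(lev)
  y_hash <- sum(as.double(y) * seq_len(n)) + n  # cheap same-data fingerprint

  if (is.null(X)) {
    # closed-form ML: cutpoints are logits of cumulative proportions
    pk <- as.numeric(table(yf)) / n
    zeta <- stats::qlogis(cumsum(pk)[-K])
    ll <- sum(table(yf) * log(pk))
    se <- sqrt(1 / (n * cumsum(pk)[-K] * (1 - cumsum(pk)[-K])))
    names(zeta) <- names(se) <- paste0("alpha_", seq_len(K - 1L))
    return(new_po_fit(ll, zeta, se, TRUE, 0L, n, K, lev, y_hash))
  }

  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- data.frame(.y = yf, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", colnames(X)),
                                       collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = dat, Hess = TRUE,
                                method = "logistic",
                                control = list(reltol = 1e-12, maxit = 500))),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new_po_fit(NA_real_, NULL, NULL, FALSE, 0L, n, K, lev, y_hash,
                      message = conditionMessage(fit)))

  beta <- fit$coefficients
  zeta <- fit$zeta
  names(zeta) <- paste0("alpha_", seq_len(K - 1L))
  coefs <- c(zeta, beta)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[c(names(fit$zeta),
                                                names(beta))],
                 error = function(e) rep(NA_real_, length(coefs)))
  names(se) <- names(coefs)
  converged <- (fit$convergence == 0L) && all(is.finite(se)) &&
    max(abs(beta)) < 30  # wild slopes signal separation
  new_po_fit(as.numeric(stats::logLik(fit)), coefs, se, converged,
             as.integer(fit$niter[1]), n, K, lev, y_hash)
}

new_po_fit <- function(loglik, coefficients, se, converged, n_iter, n_obs,
                       n_levels, levels, y_hash, message = NULL) {
  structure(list(loglik = loglik, coefficients = coefficients, se = se,
                 converged = converged, n_iter = n_iter, n_obs = n_obs,
                 n_levels = n_levels, levels = levels,
                 collapsed = length(levels) < (max(levels) - min(levels) + 1L),
                 y_hash = y_hash, message = message),
            class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Proportional-odds fit:", x$n_obs, "obs,", x$n_levels, "categories\n")
  if (!x$converged) cat("  ** not converged **",
                        if (!is.null(x$message)) x$message, "\n")
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (!is.null(x$coefficients)) {
    print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi_square = 2 (loglik_full - loglik_reduced)` (clipped below at zero),
#' degrees of freedom = difference in parameter count, upper-tail chi-square
#' p-value. With zero degrees of freedom (a model compared with itself) the
#' p-value is reported as 1. Both fits must be converged and fitted on the
#' same response.
#'
#' @param fit_full,fit_reduced nested `po_fit` (or `holr_fit`) objects on the
#'   same data; for mixed fits the random-effect structure must match and df
#'   counts fixed effects only.
#' @return list of class `lr_test`: `chi_square`, `df`, `p_value`, `valid`.
#' @export
lr_statistic <- function(fit_full, fit_reduced) {
  if (!identical(fit_full$n_obs, fit_reduced$n_obs) ||
      !isTRUE(all.equal(fit_full$y_hash, fit_reduced$y_hash)))
    stop("models were not fitted on the same data")
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  if (inherits(fit_full, "holr_fit")) {
    if (!inherits(fit_reduced, "holr_fit"))
      stop("cannot compare a mixed fit with a single-level fit")
    # sigma_u is shared structure, not a tested fixed effect
  } else if (inherits(fit_reduced, "holr_fit")) {
    stop("cannot compare a single-level fit with a mixed fit")
  }
  if (df < 0) stop("'fit_full' has fewer parameters than 'fit_reduced'")
  valid <- isTRUE(fit_full$converged) && isTRUE(fit_reduced$converged)
  chi <- if (valid) max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
         else NA_real_
  p <- if (!valid) NA_real_
       else if (df == 0L) 1
       else stats::pchisq(chi, df, lower.tail = FALSE)
  structure(list(chi_square = chi, df = df, p_value = p, valid = valid),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR test: chi-square = %.4f, df = %d, p = %.4g%s\n",
              x$chi_square, x$df, x$p_value,
              if (!x$valid) "  [invalid: non-converged fit]" else ""))
  invisible(x)
}
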