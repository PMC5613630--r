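# Gauss-Hermite nodes/weights (physicists' convention) by Golub-Welsch:
# eigendecomposition of the symmetric tridiagonal Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  Jm <- matrix(0, n, n)
  Jm[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  Jm[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(Jm, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Fit a random-intercept hierarchical cumulative-logit model (HOLR)
#'
#' Maximum marginal likelihood for the two-level proportional-odds model
#' `logit P(Y_ij <= k) = zeta_k - (x_ij' beta + u_j)`,
#' `u_j ~ N(0, sigma_u^2)`, the hierarchical engine beneath the HOLR DIF
#' tests. Cluster-level covariates (a between-cluster grouping variable)
#' enter the same linear predictor as cluster-constant columns of `X`, i.e.
#' the random-intercept equation. The per-cluster integral over `u_j` is
#' evaluated by adaptive Gauss-Hermite quadrature (nodes centred and scaled
#' at each cluster's posterior mode), falling back to plain Gauss-Hermite
#' when mode-finding fails. `sigma_u` is optimized on the log scale; an
#' estimate below `1e-8` is reported as a boundary zero.
#'
#' @param y integer ordinal response (unobserved categories are collapsed as
#'   in [fit_proportional_odds()]).
#' @param X numeric design matrix of fixed-effect predictors (no intercept
#'   column), or `NULL`.
#' @param cluster cluster identifier vector, one per observation.
#' @param nodes number of quadrature nodes (default 15).
#' @param adaptive use adaptive (mode-centred) quadrature (default `TRUE`).
#' @param sigma_fixed if non-`NULL`, fix the random-intercept SD at this
#'   value (0 reduces the model to [fit_proportional_odds()]).
#' @param start optional named start values (`zeta`, `beta`, `sigma`).
#' @param se compute standard errors from the numerically differentiated
#'   observed information (default `TRUE`; skip for speed in simulations).
#' @return object of class `c("holr_fit", "po_fit")`: fields of `po_fit`
#'   (coefficients = fixed effects only) plus `sigma_u2`, `sigma_u2_se`,
#'   `boundary`, `n_clusters`, `quadrature_nodes`, `adaptive`.
#' @export
fit_holr <- function(y, X = NULL, cluster, nodes = 15L, adaptive = TRUE,
                     sigma_fixed = NULL, start = NULL, se = TRUE) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  n <- length(y)
  if (length(cluster) != n) stop("'cluster' and 'y' sizes differ")
  if (anyNA(y) || anyNA(cluster)) stop("missing values in 'y' or 'cluster'")
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("response has fewer than 2 observed categories")
  cl <- as.integer(factor(cluster))
  J <- max(cl)
  if (J < 2L && is.null(sigma_fixed)) stop("need at least 2 clusters")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("'X' and 'y' sizes differ")
    if (ncol(X) == 0L) X <- NULL
  }
  p <- if (is.null(X)) 0L else ncol(X)
  y_hash <- sum(as.double(y) * seq_len(n)) + n
  K <- length(lev)
  yc <- as.integer(factor(y, levels = lev)) - 1L   # collapsed 0..K-1

  # sort by cluster for contiguous cluster blocks
  ord <- order(cl)
  yo <- yc[ord]
  Xo <- if (p > 0L) X[ord, , drop = FALSE] else matrix(0, n, 0L)
  clo <- cl[ord]
  cl_len <- as.integer(tabulate(clo, J))
  cl_start <- as.integer(c(0L, cumsum(cl_len)[-J]))
  gh <- gauss_hermite(nodes)

  nll_parts <- function(zeta, beta, sigma)
    holr_loglik_cpp(zeta, beta, sigma, yo, Xo, cl_start, cl_len,
                    gh$x, gh$w, adaptive)

  # unconstrained parameterization: zeta_1, log-increments, beta, log sigma
  unpack <- function(par) {
    zeta <- if (K == 2L) par[1L] else cumsum(c(par[1L], exp(par[2:(K - 1L)])))
    beta <- if (p > 0L) par[K:(K - 1L + p)] else numeric(0)
    sigma <- if (is.null(sigma_fixed)) exp(par[length(par)]) else sigma_fixed
    list(zeta = zeta, beta = beta, sigma = sigma)
  }
  negll <- function(par) {
    pp <- unpack(par)
    v <- -nll_parts(pp$zeta, pp$beta, pp$sigma)$loglik
    if (!is.finite(v)) 1e10 else v
  }
  # analytic gradient (chain rule from (zeta, beta, log sigma) to the
  # unconstrained parameterization)
  neggrad <- function(par) {
    pp <- unpack(par)
    g <- holr_loglik_grad_cpp(pp$zeta, pp$beta, pp$sigma, yo, Xo,
                              cl_start, cl_len, gh$x, gh$w)$grad
    gz <- g[seq_len(K - 1L)]
    cs <- rev(cumsum(rev(gz)))
    out <- c(cs[1L],
             if (K > 2L) exp(par[2:(K - 1L)]) * cs[-1L],
             if (p > 0L) g[K:(K - 1L + p)],
             if (is.null(sigma_fixed)) g[K + p])
    if (any(!is.finite(out))) out[] <- 0
    -out
  }

  # start values: single-level fit, sigma_u^2 = 0.1
  if (is.null(start)) {
    po <- fit_proportional_odds(yc, if (p > 0L) X else NULL)
    if (isTRUE(po$converged)) {
      zeta0 <- po$coefficients[seq_len(K - 1L)]
      beta0 <- if (p > 0L) po$coefficients[K:(K - 1L + p)] else numeric(0)
    } else {
      pk <- cumsum(tabulate(yc + 1L, K) / n)[-K]
      zeta0 <- stats::qlogis(pmin(pmax(pk, 1e-4), 1 - 1e-4))
      beta0 <- rep(0, p)
    }
    sigma0 <- sqrt(0.1)
  } else {
    zeta0 <- start$zeta; beta0 <- start$beta %||% numeric(0)
    sigma0 <- start$sigma %||% sqrt(0.1)
  }
  d0 <- diff(zeta0)
  par0 <- c(zeta0[1L], if (K > 2L) log(pmax(d0, 1e-4)), beta0,
            if (is.null(sigma_fixed)) log(sigma0))

  # The adaptive-quadrature objective carries a small smooth ripple (the
  # quadrature error moves with the parameters), which wrecks
  # finite-difference gradients; the analytic quadrature-weighted gradient
  # is immune to it. Convergence is accepted on the optimizer's own codes or
  # on a small analytic gradient at the solution (the ripple can trip the
  # line search within noise of the optimum). A derivative-free simplex
  # restart covers the rare remaining failures.
  rel_tol <- if (is.null(sigma_fixed)) 1e-9 else 1e-12
  opt <- stats::nlminb(par0, negll, gradient = neggrad,
                       control = list(rel.tol = rel_tol, iter.max = 400L,
                                      eval.max = 1000L))
  conv_ok <- function(o)
    o$convergence == 0L ||
    grepl("relative convergence|both X|singular convergence",
          o$message %||% "", ignore.case = TRUE) ||
    max(abs(neggrad(o$par))) < 0.02 * (1 + abs(o$objective) / n)
  converged <- conv_ok(opt)
  if (!converged) {
    nm <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                       control = list(maxit = 3000L, reltol = 1e-10))
    re <- stats::nlminb(nm$par, negll, gradient = neggrad,
                        control = list(rel.tol = 1e-12, iter.max = 200L))
    if (is.finite(re$objective) && re$objective <= opt$objective) {
      opt <- re
      converged <- conv_ok(opt) || nm$convergence == 0L
    } else if (nm$value <= opt$objective) {
      opt <- list(par = nm$par, objective = nm$value,
                  convergence = nm$convergence, message = NULL,
                  iterations = nm$counts[1])
      converged <- nm$convergence == 0L
    }
  }
  pp <- unpack(opt$par)
  boundary <- is.null(sigma_fixed) && pp$sigma^2 < 1e-8
  sigma_hat <- if (boundary) 0 else pp$sigma
  parts <- nll_parts(pp$zeta, pp$beta, sigma_hat)
  ll <- parts$loglik

  coefs <- c(pp$zeta, pp$beta)
  names(coefs) <- c(paste0("alpha_", seq_len(K - 1L)),
                    if (p > 0L) colnames(Xo))
  se_vec <- rep(NA_real_, length(coefs))
  names(se_vec) <- names(coefs)
  sigma_se <- NA_real_

  if (se && converged) {
    # observed information in the (zeta, beta, log sigma) parameterization;
    # valid locally since the cutpoint ordering is strict at the optimum.
    # The Hessian is differenced on a finer quadrature rule (>= 31 nodes)
    # so the quadrature ripple does not contaminate the curvature.
    # near the sigma = 0 boundary the loglik is flat in log sigma and its
    # Hessian row is numerically singular; drop it there (the variance SE is
    # not identified that close to the boundary)
    est_sig <- is.null(sigma_fixed) && !boundary && sigma_hat^2 > 1e-4
    raw <- c(pp$zeta, pp$beta, if (est_sig) log(sigma_hat))
    gh_fine <- if (nodes < 31L) gauss_hermite(31L) else gh
    nll_raw <- function(q) {
      zet <- q[seq_len(K - 1L)]
      if (is.unsorted(zet, strictly = TRUE)) return(NA_real_)
      bet <- if (p > 0L) q[K:(K - 1L + p)] else numeric(0)
      sig <- if (est_sig) exp(q[length(q)]) else sigma_hat
      -holr_loglik_cpp(zet, bet, sig, yo, Xo, cl_start, cl_len,
                       gh_fine$x, gh_fine$w, adaptive)$loglik
    }
    H <- num_hessian(nll_raw, raw, eps = 1e-3)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      sds <- sqrt(diag(V))
      se_vec[] <- sds[seq_along(coefs)]
      if (est_sig) {
        # delta method: sigma^2 = exp(2 t), d sigma^2/dt = 2 sigma^2
        sigma_se <- 2 * sigma_hat^2 * sds[length(sds)]
      } else if (boundary) sigma_se <- 0
    }
    # a failed information matrix leaves SEs NA; the ML fit itself stands
  }

  out <- new_po_fit(ll, coefs, se_vec, converged,
                    as.integer(opt$iterations), n, K, lev, y_hash,
                    message = opt$message)
  out$sigma_u2 <- sigma_hat^2
  out$sigma_u2_se <- sigma_se
  out$boundary <- boundary
  out$n_clusters <- J
  out$quadrature_nodes <- as.integer(nodes)
  out$adaptive <- adaptive
  out$quadrature_ok <- isTRUE(parts$ok)
  class(out) <- c("holr_fit", "po_fit")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central-difference Hessian of scalar function fn at x
num_hessian <- function(fn, x, eps = 1e-4) {
  q <- length(x)
  h <- eps * pmax(abs(x), 1)
  H <- matrix(NA_real_, q, q)
  f0 <- fn(x)
  for (i in seq_len(q)) {
    for (j in i:q) {
      ei <- ej <- numeric(q); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.holr_fit <- function(x, ...) {
  cat("Random-intercept cumulative-logit fit:", x$n_obs, "obs in",
      x$n_clusters, "clusters\n")
  if (!x$converged) cat("  ** not converged **\n")
  cat(sprintf("  marginal log-likelihood: %.4f (adaptive GH, %d nodes)\n",
              x$loglik, x$quadrature_nodes))
  cat(sprintf("  sigma_u^2: %.4f%s\n", x$sigma_u2,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  if (!is.null(x$coefficients))
    print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @rdname lr_statistic
#' @details `lr_statistic_mixed()` applies the same construction to marginal
#'   log-likelihoods of nested random-intercept fits; it additionally checks
#'   that both fits share the random-effect structure and quadrature
#'   settings, and degrees of freedom count fixed effects only.
#' @export
lr_statistic_mixed <- function(fit_full, fit_reduced) {
  if (!inherits(fit_full, "holr_fit") || !inherits(fit_reduced, "holr_fit"))
    stop("both fits must be 'holr_fit' objects")
  if (!identical(fit_full$quadrature_nodes, fit_reduced$quadrature_nodes) ||
      !identical(fit_full$n_clusters, fit_reduced$n_clusters))
    stop("fits do not share the random-effect/quadrature structure")
  lr_statistic(fit_full, fit_reduced)
}
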