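# Independent oracles used across tests. Everything here is written from
# first principles (no calls into the package's fitting paths).

# plain proportional-odds log-likelihood: logit P(Y<=k) = zeta_k - x'beta
oracle_po_loglik <- function(y, x, zeta, beta) {
  K <- length(zeta) + 1L
  eta <- outer(rep(1, length(y)), c(zeta, Inf)) - as.vector(x %*% beta)
  cum <- plogis(eta)                               # P(Y <= k), k = 1..K
  low <- cbind(0, cum[, -K, drop = FALSE])
  p <- cum - low
  sum(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-300)))
}

# brute-force likelihood maximization by iterative grid refinement over
# (zeta_1, increment, slope) for a 3-category, 1-predictor model
oracle_grid_search <- function(y, x, rounds = 14L, pts = 11L) {
  stopifnot(length(unique(y)) == 3L)
  x <- x - mean(x)       # loglik is centering-invariant; keeps the box small
  pk <- cumsum(as.numeric(table(factor(y, levels = 0:2)))) / length(y)
  ctr <- c(qlogis(pk[1]), log(qlogis(pk[2]) - qlogis(pk[1])), 0)
  wid <- c(3, 2, 3)
  best <- -Inf; best_par <- ctr
  for (r in seq_len(rounds)) {
    g1 <- seq(ctr[1] - wid[1], ctr[1] + wid[1], length.out = pts)
    g2 <- seq(ctr[2] - wid[2], ctr[2] + wid[2], length.out = pts)
    g3 <- seq(ctr[3] - wid[3], ctr[3] + wid[3], length.out = pts)
    for (a1 in g1) for (a2 in g2) for (b in g3) {
      ll <- oracle_po_loglik(y, cbind(x), c(a1, a1 + exp(a2)), b)
      if (ll > best) { best <- ll; best_par <- c(a1, a2, b) }
    }
    ctr <- best_par
    wid <- wid * 0.35
  }
  list(loglik = best,
       zeta = c(best_par[1], best_par[1] + exp(best_par[2])),
       beta = best_par[3])
}

# dense-grid marginalization over the random intercept: per-cluster trapezoid
# integral of prod_i P(y_i | u) * dnorm(u; 0, sigma) on a 2001-point grid
oracle_marginal_loglik <- function(y, x, cluster, zeta, beta, sigma,
                                   npts = 2001L) {
  if (sigma < 1e-10)
    return(oracle_po_loglik(y, cbind(x), zeta, beta))
  lim <- max(8 * sigma, 4)
  u <- seq(-lim, lim, length.out = npts)
  du <- u[2] - u[1]
  total <- 0
  for (j in unique(cluster)) {
    idx <- which(cluster == j)
    lg <- vapply(u, function(uu)
      oracle_po_loglik(y[idx], cbind(x[idx]), zeta - uu, beta), 0) +
      dnorm(u, 0, sigma, log = TRUE)
    m <- max(lg)
    w <- rep(1, npts); w[c(1, npts)] <- 0.5        # trapezoid weights
    total <- total + m + log(sum(w * exp(lg - m)) * du)
  }
  total
}

# one-way random-effects (ANOVA) intraclass correlation estimator
oracle_icc_anova <- function(theta, cluster) {
  m <- tapply(theta, cluster, mean)
  n_j <- tapply(theta, cluster, length)
  k <- length(m); n <- length(theta)
  gm <- mean(theta)
  msb <- sum(n_j * (m - gm)^2) / (k - 1)
  msw <- sum((theta - m[as.character(cluster)])^2) / (n - k)
  n0 <- (n - sum(n_j^2) / n) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

# theta-integrated GRM category probabilities (logistic, difficulty form)
oracle_marginal_cat_probs <- function(a, thresholds) {
  K <- length(thresholds) + 1L
  sapply(0:(K - 1L), function(k) {
    integrate(function(t) {
      cum <- sapply(thresholds, function(b) plogis(a * (t - b)))
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = length(t))
      p <- cbind(1 - cum[, 1], if (K > 2) cum[, -(K - 1), drop = FALSE] -
                   cum[, -1, drop = FALSE], cum[, K - 1])
      p[, k + 1L] * dnorm(t)
    }, -10, 10)$value
  })
}

# simulate directly from the random-intercept cumulative-logit model
# logit P(Y<=k) = zeta_k - (x'beta + u_j), u_j ~ N(0, sigma^2)
sim_holr_data <- function(n_clusters, cluster_size, zeta, beta, sigma,
                          X = NULL, seed = 1) {
  set.seed(seed)
  n <- n_clusters * cluster_size
  cl <- rep(seq_len(n_clusters), each = cluster_size)
  if (is.null(X)) X <- cbind(x = rnorm(n))
  u <- rnorm(n_clusters, 0, sigma)
  eta <- as.vector(X %*% beta) + u[cl]
  K <- length(zeta) + 1L
  cum_le <- plogis(outer(-eta, zeta, "+"))        # P(Y <= k)
  r <- runif(n)
  y <- rowSums(r > cum_le)                        # 0..K-1
  list(y = as.integer(y), X = X, cluster = cl)
}
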