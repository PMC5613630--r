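#' Item characteristic function (expected score curve)
#'
#' For a graded item with categories `0..K-1`, the ICF is the expected score
#' `E[X | theta] = sum_x x p_x(theta)`, computed pointwise from
#' [category_probabilities()]. A positive `dif_offset` (uniform DIF against
#' the focal group) lowers the whole curve. Useful for visualising DIF by
#' overlaying group-specific curves.
#'
#' @param a positive discrimination.
#' @param thresholds strictly increasing thresholds.
#' @param dif_offset uniform threshold shift (default 0).
#' @param theta_grid evaluation grid (default `seq(-4, 4, by = 0.05)`).
#' @return data frame of class `icf_curve`: `theta`, `expected_score`; the
#'   category probability matrix is attached as attribute `probabilities`.
#' @examples
#' icf(1, c(-1, 0, 1, 2), theta_grid = 0)
#' @export
icf <- function(a, thresholds, dif_offset = 0,
                theta_grid = seq(-4, 4, by = 0.05)) {
  p <- category_probabilities(theta_grid, a, thresholds, dif_offset)
  K <- ncol(p)
  es <- as.numeric(p %*% (0:(K - 1)))
  out <- data.frame(theta = theta_grid, expected_score = es)
  attr(out, "probabilities") <- p
  attr(out, "dif_offset") <- dif_offset
  class(out) <- c("icf_curve", "data.frame")
  out
}

#' @export
plot.icf_curve <- function(x, ..., add = FALSE, lty = 1) {
  if (add) graphics::lines(x$theta, x$expected_score, lty = lty, ...)
  else plot(x$theta, x$expected_score, type = "l", lty = lty,
            xlab = expression(theta), ylab = "expected item score", ...)
  invisible(x)
}

#' Ordinal intraclass correlation of one item
#'
#' Fits the intercept-only random-intercept cumulative-logit model with
#' [fit_holr()] and reports the latent-scale intraclass correlation
#' `sigma_u^2 / (sigma_u^2 + pi^2 / 3)` (logistic residual variance
#' `pi^2/3`). Used to screen items for whether a hierarchical analysis is
#' warranted.
#'
#' @param y ordinal item responses.
#' @param cluster cluster identifiers (>= 2 clusters).
#' @param nodes quadrature nodes.
#' @return list: `icc`, `sigma_u2`, `boundary` (TRUE when the variance
#'   estimate was pinned at zero), `fit` (the `holr_fit`).
#' @export
icc_ordinal <- function(y, cluster, nodes = 15L) {
  fit <- fit_holr(y, NULL, cluster, nodes = nodes, se = FALSE)
  list(icc = fit$sigma_u2 / (fit$sigma_u2 + pi^2 / 3),
       sigma_u2 = fit$sigma_u2, boundary = isTRUE(fit$boundary), fit = fit)
}

#' Design effect of cluster sampling
#'
#' Variance inflation from sampling clusters of average size `m` with
#' intraclass correlation `icc`: `1 + (m - 1) * icc`. Values above 2 are the
#' conventional signal that a multilevel analysis is needed.
#'
#' @param icc intraclass correlation in `[0, 1]`.
#' @param m mean cluster size (>= 1).
#' @return numeric design effect.
#' @examples
#' design_effect(0.05, 36)
#' @export
design_effect <- function(icc, m) {
  if (any(icc < 0 | icc > 1)) stop("'icc' must be in [0, 1]")
  if (any(m < 1)) stop("'m' must be >= 1")
  1 + (m - 1) * icc
}

#' Per-item screening table: ICC and design effect
#'
#' Runs [icc_ordinal()] and [design_effect()] on every item of a dataset —
#' the pre-analysis check for whether the hierarchical (HOLR) DIF tests are
#' needed. A design effect above `deff_threshold` recommends HOLR.
#'
#' @param data a `dif_data` data frame.
#' @param cluster cluster-id column name.
#' @param items item columns.
#' @param nodes quadrature nodes.
#' @param deff_threshold design-effect cutoff for the recommendation flag
#'   (default 2, the conventional rule of thumb).
#' @return data frame: `item`, `icc`, `sigma_u2`, `design_effect`,
#'   `needs_multilevel`.
#' @export
screen_clustering <- function(data, cluster = "cluster_id",
                              items = dif_items(data), nodes = 15L,
                              deff_threshold = 2) {
  cl <- data[[cluster]]
  m <- mean(table(cl))
  rows <- lapply(items, function(it) {
    r <- icc_ordinal(data[[it]], cl, nodes = nodes)
    de <- design_effect(r$icc, m)
    data.frame(item = it, icc = r$icc, sigma_u2 = r$sigma_u2,
               design_effect = de, needs_multilevel = de > deff_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
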