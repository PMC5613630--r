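#' Sample a graded-response item bank
#'
#' Draws item parameters for a simulated instrument of `n_items` polytomous
#' items with `n_categories` ordered response categories: one discrimination
#' per item, uniform on `disc_range`, and `n_categories - 1` ordered category
#' thresholds per item, i.i.d. uniform on `threshold_range` then sorted
#' ascending (ties re-drawn). One *studied* item may carry uniform DIF: for
#' focal-group respondents `dif_magnitude` is added to all of its thresholds,
#' shifting the whole item towards lower categories for the focal group.
#'
#' @param n_items number of items (default 16: 15 DIF-free core items plus
#'   one studied item).
#' @param disc_range length-2 numeric, lower/upper bound of the uniform
#'   distribution for discriminations. `c(0.5, 0.99)` and `c(1.5, 2)` are the
#'   conventional "low" and "high" ranges.
#' @param threshold_range length-2 numeric bounds for the threshold draws.
#' @param n_categories number of ordered response categories K (scores
#'   `0 .. K-1`), at least 2.
#' @param studied_item index of the item receiving DIF (default: last item).
#' @param dif_magnitude nonnegative shift added to every threshold of the
#'   studied item for focal-group respondents (0 = no DIF).
#' @param dif_target whether the focal group is defined at the person level
#'   (`"focal_persons"`) or the cluster level (`"focal_clusters"`).
#' @return an object of class `item_bank`: list with `discrimination`
#'   (length `n_items`), `thresholds` (`n_items` x `K-1` matrix, rows strictly
#'   increasing), `n_categories`, `studied_item`, `dif_magnitude`,
#'   `dif_target`.
#' @examples
#' set.seed(1)
#' bank <- sample_item_bank(16, c(0.5, 0.99), c(-2.5, 2.5), 5)
#' range(bank$discrimination)
#' @export
sample_item_bank <- function(n_items = 16L,
                             disc_range = c(0.5, 0.99),
                             threshold_range = c(-2.5, 2.5),
                             n_categories = 5L,
                             studied_item = n_items,
                             dif_magnitude = 0,
                             dif_target = c("focal_persons", "focal_clusters")) {
  dif_target <- match.arg(dif_target)
  if (length(disc_range) != 2L || disc_range[1] >= disc_range[2])
    stop("'disc_range' must be c(lo, hi) with lo < hi")
  if (disc_range[1] <= 0)
    stop("discriminations must be positive: disc_range[1] > 0 required")
  if (length(threshold_range) != 2L || threshold_range[1] >= threshold_range[2])
    stop("'threshold_range' must be c(lo, hi) with lo < hi")
  if (n_categories < 2L) stop("'n_categories' must be at least 2")
  if (n_items < 1L) stop("'n_items' must be at least 1")
  if (studied_item < 1L || studied_item > n_items)
    stop("'studied_item' out of range")
  if (dif_magnitude < 0) stop("'dif_magnitude' must be >= 0")

  a <- stats::runif(n_items, disc_range[1], disc_range[2])
  K <- as.integer(n_categories)
  thr <- matrix(NA_real_, n_items, K - 1L)
  for (j in seq_len(n_items)) {
    b <- sort(stats::runif(K - 1L, threshold_range[1], threshold_range[2]))
    while (K > 2L && any(diff(b) <= 0))  # ties have probability 0; guard anyway
      b <- sort(stats::runif(K - 1L, threshold_range[1], threshold_range[2]))
    thr[j, ] <- b
  }
  structure(list(discrimination = a, thresholds = thr,
                 n_categories = K, studied_item = as.integer(studied_item),
                 dif_magnitude = dif_magnitude, dif_target = dif_target),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Graded-response item bank: %d items, %d categories\n",
              length(x$discrimination), x$n_categories))
  cat(sprintf("  discrimination range: [%.3f, %.3f]\n",
              min(x$discrimination), max(x$discrimination)))
  cat(sprintf("  studied item: %d (DIF magnitude %.2f, target %s)\n",
              x$studied_item, x$dif_magnitude, x$dif_target))
  invisible(x)
}

#' Sample two-level latent abilities
#'
#' Draws person abilities from a two-level normal linear mixed model:
#' `theta_ij = u_j + e_ij` with `u_j ~ N(0, icc)` and
#' `e_ij ~ N(0, 1 - icc)`, so the marginal variance is 1 and the intraclass
#' correlation (share of latent variance between clusters) is `icc`.
#'
#' @param n_clusters number of level-2 units (e.g. schools).
#' @param cluster_size persons per cluster (balanced).
#' @param icc intraclass correlation in `[0, 1)`.
#' @return an object of class `ability_sample`: list with `theta` (length
#'   `n_clusters * cluster_size`), `cluster_id` (integer, same length),
#'   `cluster_effect` (length `n_clusters`), `icc`.
#' @export
sample_abilities <- function(n_clusters, cluster_size, icc) {
  if (icc < 0 || icc >= 1) stop("'icc' must be in [0, 1)")
  if (n_clusters < 1L || cluster_size < 1L)
    stop("'n_clusters' and 'cluster_size' must be >= 1")
  u <- stats::rnorm(n_clusters, 0, sqrt(icc))
  cluster_id <- rep(seq_len(n_clusters), each = cluster_size)
  e <- stats::rnorm(n_clusters * cluster_size, 0, sqrt(1 - icc))
  structure(list(theta = u[cluster_id] + e, cluster_id = cluster_id,
                 cluster_effect = u, icc = icc),
            class = "ability_sample")
}

#' Assign balanced focal/reference group labels
#'
#' Builds a dichotomous grouping variable at the person level (`"within"`,
#' e.g. gender) or at the cluster level (`"between"`: exactly half of the
#' clusters are focal and the label is constant within cluster, e.g. type of
#' school). The design is balanced: exactly half of all persons are focal.
#' For `"within"` with an even `cluster_size` every cluster is split half and
#' half; with an odd `cluster_size` exact per-cluster balance is impossible,
#' so a randomly chosen half of the clusters carries the extra focal person
#' (requires an even `n_clusters`), keeping the totals exactly balanced.
#'
#' @param n_clusters,cluster_size design dimensions.
#' @param level `"within"` or `"between"`.
#' @return integer vector of 0 (reference) / 1 (focal) of length
#'   `n_clusters * cluster_size`, ordered by cluster.
#' @export
assign_groups <- function(n_clusters, cluster_size,
                          level = c("within", "between")) {
  level <- match.arg(level)
  if (level == "within") {
    if (cluster_size %% 2L == 0L) {
      n_focal <- rep(cluster_size / 2L, n_clusters)
    } else {
      if (n_clusters %% 2L != 0L)
        stop("balanced design with odd 'cluster_size' needs an even ",
             "'n_clusters'")
      n_focal <- sample(rep(c((cluster_size + 1L) %/% 2L,
                              (cluster_size - 1L) %/% 2L),
                            n_clusters / 2L))
    }
    g <- unlist(lapply(seq_len(n_clusters), function(j)
      sample(rep(c(1L, 0L), c(n_focal[j], cluster_size - n_focal[j])))),
      use.names = FALSE)
  } else {
    if (n_clusters %% 2L != 0L)
      stop("between-cluster balanced design needs an even 'n_clusters'")
    focal <- sample(rep(c(0L, 1L), n_clusters / 2L))
    g <- rep(focal, each = cluster_size)
  }
  g
}

#' Graded-response category probabilities
#'
#' Cumulative-logit graded response model: for thresholds `b_1 < ... <
#' b_{K-1}` and discrimination `a`,
#' `P(Y >= k | theta) = plogis(a * (theta - (b_k + dif_offset)))`, and the
#' probability of scoring exactly `k` is the adjacent difference.
#'
#' @param theta numeric vector of abilities.
#' @param a positive discrimination.
#' @param thresholds strictly increasing numeric vector (length K-1).
#' @param dif_offset location shift added to every threshold (uniform DIF).
#' @return `length(theta) x K` matrix of category probabilities, columns
#'   `0 .. K-1`, rows summing to 1.
#' @examples
#' category_probabilities(0, 1, c(-1, 0, 1, 2))
#' @export
category_probabilities <- function(theta, a, thresholds, dif_offset = 0) {
  if (a <= 0) stop("'a' must be positive")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing")
  cum <- cumulative_ge(theta, a, thresholds, dif_offset)  # P(Y >= k), k=1..K-1
  K <- length(thresholds) + 1L
  p <- cbind(1 - cum[, 1L, drop = FALSE],
             if (K > 2L) cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE],
             cum[, ncol(cum), drop = FALSE])
  colnames(p) <- as.character(0:(K - 1L))
  p
}

# P(Y >= k), k = 1..K-1, as an n x (K-1) matrix
cumulative_ge <- function(theta, a, thresholds, dif_offset = 0) {
  m <- vapply(thresholds + dif_offset,
              function(b) stats::plogis(a * (theta - b)),
              numeric(length(theta)))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(theta))
  m
}

#' Generate polytomous item responses from the multilevel GRM
#'
#' Draws one response per person per item from [category_probabilities()].
#' Focal respondents (person label for `level = "within"`, cluster label for
#' `level = "between"`) receive the bank's `dif_magnitude` as a threshold
#' shift on the studied item only; core items and reference respondents are
#' untouched.
#'
#' @param ability an [sample_abilities()] result (or list with `theta`,
#'   `cluster_id`).
#' @param bank an [sample_item_bank()] result.
#' @param groups 0/1 vector from [assign_groups()].
#' @param level `"within"` or `"between"` (how `groups` was assigned; kept as
#'   metadata and validated for between: label constant per cluster).
#' @return a `dif_data` data frame: columns `person_id`, `cluster_id`,
#'   `group`, then `item_1 .. item_J` with integer scores `0 .. K-1`.
#'   Attributes: `items` (item column names), `level`, `n_categories`,
#'   `bank`, `theta` (true abilities).
#' @export
generate_responses <- function(ability, bank, groups,
                               level = c("within", "between")) {
  level <- match.arg(level)
  theta <- ability$theta
  n <- length(theta)
  if (length(groups) != n) stop("'groups' and 'ability' sizes differ")
  if (length(ability$cluster_id) != n) stop("malformed 'ability'")
  if (level == "between" &&
      any(stats::ave(groups, ability$cluster_id, FUN = stats::var) > 0,
          na.rm = TRUE))
    stop("level = 'between' requires the group label constant within cluster")

  J <- length(bank$discrimination)
  K <- bank$n_categories
  y <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    off <- if (j == bank$studied_item) bank$dif_magnitude * groups else 0
    cum <- cumulative_ge(theta, bank$discrimination[j], bank$thresholds[j, ],
                         0)
    if (j == bank$studied_item && bank$dif_magnitude > 0) {
      # focal rows get shifted thresholds
      foc <- groups == 1L
      if (any(foc))
        cum[foc, ] <- cumulative_ge(theta[foc], bank$discrimination[j],
                                    bank$thresholds[j, ], bank$dif_magnitude)
    }
    u <- stats::runif(n)
    # inverse CDF from the top: score = number of exceeded cumulative probs
    y[, j] <- as.integer(rowSums(u <= cum))
  }
  colnames(y) <- paste0("item_", seq_len(J))
  out <- data.frame(person_id = seq_len(n), cluster_id = ability$cluster_id,
                    group = as.integer(groups), y)
  structure(out,
            items = colnames(y), level = level, n_categories = K,
            bank = bank, theta = theta,
            class = c("dif_data", "data.frame"))
}

#' Item columns of a DIF dataset
#' @param data a `dif_data` object or plain data frame.
#' @return character vector of item column names.
#' @export
dif_items <- function(data) {
  it <- attr(data, "items")
  if (is.null(it)) it <- grep("^item_", names(data), value = TRUE)
  if (length(it) == 0L) stop("no item columns found")
  it
}

#' Simulate one multilevel DIF dataset
#'
#' Convenience wrapper chaining [sample_item_bank()], [sample_abilities()],
#' [assign_groups()] and [generate_responses()] — one replication of one
#' simulation condition.
#'
#' @param n_clusters,cluster_size,icc design of the two-level sample.
#' @param dif uniform DIF magnitude for the studied item (0, 0.4 or 0.8 in
#'   the factorial study).
#' @param level `"within"` or `"between"` grouping variable.
#' @param disc `"low"` (U(0.5, 0.99)), `"high"` (U(1.5, 2)), or a numeric
#'   length-2 range.
#' @param n_items,n_categories instrument dimensions.
#' @param seed optional integer; if given, `set.seed(seed)` first.
#' @return a `dif_data` object (see [generate_responses()]).
#' @examples
#' d <- simulate_dif_data(50, 5, icc = 0.05, dif = 0.4, level = "within",
#'                        disc = "low", seed = 7)
#' dim(d)
#' @export
simulate_dif_data <- function(n_clusters, cluster_size, icc, dif,
                              level = c("within", "between"),
                              disc = c("low", "high"),
                              n_items = 16L, n_categories = 5L,
                              seed = NULL) {
  level <- match.arg(level)
  if (is.character(disc)) {
    disc <- match.arg(disc)
    disc_range <- if (disc == "low") c(0.5, 0.99) else c(1.5, 2)
  } else disc_range <- disc
  if (!is.null(seed)) set.seed(as.integer(seed))
  bank <- sample_item_bank(n_items, disc_range, c(-2.5, 2.5), n_categories,
                           studied_item = n_items, dif_magnitude = dif,
                           dif_target = if (level == "within")
                             "focal_persons" else "focal_clusters")
  ab <- sample_abilities(n_clusters, cluster_size, icc)
  g <- assign_groups(n_clusters, cluster_size, level)
  generate_responses(ab, bank, g, level)
}
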