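# Bias-corrected and accelerated (BCa) nonparametric bootstrap intervals
# and the cluster-specificity decision rule built on them.

#' BCa bootstrap confidence interval
#'
#' Nonparametric bootstrap of `statistic` over `B` resamples with
#' replacement. The bias correction is
#' `z0 = qnorm(#\{theta*_b < theta_hat\} / B)` with ties
#' (`theta*_b == theta_hat`) counting half; the acceleration comes from
#' the leave-one-out jackknife,
#' `a = sum(d_i^3) / (6 * sum(d_i^2)^{3/2})` with
#' `d_i = mean(theta_(.)) - theta_(i)`. Adjusted percentile levels are
#' `alpha_1 = pnorm(z0 + (z0 + z_{a/2}) / (1 - a (z0 + z_{a/2})))` and
#' analogously for the upper tail; the interval endpoints are the
#' type-7 empirical quantiles of the bootstrap distribution at those
#' levels. When all values are equal or the jackknife variance is 0 the
#' degenerate interval `[theta_hat, theta_hat]` is returned. If every
#' bootstrap replicate falls on one side of the estimate the proportion
#' is clamped to `1/(2B)` from the boundary so z0 stays finite.
#'
#' @param values Numeric vector, length >= 2.
#' @param B Number of bootstrap replications (default 10000).
#' @param alpha Two-sided miscoverage; 0.05 gives the 2.5 and 97.5
#'   percentiles.
#' @param statistic Function of a numeric vector (default `mean`;
#'   `mean` is special-cased for a vectorized fast path).
#' @param seed Integer seed for the resampling.
#' @return Object of class `bca_interval`: `estimate`, `lower`, `upper`,
#'   `z0`, `a`, `B`, `alpha`, `degenerate`.
#' @export
bca_interval <- function(values, B = 10000, alpha = 0.05,
                         statistic = mean, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("bca_interval: need at least 2 values")
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  theta_hat <- statistic(values)
  is_mean <- identical(statistic, mean)

  # jackknife acceleration
  theta_jack <- if (is_mean) (sum(values) - values) / (n - 1)
  else vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  d <- mean(theta_jack) - theta_jack
  denom <- sum(d^2)
  if (all(values == values[1L]) || denom == 0) {
    return(structure(list(estimate = theta_hat, lower = theta_hat,
                          upper = theta_hat, z0 = 0, a = 0, B = B,
                          alpha = alpha, degenerate = TRUE),
                     class = "bca_interval"))
  }
  a <- sum(d^3) / (6 * denom^1.5)

  boot_stats <- with_seed(seed, {
    if (is_mean) {
      colMeans(matrix(sample(values, n * B, replace = TRUE), n, B))
    } else {
      vapply(seq_len(B), function(b)
        statistic(sample(values, n, replace = TRUE)), numeric(1))
    }
  })

  prop <- (sum(boot_stats < theta_hat) +
             0.5 * sum(boot_stats == theta_hat)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  zlo <- stats::qnorm(alpha / 2)
  zhi <- stats::qnorm(1 - alpha / 2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  q <- stats::quantile(boot_stats, probs = c(adj(zlo), adj(zhi)),
                       names = FALSE, type = 7)
  structure(list(estimate = theta_hat, lower = q[1L], upper = q[2L],
                 z0 = z0, a = a, B = B, alpha = alpha,
                 degenerate = FALSE),
            class = "bca_interval")
}

#' @export
print.bca_interval <- function(x, ...) {
  cat(sprintf(
    "BCa %.0f%% interval: [%.4g, %.4g] (estimate %.4g, z0 %.3f, a %.3f%s)\n",
    100 * (1 - x$alpha), x$lower, x$upper, x$estimate, x$z0, x$a,
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Cluster-specificity calls for a gene list
#'
#' For each gene and each experiment cluster, a BCa interval of the mean
#' log2FC across the cluster's experiments is computed (the experiment
#' is the resampled unit). The gene is flagged as behaving specifically
#' in that cluster when the global mean -- the mean log2FC of all the
#' supplied genes over all experiments -- falls outside the interval;
#' the direction records whether the cluster sits above or below the
#' global mean. With few experiments per cluster the BCa interval is
#' crude; that is a property of the design, not corrected here.
#'
#' @param matrix A `deg_matrix`.
#' @param genes Character vector of gene ids, or the data frame from
#'   [top_contributing_genes()].
#' @param clusters A [cluster_experiments()] result.
#' @param B Bootstrap replications per gene x cluster (default 10000).
#' @param alpha Two-sided miscoverage (default 0.05).
#' @param seed Integer root seed; each gene x cluster uses a distinct
#'   deterministic sub-seed.
#' @return Data frame with one row per gene x cluster: `gene_id`,
#'   `cluster`, `estimate`, `lower`, `upper`, `z0`, `a`, `degenerate`,
#'   `global_mean`, `flagged`, `direction` ("above"/"below"/"none").
#' @export
cluster_specificity <- function(matrix, genes, clusters, B = 10000,
                                alpha = 0.05, seed = 1L) {
  stopifnot(inherits(matrix, "deg_matrix"),
            inherits(clusters, "cluster_assignment"))
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- as.character(genes)
  missing_g <- setdiff(genes, matrix$genes)
  if (length(missing_g))
    stop("cluster_specificity: gene(s) not in matrix: ",
         paste(utils::head(missing_g, 5L), collapse = ", "))
  labels <- sort(unique(clusters$assignment))
  exps_of <- lapply(labels, function(cl)
    names(clusters$assignment)[clusters$assignment == cl])
  names(exps_of) <- labels
  small <- labels[vapply(exps_of, length, integer(1)) < 2]
  if (length(small))
    stop("cluster_specificity: cluster(s) with fewer than 2 experiments: ",
         paste(small, collapse = ", "))
  global_mean <- mean(matrix$lfc[genes, , drop = FALSE])
  rows <- vector("list", length(genes) * length(labels))
  i <- 0L
  for (ci in seq_along(labels)) {
    cl <- labels[ci]
    cols <- exps_of[[cl]]
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      vals <- matrix$lfc[g, cols]
      sub_seed <- stage_seed(seed, sprintf("specificity/%s/%s", cl, g))
      iv <- bca_interval(vals, B = B, alpha = alpha, seed = sub_seed)
      flagged <- global_mean < iv$lower || global_mean > iv$upper
      i <- i + 1L
      rows[[i]] <- data.frame(
        gene_id = g, cluster = cl, estimate = iv$estimate,
        lower = iv$lower, upper = iv$upper, z0 = iv$z0, a = iv$a,
        degenerate = iv$degenerate, global_mean = global_mean,
        flagged = flagged,
        direction = if (!flagged) "none"
                    else if (global_mean < iv$lower) "above" else "below",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
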