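# Independent oracles used to cross-check the package implementation.
# All are deliberately naive (brute force / textbook formulas) and share
# no code with the functions they verify.

# textbook Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# per-element membership-signature tally of a named list of sets
oracle_venn_counts <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  counts <- integer(0)
  for (el in universe) {
    sig <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                    logical(1))], collapse = "&")
    counts[sig] <- (if (is.na(counts[sig])) 0L else counts[sig]) + 1L
  }
  counts
}

# --- graphs as adjacency matrices (rows/cols named) -----------------------

adj_from_ppi <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$node_a[i], net$edges$node_b[i]] <- TRUE
    A[net$edges$node_b[i], net$edges$node_a[i]] <- TRUE
  }
  A
}

# hand-coded BFS distances from one vertex over an adjacency matrix
oracle_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); names(d) <- rownames(A)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      nb <- rownames(A)[A[u, ]]
      new <- nb[is.infinite(d[nb])]
      d[new] <- d[u] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# exhaustive enumeration of all shortest paths between two vertices
oracle_all_shortest_paths <- function(A, s, t) {
  d <- oracle_bfs(A, s)
  if (is.infinite(d[t])) return(list())
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) { paths[[length(paths) + 1L]] <<- path; return() }
    for (v in rownames(A)[A[u, ]])
      if (d[v] == d[u] + 1) walk(c(path, v))
  }
  walk(s)
  paths
}

# betweenness by explicit path enumeration over unordered pairs
oracle_betweenness <- function(A) {
  nodes <- rownames(A)
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- oracle_all_shortest_paths(A, nodes[i], nodes[j])
    if (!length(paths)) next
    for (p in paths) {
      interior <- p[-c(1L, length(p))]
      if (length(interior))
        btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw
}

# is the induced subgraph on `keep` connected (covering all of `keep`)?
oracle_connected <- function(A, keep) {
  if (length(keep) <= 1L) return(TRUE)
  B <- A[keep, keep, drop = FALSE]
  reach <- oracle_bfs(B, keep[1L])
  all(is.finite(reach))
}

# exact minimum Steiner tree size (edges) by exhaustive enumeration of
# optional-node subsets; returns Inf if the seeds cannot be connected
oracle_steiner_edges <- function(A, seeds) {
  optional <- setdiff(rownames(A), seeds)
  best <- Inf
  for (k in 0:length(optional)) {
    if (length(seeds) + k - 1 >= best) break
    subsets <- if (k == 0) list(character(0))
    else utils::combn(optional, k, simplify = FALSE)
    for (x in subsets) {
      keep <- c(seeds, x)
      if (oracle_connected(A, keep)) {
        best <- min(best, length(keep) - 1L)
        break  # any larger subset at this k cannot improve
      }
    }
  }
  best
}

# --- BCa oracle -----------------------------------------------------------

# manual type-7 quantile of a sorted sample
oracle_quantile7 <- function(sorted, p) {
  n <- length(sorted)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
}

# independent BCa implementation: its own resampling loop, explicit
# counting, manual quantiles
oracle_bca <- function(values, B, alpha, seed) {
  n <- length(values)
  theta_hat <- sum(values) / n
  set.seed(seed)
  boot_stats <- numeric(B)
  for (b in seq_len(B))
    boot_stats[b] <- mean(values[sample.int(n, n, replace = TRUE)])
  jack <- numeric(n)
  for (i in seq_len(n)) jack[i] <- mean(values[-i])
  dd <- mean(jack) - jack
  a <- sum(dd^3) / (6 * (sum(dd^2))^1.5)
  less <- sum(boot_stats < theta_hat) + 0.5 * sum(boot_stats == theta_hat)
  z0 <- qnorm(less / B)
  zl <- qnorm(alpha / 2); zu <- qnorm(1 - alpha / 2)
  a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  srt <- sort(boot_stats)
  list(lower = oracle_quantile7(srt, a1),
       upper = oracle_quantile7(srt, a2),
       z0 = z0, a = a, boot_sorted = srt, a1 = a1, a2 = a2,
       percentile = c(oracle_quantile7(srt, alpha / 2),
                      oracle_quantile7(srt, 1 - alpha / 2)))
}

# local spacing of the bootstrap order statistics around a quantile
# level: the resolution at which two independent B-replicate bootstrap
# quantile estimates can be expected to agree
grid_resolution <- function(sorted, p, width = 0.01) {
  lo <- oracle_quantile7(sorted, max(p - width, 0))
  hi <- oracle_quantile7(sorted, min(p + width, 1))
  max(hi - lo, 1e-8)
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# random connected undirected graph as a ppi_network (all edges pass the
# default score filter)
random_connected_ppi <- function(n, p_edge = 0.4) {
  repeat {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p_edge
    if (!any(keep)) next
    net <- ppi_network(data.frame(node_a = pairs[1, keep],
                                  node_b = pairs[2, keep],
                                  combined_score = 999,
                                  experimental_score = 500,
                                  stringsAsFactors = FALSE),
                       nodes = nodes)
    A <- adj_from_ppi(net)
    if (oracle_connected(A, nodes)) return(net)
  }
}

# small deg_matrix straight from an lfc matrix (everything measured,
# DE wherever |lfc| > 1)
matrix_from_lfc <- function(lfc) {
  de <- abs(lfc) > 1
  keep <- rowSums(de) > 0
  lfc <- lfc[keep, , drop = FALSE]
  herbimeta:::new_deg_matrix(lfc, abs(lfc) > 1,
                             matrix(TRUE, nrow(lfc), ncol(lfc),
                                    dimnames = dimnames(lfc)))
}
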