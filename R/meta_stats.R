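# Statistical core: correlation subnetworks, experiment clustering, and
# PCA gene contributions with dimension selection.

#' Pearson correlation graph over a gene set
#'
#' Computes all pairwise Pearson correlations of gene log2FC profiles
#' across experiments (fill-policy cells included) and keeps an edge
#' when `r >= r_min` (signed, the default, so perfectly anti-correlated
#' profiles yield no edge) or `|r| >= r_min` when `signed = FALSE`.
#' Genes with zero variance across experiments produce no edges and are
#' returned in a diagnostics field.
#'
#' @param matrix A `deg_matrix`.
#' @param genes Gene identifiers to correlate (at least 2).
#' @param r_min Correlation threshold (default 0.95).
#' @param signed Use signed r (default) or absolute value.
#' @return Object of class `corr_graph`: list with `genes`, `edges`
#'   (data frame `gene_a`, `gene_b`, `r`), `threshold`, `signed`, and
#'   `zero_variance` diagnostics.
#' @export
correlation_graph <- function(matrix, genes, r_min = 0.95, signed = TRUE) {
  stopifnot(inherits(matrix, "deg_matrix"), length(genes) >= 2)
  genes <- as.character(genes)
  missing_g <- setdiff(genes, matrix$genes)
  if (length(missing_g))
    stop("correlation_graph: gene(s) not in matrix: ",
         paste(utils::head(missing_g, 5L), collapse = ", "))
  m <- matrix$lfc[genes, , drop = FALSE]
  if (ncol(m) < 3)
    stop("correlation_graph: need at least 3 experiments")
  sds <- apply(m, 1L, stats::sd)
  zero_var <- genes[sds == 0]
  r <- suppressWarnings(stats::cor(t(m)))
  r[is.na(r)] <- 0  # zero-variance genes: no edges
  ut <- upper.tri(r)
  hit <- if (signed) r >= r_min else abs(r) >= r_min
  idx <- which(ut & hit, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                      r = r[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges, threshold = r_min,
                 signed = signed, zero_variance = zero_var),
            class = "corr_graph")
}

#' @export
print.corr_graph <- function(x, ...) {
  cat(sprintf("corr_graph: %d genes, %d edges at r >= %g (%s)\n",
              length(x$genes), nrow(x$edges), x$threshold,
              if (x$signed) "signed" else "absolute"))
  invisible(x)
}

#' Correlated genes and fully connected subnetworks
#'
#' From a thresholded correlation graph: `connected_genes` are all genes
#' with at least one edge (the "any correlation" set); the reported
#' coexpression module is the union of *fully connected* subnetworks,
#' i.e. connected components of size >= 2 in which every pair of members
#' is adjacent (components that are cliques). A component where two
#' members lack a direct edge is not fully connected and contributes no
#' module genes. Set `components_only = TRUE` to treat every connected
#' component (clique or not) as a module.
#'
#' @param graph A [correlation_graph()] result.
#' @param components_only Relax the clique requirement (default FALSE).
#' @return List with `connected_genes` (character) and
#'   `clique_components` (list of character vectors, largest first).
#' @export
fully_connected_subnetworks <- function(graph, components_only = FALSE) {
  stopifnot(inherits(graph, "corr_graph"))
  e <- graph$edges
  if (nrow(e) == 0L)
    return(list(connected_genes = character(0),
                clique_components = list()))
  g <- igraph::graph_from_data_frame(e[c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  if (!components_only) {
    is_clique <- vapply(members, function(v) {
      sub <- igraph::induced_subgraph(g, v)
      igraph::ecount(sub) == length(v) * (length(v) - 1) / 2
    }, logical(1))
    members <- members[is_clique]
  }
  members <- members[order(-vapply(members, length, integer(1)),
                           vapply(members, `[`, character(1), 1L))]
  list(connected_genes = sort(names(comp$membership)),
       clique_components = unname(members))
}

#' Hierarchical clustering of experiments
#'
#' Agglomerative clustering of the experiment column vectors of the
#' log2FC matrix using Euclidean distance and Ward's linkage
#' (variance-minimizing `ward.D2` update), cut into `k` clusters.
#' Deterministic given the matrix; `hclust` breaks merge ties by input
#' order.
#'
#' @param matrix A `deg_matrix`.
#' @param k Number of clusters (default 4, the depth chosen for the
#'   herbivore collection).
#' @return Object of class `cluster_assignment`: list with `assignment`
#'   (named vector experiment -> "cluster<i>" label), `k`, `linkage`,
#'   `metric` and the `hclust` merge history.
#' @export
cluster_experiments <- function(matrix, k = 4) {
  stopifnot(inherits(matrix, "deg_matrix"))
  n_exp <- length(matrix$experiments)
  if (k < 1) stop("cluster_experiments: k must be >= 1")
  if (k > n_exp)
    stop("cluster_experiments: k (", k, ") exceeds number of experiments (",
         n_exp, ")")
  d <- stats::dist(t(matrix$lfc), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  assignment <- stats::setNames(paste0("cluster", raw), names(raw))
  structure(list(assignment = assignment, k = k, linkage = "ward.D2",
                 metric = "euclidean", hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d experiments in %d clusters (%s/%s)\n",
              length(x$assignment), x$k, x$metric, x$linkage))
  print(table(x$assignment))
  invisible(x)
}

#' PCA of genes with experiments as variables
#'
#' Principal component analysis of the genes x experiments log2FC matrix
#' with experiments as variables: columns are centered (and scaled to
#' unit variance only when `scale = TRUE`; the default is
#' covariance-based). Gene contributions to dimension d are
#' `ctr[g, d] = 100 * score[g, d]^2 / sum_h score[h, d]^2`, the standard
#' contribution measure of PCA biplot tooling; experiment contributions
#' are analogous on the loadings. Eigenvalues are the variances of the
#' scores.
#'
#' @param matrix A `deg_matrix`.
#' @param scale Standardize experiments to unit variance (default
#'   FALSE).
#' @return Object of class `pca_result`: `eigenvalues`, `scores`
#'   (genes x dims), `loadings` (experiments x dims),
#'   `gene_contributions` and `experiment_contributions` (percent),
#'   `center`/`scale` flags.
#' @export
pca_contributions <- function(matrix, scale = FALSE) {
  stopifnot(inherits(matrix, "deg_matrix"))
  X <- matrix$lfc
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("pca_contributions: need at least 2 genes and 2 experiments")
  if (scale) {
    csd <- apply(X, 2L, stats::sd)
    if (any(csd == 0))
      stop("pca_contributions: constant experiment column(s) with scale=TRUE: ",
           paste(colnames(X)[csd == 0], collapse = ", "))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale)
  lambda <- p$sdev^2
  scores <- p$x
  loadings <- p$rotation
  ctr_g <- sweep(scores^2, 2L, colSums(scores^2), "/") * 100
  ctr_e <- sweep(loadings^2, 2L, colSums(loadings^2), "/") * 100
  structure(list(eigenvalues = lambda, scores = scores,
                 loadings = loadings, gene_contributions = ctr_g,
                 experiment_contributions = ctr_e,
                 center = TRUE, scale = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  frac <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("pca_result: %d genes x %d dims; top dims explain %s\n",
              nrow(x$scores), length(x$eigenvalues),
              paste(sprintf("%.1f%%", 100 * frac[seq_len(min(3,
                    length(frac)))]), collapse = ", ")))
  invisible(x)
}

#' Select the informative PCA dimensions
#'
#' Returns dimensions 1..D where D is the smallest depth whose
#' cumulative variance fraction exceeds `var_threshold`; the scree-plot
#' inflection (the index maximizing the second difference of the
#' eigenvalue sequence) is reported as a diagnostic, and when it lies
#' deeper than D the deeper of the two is used. This mirrors the
#' combined ">70% of total variation plus scree inflection" selection
#' rule.
#'
#' @param result A [pca_contributions()] result.
#' @param var_threshold Cumulative variance fraction to exceed
#'   (default 0.70).
#' @return List with `dims` (integer vector 1..D), `d_variance`,
#'   `inflection` and `cumulative_fraction`.
#' @export
select_dimensions <- function(result, var_threshold = 0.70) {
  stopifnot(inherits(result, "pca_result"),
            var_threshold > 0, var_threshold < 1)
  lambda <- result$eigenvalues
  cumfrac <- cumsum(lambda) / sum(lambda)
  d_var <- which(cumfrac > var_threshold)[1L]
  if (is.na(d_var)) d_var <- length(lambda)
  inflection <- if (length(lambda) >= 3L) {
    d2 <- diff(diff(lambda))  # lambda[d-1] - 2 lambda[d] + lambda[d+1]
    which.max(d2) + 1L
  } else 1L
  d_final <- max(d_var, inflection)
  list(dims = seq_len(d_final), d_variance = d_var,
       inflection = inflection, cumulative_fraction = cumfrac)
}

#' Rank genes by contribution to selected dimensions
#'
#' The multi-dimension contribution of a gene is the eigenvalue-weighted
#' mean of its per-dimension contributions over `dims`:
#' `sum_d ctr[g, d] * lambda_d / sum_d lambda_d` -- the convention of
#' standard contribution-plot tooling. Ties are broken lexicographically
#' by gene identifier.
#'
#' @param result A [pca_contributions()] result.
#' @param dims Integer vector of dimensions (non-empty).
#' @param n Number of genes to return (default 100).
#' @return Data frame `gene_id`, `contribution`, sorted descending.
#' @export
top_contributing_genes <- function(result, dims, n = 100) {
  stopifnot(inherits(result, "pca_result"), length(dims) >= 1)
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1), all(dims <= length(result$eigenvalues)))
  ctr <- result$gene_contributions[, dims, drop = FALSE]
  lambda <- result$eigenvalues[dims]
  score <- as.numeric(ctr %*% lambda) / sum(lambda)
  genes <- rownames(result$scores)
  if (n > length(genes))
    stop("top_contributing_genes: n exceeds number of genes")
  ord <- order(-score, genes)
  out <- data.frame(gene_id = genes[ord], contribution = score[ord],
                    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
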