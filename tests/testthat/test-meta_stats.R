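test_that("correlation_graph thresholds signed Pearson r", {
  base <- c(0, 1, 2, 3, 2, 1, 0, 4)
  lfc <- rbind(g1 = base + 2, g2 = 2 * base + 2, g3 = -base + 2,
               g4 = c(2, 2, 2, 2, 2, 2, 2, 2.0001))
  colnames(lfc) <- sprintf("e%d", 1:8)
  m <- matrix_from_lfc(lfc)
  g <- correlation_graph(m, rownames(lfc), r_min = 0.95)
  # identical (affine) profiles correlate at exactly 1
  expect_equal(g$edges[g$edges$gene_a == "g1" &
                         g$edges$gene_b == "g2", "r"], 1)
  # perfect anti-correlation yields no signed edge ...
  expect_false(any(g$edges$gene_a == "g3" | g$edges$gene_b == "g3"))
  # ... but an absolute-value edge
  ga <- correlation_graph(m, rownames(lfc), r_min = 0.95, signed = FALSE)
  expect_true(any((ga$edges$gene_a == "g1" & ga$edges$gene_b == "g3")))
  expect_error(correlation_graph(m, c("g1", "nope")), "nope")
})

test_that("edge set equals a textbook Pearson recomputation on 50 genes", {
  set.seed(31)
  lfc <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("e%02d", 1:12)))
  lfc[1, ] <- 5  # zero-variance row: diagnostics, no edges
  m <- herbimeta:::new_deg_matrix(
    lfc, abs(lfc) > 1, matrix(TRUE, 50, 12, dimnames = dimnames(lfc)))
  r_min <- 0.3  # low threshold so random data yields edges to compare
  g <- correlation_graph(m, rownames(lfc), r_min = r_min)
  expect_equal(g$zero_variance, "g01")
  oracle_edges <- character(0)
  for (i in 1:49) for (j in (i + 1):50) {
    if (i == 1) next
    r <- oracle_pearson(lfc[i, ], lfc[j, ])
    if (r >= r_min)
      oracle_edges <- c(oracle_edges,
                        paste(rownames(lfc)[i], rownames(lfc)[j]))
  }
  expect_setequal(paste(g$edges$gene_a, g$edges$gene_b), oracle_edges)
  for (k in seq_len(min(10, nrow(g$edges))))
    expect_equal(g$edges$r[k],
                 oracle_pearson(lfc[g$edges$gene_a[k], ],
                                lfc[g$edges$gene_b[k], ]))
})

corr_graph_from_pairs <- function(genes, pairs) {
  structure(list(genes = genes,
                 edges = data.frame(gene_a = pairs[, 1],
                                    gene_b = pairs[, 2], r = 0.99,
                                    stringsAsFactors = FALSE),
                 threshold = 0.95, signed = TRUE,
                 zero_variance = character(0)),
            class = "corr_graph")
}

test_that("fully connected subnetworks are clique components", {
  tri <- corr_graph_from_pairs(letters[1:3],
                               cbind(c("a", "a", "b"), c("b", "c", "c")))
  out <- fully_connected_subnetworks(tri)
  expect_equal(out$clique_components, list(c("a", "b", "c")))

  path <- corr_graph_from_pairs(letters[1:3],
                                cbind(c("a", "b"), c("b", "c")))
  outp <- fully_connected_subnetworks(path)
  expect_setequal(outp$connected_genes, c("a", "b", "c"))
  expect_length(outp$clique_components, 0L)
  # the relaxed reading keeps the whole component
  expect_equal(fully_connected_subnetworks(path, components_only = TRUE)
               $clique_components, list(c("a", "b", "c")))

  # property: clique components agree with a brute-force all-pairs
  # adjacency check on random thresholded graphs
  set.seed(7)
  for (rep in 1:15) {
    nodes <- sprintf("n%02d", 1:30)
    pr <- utils::combn(nodes, 2)
    keep <- runif(ncol(pr)) < 0.06
    if (!any(keep)) next
    g <- corr_graph_from_pairs(nodes, t(pr[, keep, drop = FALSE]))
    out <- fully_connected_subnetworks(g)
    adj <- matrix(FALSE, 30, 30, dimnames = list(nodes, nodes))
    for (k in which(keep)) {
      adj[pr[1, k], pr[2, k]] <- TRUE; adj[pr[2, k], pr[1, k]] <- TRUE
    }
    all_comp <- fully_connected_subnetworks(g, components_only = TRUE)
    oracle <- Filter(function(comp)
      all(adj[comp, comp][upper.tri(diag(length(comp)))]),
      all_comp$clique_components)
    expect_setequal(lapply(out$clique_components, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("Ward clustering separates planted groups deterministically", {
  # two groups with identical within-group columns: 2-cut is exact
  lfc <- cbind(e1 = c(5, 5, 0), e2 = c(5, 5, 0),
               e3 = c(0, 0, 5), e4 = c(0, 0, 5))
  rownames(lfc) <- c("g1", "g2", "g3")
  m <- matrix_from_lfc(lfc)
  cl <- cluster_experiments(m, k = 2)
  expect_equal(cl$assignment[["e1"]], cl$assignment[["e2"]])
  expect_equal(cl$assignment[["e3"]], cl$assignment[["e4"]])
  expect_false(cl$assignment[["e1"]] == cl$assignment[["e3"]])
  # k = number of experiments: singletons
  expect_equal(length(unique(cluster_experiments(m, 4)$assignment)), 4L)
  expect_error(cluster_experiments(m, 5), "exceeds")
  expect_error(cluster_experiments(m, 0), ">= 1")

  # planted 4-cluster recovery at effect 4*noise_sd, and invariance of
  # the assignment to gene-row permutation
  spec <- synthetic_spec(n_genes = 400, noise_sd = 0.5,
                         core_module = list(n = 60, mu = 2,
                                            silent_clusters = "cluster1"),
                         cluster_modules = list(
                           cluster2 = list(n = 40, mu = 2),
                           cluster3 = list(n = 40, mu = 2),
                           cluster4 = list(n = 40, mu = 2)))
  sim <- simulate_meta_experiments(spec, seed = 23)
  m4 <- assemble_matrix(sim$tables, sim$manifest)
  cl4 <- cluster_experiments(m4, k = 4)
  expect_equal(oracle_ari(cl4$assignment[m4$experiments],
                          sim$truth$cluster_of[m4$experiments]), 1)
  perm <- sample(length(m4$genes))
  mp <- herbimeta:::new_deg_matrix(m4$lfc[perm, ], m4$de_mask[perm, ],
                                   m4$measured_mask[perm, ])
  expect_identical(cluster_experiments(mp, k = 4)$assignment,
                   cl4$assignment)
})

test_that("PCA matches a direct eigendecomposition and its identities", {
  set.seed(11)
  X <- matrix(rnorm(18), 6, 3,
              dimnames = list(sprintf("g%d", 1:6), c("e1", "e2", "e3")))
  m <- herbimeta:::new_deg_matrix(
    X, abs(X) > 1, matrix(TRUE, 6, 3, dimnames = dimnames(X)))
  p <- pca_contributions(m)
  # oracle: spectral decomposition of the column covariance matrix
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(p$eigenvalues, ev$values, tolerance = 1e-10)
  Xc <- sweep(X, 2, colMeans(X))
  oracle_scores <- Xc %*% ev$vectors
  for (d in 1:3)  # scores match up to the sign of the eigenvector
    expect_equal(abs(unname(p$scores[, d])),
                 abs(unname(oracle_scores[, d])), tolerance = 1e-8)
  # contribution normalization and trace identity
  expect_equal(unname(colSums(p$gene_contributions)), rep(100, 3),
               tolerance = 1e-6)
  expect_equal(unname(colSums(p$experiment_contributions)), rep(100, 3),
               tolerance = 1e-6)
  expect_equal(sum(p$eigenvalues), sum(diag(stats::cov(X))),
               tolerance = 1e-10)
  # orthogonality of score vectors
  gram <- crossprod(p$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # constant column is only an error when standardizing
  Xz <- X; Xz[, 2] <- 1
  mz <- herbimeta:::new_deg_matrix(
    Xz, abs(Xz) > 1, matrix(TRUE, 6, 3, dimnames = dimnames(Xz)))
  expect_error(pca_contributions(mz, scale = TRUE), "e2")
  expect_silent(pca_contributions(mz))
})

fake_pca <- function(lambda)
  structure(list(eigenvalues = lambda), class = "pca_result")

test_that("dimension selection combines variance cut and scree inflection", {
  sel <- select_dimensions(fake_pca(c(5, 3, 1.5, 0.5)),
                           var_threshold = 0.70)
  expect_equal(sel$dims, 1:2)          # cumulative 0.50, 0.80
  expect_equal(sel$inflection, 2L)
  expect_equal(select_dimensions(fake_pca(c(10, 0)))$d_variance, 1L)

  # synthetic 8-dominant spectrum: a matrix whose leading eight
  # dimensions carry the signal selects depth 8
  lambda <- c(50, 20, 12, 9, 7.5, 6.5, 6, 5.8, rep(2, 22))
  n <- 500
  set.seed(5)
  G <- scale(matrix(rnorm(n * 30), n, 30), scale = FALSE)
  sv <- svd(G)
  X <- sv$u %*% diag(sqrt(lambda * (n - 1))) %*% t(sv$v)
  dimnames(X) <- list(sprintf("g%03d", 1:n), sprintf("e%02d", 1:30))
  m <- herbimeta:::new_deg_matrix(
    X, abs(X) > 1, matrix(TRUE, n, 30, dimnames = dimnames(X)))
  p <- pca_contributions(m)
  expect_equal(p$eigenvalues[1:8], lambda[1:8], tolerance = 1e-8)
  sel8 <- select_dimensions(p, var_threshold = 0.70)
  expect_equal(max(sel8$dims), 8L)
})

test_that("top contributing genes use eigenvalue-weighted contributions", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("e%d", 1:6)))
  m <- herbimeta:::new_deg_matrix(
    X, abs(X) > 1, matrix(TRUE, 40, 6, dimnames = dimnames(X)))
  p <- pca_contributions(m)
  # single dimension: ranking equals the per-dimension contribution order
  top1 <- top_contributing_genes(p, dims = 2, n = 10)
  ord <- order(-p$gene_contributions[, 2],
               rownames(p$gene_contributions))
  expect_equal(top1$gene_id, rownames(p$gene_contributions)[ord][1:10])
  # n = all genes is a permutation of the gene list
  all_g <- top_contributing_genes(p, dims = 1:3, n = 40)
  expect_setequal(all_g$gene_id, rownames(X))
  expect_error(top_contributing_genes(p, dims = 1, n = 41), "exceeds")
  # weighted score recomputed by hand for a spot-checked gene
  dims <- 1:3
  w <- p$eigenvalues[dims]
  manual <- sum(p$gene_contributions["g07", dims] * w) / sum(w)
  expect_equal(all_g$contribution[all_g$gene_id == "g07"], manual)
})
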