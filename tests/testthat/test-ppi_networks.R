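ppi_from_pairs <- function(a, b)
  ppi_network(data.frame(node_a = a, node_b = b, combined_score = 999,
                         experimental_score = 500,
                         stringsAsFactors = FALSE))

test_that("minimum connected network keeps only the needed connectors", {
  # star: two leaf seeds are joined through the non-seed centre
  star <- ppi_from_pairs(rep("hub", 4), c("l1", "l2", "l3", "l4"))
  mn <- minimum_connected_network(star, c("l1", "l3"))
  expect_setequal(mn$retained_nodes, c("hub", "l1", "l3"))
  expect_equal(mn$tree_edges, 2L)

  # mutually adjacent seeds need no connectors at all
  tri <- ppi_from_pairs(c("a", "a", "b"), c("b", "c", "c"))
  mn2 <- minimum_connected_network(tri, c("a", "b", "c"))
  expect_setequal(mn2$retained_nodes, c("a", "b", "c"))
  expect_equal(nrow(mn2$subnetwork$edges), 3L)  # induced edges restored

  # absent seeds are dropped and reported; empty seed set refused
  mn3 <- minimum_connected_network(star, c("l1", "ghost"))
  expect_equal(mn3$dropped_seeds, "ghost")
  expect_equal(mn3$retained_nodes, "l1")
  expect_error(minimum_connected_network(star, character(0)), "empty")

  # two components: each contributes its own piece
  two <- ppi_from_pairs(c("a", "x"), c("b", "y"))
  mn4 <- minimum_connected_network(two, c("a", "b", "x"))
  expect_setequal(mn4$retained_nodes, c("a", "b", "x"))
})

test_that("Steiner heuristic is connected, seed-complete and within 2x", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(6:10, 1)
    net <- random_connected_ppi(n, p_edge = 0.35)
    seeds <- sample(net$nodes, sample(2:4, 1))
    mn <- minimum_connected_network(net, seeds)
    A <- adj_from_ppi(net)
    expect_true(all(seeds %in% mn$retained_nodes))
    expect_true(oracle_connected(A, mn$retained_nodes))
    opt <- oracle_steiner_edges(A, seeds)
    expect_lte(mn$tree_edges, 2 * opt)
  }
})

test_that("betweenness and degree match brute-force enumeration", {
  # path a-b-c: only the middle node carries a shortest path
  path <- ppi_from_pairs(c("a", "b"), c("b", "c"))
  st <- node_centralities(path)
  expect_equal(st$betweenness[st$node == "b"], 1)
  expect_equal(st$betweenness[st$node != "b"], c(0, 0))
  # complete graph: all pairs adjacent, all betweenness zero
  k4 <- random_connected_ppi(4, p_edge = 1)
  expect_equal(node_centralities(k4)$betweenness, rep(0, 4))

  set.seed(71)
  for (rep in 1:30) {
    net <- random_connected_ppi(sample(5:8, 1), p_edge = 0.4)
    st <- node_centralities(net)
    oracle <- oracle_betweenness(adj_from_ppi(net))
    expect_equal(stats::setNames(st$betweenness, st$node),
                 oracle[st$node], tolerance = 1e-10)
    expect_equal(sum(st$degree), 2L * nrow(net$edges))
  }
})

test_that("hub ranking uses betweenness, then degree, then name", {
  star <- ppi_from_pairs(rep("hub", 6), paste0("l", 1:6))
  st <- node_centralities(star, seeds = paste0("l", 1:6))
  expect_equal(top_betweenness(st, n = 1)$node, "hub")
  expect_false(top_betweenness(st, n = 1)$is_seed)

  # all-zero betweenness: degree then lexicographic order decides
  k3 <- ppi_from_pairs(c("b", "b", "a"), c("a", "c", "c"))
  st3 <- node_centralities(k3)
  expect_equal(top_betweenness(st3, n = 3)$node, c("a", "b", "c"))

  # expression annotation: unannotated nodes are marked not-altered
  ste <- node_centralities(star, expression = c(l1 = 2.5))
  expect_equal(ste$expression[ste$node == "l1"], 2.5)
  expect_true(is.na(ste$expression[ste$node == "hub"]))
})

test_that("recurrent hubs are the order-free intersection of rankings", {
  r1 <- data.frame(node = c("H1", "H2", "H3", "x1", "x2"))
  r2 <- data.frame(node = c("x3", "H3", "H1", "H2"))
  r3 <- c("H2", "H1", "H3", "x4")
  r4 <- c("H3", "x5", "H2", "H1")
  expect_equal(recurrent_hubs(list(r1, r2, r3, r4)),
               c("H1", "H2", "H3"))
  expect_length(recurrent_hubs(list(c("a"), c("b"))), 0L)
  expect_error(recurrent_hubs(list(r1)), ">= 2")
})

test_that("planted connectors surface in every time point's hub table", {
  seeds <- sprintf("S%02d", 1:12)
  plan <- list(HUB1 = seeds[1:4], HUB2 = seeds[5:8], HUB3 = seeds[9:12])
  sim <- simulate_ppi(n_background = 150, seed_genes = seeds,
                      hub_plan = plan, attach_m = 1, seed = 29)
  rankings <- lapply(1:4, function(t) {
    mn <- minimum_connected_network(sim$network, seeds)
    top_betweenness(node_centralities(mn$subnetwork, seeds), n = 15)
  })
  hubs <- recurrent_hubs(rankings)
  expect_true(all(c("HUB1", "HUB2", "HUB3") %in% hubs))
})

test_that("expansion adds the strongest-evidence neighbors round by round", {
  net <- ppi_network(data.frame(
    node_a = c("s1", "s1", "s2", "n1", "n2"),
    node_b = c("n1", "n2", "n1", "n3", "n3"),
    combined_score = c(999, 999, 999, 950, 940),
    experimental_score = 500, stringsAsFactors = FALSE))
  # n1 touches both seeds (score 1998), n2 only one (999)
  tr <- expand_network(net, c("s1", "s2"), rounds = 1, per_round = 1)
  expect_equal(tr$rounds[[1]]$node, "n1")
  expect_equal(tr$rounds[[1]]$score, 1998)
  # next round: n2 (999 via s1) beats n3 (950 via n1)
  tr2 <- expand_network(net, c("s1", "s2"), rounds = 2, per_round = 1)
  expect_equal(tr2$rounds[[2]]$node, "n2")
  # exhausting the graph stops early and records truncation
  tr_all <- expand_network(net, c("s1", "s2"), rounds = 10,
                           per_round = 5)
  expect_true(tr_all$truncated)
  expect_setequal(tr_all$members, c("s1", "s2", "n1", "n2", "n3"))
  expect_error(expand_network(net, "ghost"), "ghost")

  # nested-growth property on random instances
  set.seed(83)
  for (rep in 1:15) {
    rnet <- random_connected_ppi(12, p_edge = 0.25)
    sd2 <- sample(rnet$nodes, 2)
    prev <- character(0)
    for (r in 1:4) {
      tr <- expand_network(rnet, sd2, rounds = r, per_round = 2)
      expect_true(all(prev %in% tr$members))
      prev <- tr$members
    }
    tr_b <- expand_network(rnet, sd2, rounds = 4, per_round = 2)
    expect_identical(tr_b$members, prev)  # deterministic
  }
})

test_that("enrichment p-values are exactly hypergeometric, Holm-adjusted", {
  universe <- sprintf("u%02d", 1:20)
  query <- universe[1:5]
  ann <- list(T1 = universe[2:6],        # overlap 4 of term size 5
              T2 = universe[1:5],        # identical to the query
              T3 = universe[10:14],      # overlap 0: skipped
              T4 = universe[c(1, 10:12)])
  out <- enrich_terms(query, ann, universe)
  expect_false("T3" %in% out$term)
  p_t1 <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(out$p[out$term == "T1"], p_t1, tolerance = 1e-12)
  expect_equal(p_t1, 4.902e-3, tolerance = 1e-3)
  # identical term attains the minimal possible p = 1/C(20,5)
  expect_equal(out$p[out$term == "T2"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(out$term[1], "T2")
  # Holm: monotone in rank, never below the raw p
  expect_true(all(out$p_adjusted >= out$p))
  expect_true(all(diff(out$p_adjusted) >= -1e-15))
  # single tested term: adjustment is the identity
  one <- enrich_terms(query, ann["T1"], universe)
  expect_equal(one$p_adjusted, one$p)
  expect_error(enrich_terms(query, ann, character(0)), "universe")
  expect_error(enrich_terms(c(query, "zz"), ann, universe), "zz")
})
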