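# Graph analytics on the filtered PPI network: minimum connected
# subnetwork extraction, betweenness hub discovery, round-based network
# expansion, and generic gene-set enrichment.

# igraph view of a ppi_network; edge attribute 'weight' unset (the score
# filter already binarized confidence -- all topology is unweighted).
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# Lexicographically smallest shortest path between two nodes of an
# unweighted igraph (deterministic tie-break). du, dv: distance vectors
# from `from` and `to` over all vertices.
.lex_shortest_path <- function(g, from, to, du, dv) {
  total <- du[[to]]
  path <- from
  cur <- from
  while (cur != to) {
    nb <- names(igraph::neighbors(g, cur))
    ok <- nb[du[nb] == du[[cur]] + 1 & du[nb] + dv[nb] == total]
    cur <- sort(ok)[1L]
    path <- c(path, cur)
  }
  path
}

#' Minimum connected subnetwork around seed genes
#'
#' Maps the seed genes onto the interaction graph (absent seeds are
#' reported as dropped) and, within every connected component holding at
#' least two seeds, extracts a Steiner-tree approximation by the
#' metric-closure heuristic: compute unweighted shortest-path distances
#' among the seeds, take a minimum spanning tree of that seed-seed
#' closure, replace each closure edge by an underlying graph path, and
#' prune non-seed leaves. The returned subnetwork is the induced
#' subgraph on the retained nodes (set `induce_edges = FALSE` to keep
#' only the path edges). Components with exactly one seed contribute
#' that seed as a singleton. All shortest-path and spanning-tree ties
#' are broken by lexicographic node order, so the result is
#' deterministic. The heuristic is the standard 2-approximation: the
#' retained tree has at most twice the edges of an optimal Steiner tree.
#'
#' @param network A [ppi_network()].
#' @param seeds Character vector of seed genes (non-empty).
#' @param induce_edges Restore all original edges among retained nodes
#'   (default TRUE).
#' @return List with `subnetwork` ([ppi_network()]), `dropped_seeds`,
#'   `retained_nodes`, `tree_edges` (edge count of the pruned path
#'   union, the quantity the approximation bound applies to).
#' @export
minimum_connected_network <- function(network, seeds,
                                      induce_edges = TRUE) {
  stopifnot(inherits(network, "ppi_network"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L)
    stop("minimum_connected_network: empty seed set")
  if (length(network$nodes) == 0L)
    stop("minimum_connected_network: empty network")
  dropped <- setdiff(seeds, network$nodes)
  mapped <- setdiff(seeds, dropped)
  g <- as_igraph(network)
  comp <- igraph::components(g)
  memb <- comp$membership[mapped]
  retained <- character(0)
  tree_edge_keys <- character(0)
  for (cid in unique(memb)) {
    cs <- sort(mapped[memb == cid])
    if (length(cs) == 1L) {
      retained <- c(retained, cs)
      next
    }
    dmat <- igraph::distances(g, v = cs, to = igraph::V(g))
    # Prim on the seed metric closure, lexicographic tie-break
    in_tree <- cs[1L]
    out_tree <- cs[-1L]
    mst <- list()
    while (length(out_tree)) {
      best <- NULL
      for (u in in_tree) for (v in out_tree) {
        w <- dmat[u, v]
        cand <- list(w = w, u = u, v = v)
        if (is.null(best) || w < best$w ||
            (w == best$w && (u < best$u ||
                             (u == best$u && v < best$v))))
          best <- cand
      }
      mst[[length(mst) + 1L]] <- best
      in_tree <- c(in_tree, best$v)
      out_tree <- setdiff(out_tree, best$v)
    }
    # expand closure edges into lexicographically minimal graph paths
    nodes <- character(0)
    edges <- character(0)
    dcache <- lapply(stats::setNames(cs, cs), function(s)
      stats::setNames(dmat[s, ], colnames(dmat)))
    for (e in mst) {
      path <- .lex_shortest_path(g, e$u, e$v, dcache[[e$u]],
                                 dcache[[e$v]])
      nodes <- union(nodes, path)
      if (length(path) > 1L)
        edges <- union(edges, paste(pmin(path[-length(path)], path[-1L]),
                                    pmax(path[-length(path)], path[-1L]),
                                    sep = "\r"))
    }
    # prune non-seed leaves of the path union
    repeat {
      parts <- strsplit(edges, "\r", fixed = TRUE)
      deg <- table(unlist(parts))
      leaves <- setdiff(names(deg)[deg == 1L], cs)
      isolated <- setdiff(nodes, c(names(deg), cs))
      if (!length(leaves) && !length(isolated)) break
      nodes <- setdiff(nodes, c(leaves, isolated))
      edges <- edges[vapply(parts, function(p)
        !any(p %in% leaves), logical(1))]
    }
    retained <- c(retained, nodes)
    tree_edge_keys <- c(tree_edge_keys, edges)
  }
  retained <- sort(unique(retained))
  ed <- network$edges
  key <- paste(ed$node_a, ed$node_b, sep = "\r")
  keep <- if (induce_edges)
    ed$node_a %in% retained & ed$node_b %in% retained
  else key %in% tree_edge_keys
  sub <- ppi_network(ed[keep, , drop = FALSE], nodes = retained)
  list(subnetwork = sub, dropped_seeds = sort(dropped),
       retained_nodes = retained,
       tree_edges = length(unique(tree_edge_keys)))
}

#' Node centralities of a subnetwork
#'
#' Degree and exact unnormalized betweenness (Brandes' algorithm via
#' igraph, summed over unordered pairs of other nodes) for every node,
#' with seed membership and an optional expression annotation; nodes
#' without an expression value are marked not-altered (`NA`), matching
#' how linker nodes that are not differentially expressed are reported.
#'
#' @param subnetwork A [ppi_network()].
#' @param seeds Character vector of seed genes.
#' @param expression Optional named numeric vector gene -> log2FC.
#' @param normalized Divide betweenness by the number of ordered pairs
#'   (default FALSE; raw counts are reported).
#' @return Data frame `node`, `degree`, `betweenness`, `is_seed`,
#'   `expression`.
#' @export
node_centralities <- function(subnetwork, seeds = character(0),
                              expression = NULL, normalized = FALSE) {
  stopifnot(inherits(subnetwork, "ppi_network"))
  g <- as_igraph(subnetwork)
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = normalized)
  deg <- igraph::degree(g)
  nodes <- igraph::V(g)$name
  expr <- rep(NA_real_, length(nodes))
  if (!is.null(expression))
    expr <- unname(expression[nodes])
  out <- data.frame(node = nodes, degree = as.integer(deg[nodes]),
                    betweenness = unname(btw[nodes]),
                    is_seed = nodes %in% seeds, expression = expr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-betweenness nodes
#'
#' Ranks nodes by descending betweenness, ties by descending degree,
#' then lexicographic identifier, and returns the first `n` -- the
#' connector-hub table reported per network.
#'
#' @param stats Data frame from [node_centralities()].
#' @param n Number of nodes (default 15).
#' @return Data frame of the top `n` rows in rank order.
#' @export
top_betweenness <- function(stats, n = 15) {
  stopifnot(is.data.frame(stats), n >= 1)
  ord <- order(-stats$betweenness, -stats$degree, stats$node)
  out <- stats[ord, , drop = FALSE][seq_len(min(n, nrow(stats))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hubs recurring across several rankings
#'
#' Order-free intersection of the node sets of the given rankings, e.g.
#' the connector hubs present in the top-betweenness table of every
#' infestation time point.
#'
#' @param rankings List (length >= 2) of data frames from
#'   [top_betweenness()] or character vectors.
#' @return Sorted character vector of recurrent nodes.
#' @export
recurrent_hubs <- function(rankings) {
  stopifnot(length(rankings) >= 2)
  sets <- lapply(rankings, function(r)
    if (is.data.frame(r)) r$node else as.character(r))
  sort(Reduce(intersect, sets))
}

#' Round-based network expansion from a seed set
#'
#' Starting from the induced subgraph on the seeds, each round scores
#' every non-member neighbor by the sum of combined scores of its edges
#' to current members and adds the `per_round` highest-scoring
#' candidates (ties by lexicographic identifier). Edges among members
#' are always induced from the full network. Stops early, recording
#' truncation, when no addable neighbor remains.
#'
#' @param network A [ppi_network()].
#' @param seeds Character vector of seed genes present in the network.
#' @param rounds Number of expansion rounds (default 6).
#' @param per_round Nodes added per round (default 5).
#' @return Object of class `expansion_trace`: `rounds` (list of data
#'   frames `node`, `score` per round), `members` (final node set),
#'   `subnetwork` (induced [ppi_network()]), `truncated`.
#' @export
expand_network <- function(network, seeds, rounds = 6, per_round = 5) {
  stopifnot(inherits(network, "ppi_network"), rounds >= 1, per_round >= 1)
  seeds <- unique(as.character(seeds))
  missing_s <- setdiff(seeds, network$nodes)
  if (length(missing_s))
    stop("expand_network: seed(s) not in network: ",
         paste(missing_s, collapse = ", "))
  ed <- network$edges
  members <- sort(seeds)
  trace <- list()
  truncated <- FALSE
  for (r in seq_len(rounds)) {
    a_in <- ed$node_a %in% members
    b_in <- ed$node_b %in% members
    cand_edges <- rbind(
      data.frame(node = ed$node_b[a_in & !b_in],
                 score = ed$combined_score[a_in & !b_in]),
      data.frame(node = ed$node_a[b_in & !a_in],
                 score = ed$combined_score[b_in & !a_in]))
    if (nrow(cand_edges) == 0L) { truncated <- TRUE; break }
    score <- tapply(cand_edges$score, cand_edges$node, sum)
    cand <- data.frame(node = names(score), score = as.numeric(score),
                       stringsAsFactors = FALSE)
    cand <- cand[order(-cand$score, cand$node), , drop = FALSE]
    added <- cand[seq_len(min(per_round, nrow(cand))), , drop = FALSE]
    rownames(added) <- NULL
    trace[[r]] <- added
    members <- sort(c(members, added$node))
  }
  keep <- ed$node_a %in% members & ed$node_b %in% members
  structure(list(rounds = trace, members = members,
                 subnetwork = ppi_network(ed[keep, , drop = FALSE],
                                          nodes = members),
                 truncated = truncated),
            class = "expansion_trace")
}

#' @export
print.expansion_trace <- function(x, ...) {
  cat(sprintf("expansion_trace: %d rounds, %d final nodes%s\n",
              length(x$rounds), length(x$members),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Hypergeometric gene-set enrichment with Holm correction
#'
#' For every annotation term, the upper-tail hypergeometric probability
#' of observing at least the seen overlap between the query and the
#' term's genes within the universe, adjusted across tested terms by
#' the Bonferroni step-down (Holm) procedure. Terms with no overlap are
#' skipped. Annotation gene sets are intersected with the universe
#' before testing.
#'
#' @param query Character vector, subset of `universe`.
#' @param annotation Named list term -> character vector of genes.
#' @param universe Character vector of all considered genes.
#' @return Data frame `term`, `term_size`, `overlap`, `p`,
#'   `p_adjusted`, sorted by `p`.
#' @export
enrich_terms <- function(query, annotation, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("enrich_terms: empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("enrich_terms: query gene(s) outside universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(annotation), function(term) {
    term_genes <- intersect(unique(as.character(annotation[[term]])),
                            universe)
    k <- length(intersect(term_genes, query))
    if (k == 0L) return(NULL)
    K <- length(term_genes)
    p <- stats::phyper(k - 1L, K, N - K, q, lower.tail = FALSE)
    data.frame(term = term, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adjusted = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
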