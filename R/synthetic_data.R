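# Synthetic DEG tables, manifests and PPI graphs with planted structure.
# Every downstream stage of the pipeline is testable against the ground
# truth these generators emit, with no external download.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards; generators stay pure functions of (spec, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed for a named pipeline stage.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Specification of a synthetic meta-experiment collection
#'
#' Describes the planted structure the generator emits: a shared "core
#' response" module (up-regulated across taxa but silent in designated
#' clusters, emulating the general absence of response in aphid
#' experiments), per-cluster modules, species-specific genes, Gaussian
#' log2FC noise, and platform missingness for microarray experiments.
#' Defaults mirror the study design: 28 experiments (17 microarray,
#' 11 RNA-seq) over 4 response clusters, with a mite time course.
#'
#' @param n_genes Number of genes in the universe (default 2000).
#' @param experiments Experiment manifest data frame; default
#'   [default_synthetic_manifest()].
#' @param cluster_of Named character vector mapping experiment_id to
#'   cluster label; default follows the default manifest.
#' @param core_module List `(n, mu, silent_clusters)`: size, log2 effect
#'   and clusters where the core module is not activated.
#' @param cluster_modules Named list per cluster label of `(n, mu)`.
#' @param species_specific Named list per species of `(n, mu)`.
#' @param noise_sd Standard deviation of Gaussian log2FC noise (log2
#'   units, default 0.5 -- a typical replicate-level spread for DEG
#'   effect estimates).
#' @param de_padj Adjusted p-value assigned to genes with a planted
#'   effect (default 0.001).
#' @param null_padj Adjusted p-value assigned to null genes
#'   (default 0.5).
#' @param platform_missing_rate Fraction of genes absent from each
#'   microarray experiment's platform (default 0.2).
#' @param time_course List `(early, persistent, late, mu)`: sizes of the
#'   early-only / persistent / late-only gene sets and their effect,
#'   used by [simulate_time_course()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           experiments = default_synthetic_manifest(),
                           cluster_of = NULL,
                           core_module = list(n = 120, mu = 2,
                                              silent_clusters = "cluster1"),
                           cluster_modules = list(
                             cluster2 = list(n = 40, mu = 2.5),
                             cluster3 = list(n = 40, mu = 2.5),
                             cluster4 = list(n = 40, mu = 2.5)),
                           species_specific = list(
                             T_urticae = list(n = 20, mu = 3)),
                           noise_sd = 0.5,
                           de_padj = 0.001,
                           null_padj = 0.5,
                           platform_missing_rate = 0.2,
                           time_course = list(early = 30, persistent = 50,
                                              late = 30, mu = 3)) {
  validate_manifest(experiments)
  if (is.null(cluster_of)) {
    if (!"cluster" %in% names(experiments))
      stop("synthetic_spec: provide cluster_of or a manifest with a ",
           "'cluster' column")
    cluster_of <- stats::setNames(experiments$cluster,
                                  experiments$experiment_id)
  }
  stopifnot(all(experiments$experiment_id %in% names(cluster_of)),
            noise_sd > 0,
            platform_missing_rate >= 0, platform_missing_rate <= 1,
            de_padj >= 0, de_padj <= 1, null_padj >= 0, null_padj <= 1)
  n_planted <- core_module$n +
    sum(vapply(cluster_modules, `[[`, numeric(1), "n")) +
    sum(vapply(species_specific, `[[`, numeric(1), "n"))
  if (n_planted > n_genes)
    stop("synthetic_spec: planted module sizes exceed n_genes")
  unknown <- setdiff(unlist(lapply(list(core_module$silent_clusters),
                                   as.character)),
                     unique(cluster_of))
  if (length(unknown))
    stop("synthetic_spec: unknown silent cluster(s): ",
         paste(unknown, collapse = ", "))
  structure(list(n_genes = n_genes, experiments = experiments,
                 cluster_of = cluster_of, core_module = core_module,
                 cluster_modules = cluster_modules,
                 species_specific = species_specific,
                 noise_sd = noise_sd, de_padj = de_padj,
                 null_padj = null_padj,
                 platform_missing_rate = platform_missing_rate,
                 time_course = time_course),
            class = "synthetic_spec")
}

#' Default synthetic experiment manifest
#'
#' 28 experiments emulating the composition of the real collection:
#' cluster1 groups the aphid-like non-responders (aphids, whitefly, a
#' late thrips sample), cluster2 the broad lepidopteran responses plus a
#' flat mite and thrips, cluster3 a strong late lepidopteran series, and
#' cluster4 the spider-mite time course together with the leafminer.
#' 17 experiments are microarray, 11 RNA-seq.
#'
#' @return Manifest data frame with an extra `cluster` column.
#' @export
default_synthetic_manifest <- function() {
  rec <- function(id, species, taxon, t, platform, cluster)
    data.frame(experiment_id = id, species = species, taxon_group = taxon,
               time_point_h = t, platform = platform, cluster = cluster,
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    # cluster 1: aphid-like, largely unresponsive core
    rec("mp_6h",  "M_persicae",  "aphid", 6,  "microarray", "cluster1"),
    rec("mp_12h", "M_persicae",  "aphid", 12, "microarray", "cluster1"),
    rec("mp_48h", "M_persicae",  "aphid", 48, "microarray", "cluster1"),
    rec("mc_3h",  "M_cerasi",    "aphid", 3,  "rnaseq",     "cluster1"),
    rec("mc_10h", "M_cerasi",    "aphid", 10, "rnaseq",     "cluster1"),
    rec("bb_24h", "B_brassicae", "aphid", 24, "microarray", "cluster1"),
    rec("bt_21d", "B_tabaci",    "whitefly", 504, "microarray", "cluster1"),
    rec("fo_24h", "F_occidentalis", "thrips", 24, "microarray", "cluster1"),
    # cluster 2: broad lepidopteran-style response
    rec("pb_24h", "P_brassicae", "lepidopteran", 24, "microarray", "cluster2"),
    rec("mb_24h", "M_brassicae", "lepidopteran", 24, "microarray", "cluster2"),
    rec("sl_1h",  "S_littoralis", "lepidopteran", 1, "microarray", "cluster2"),
    rec("sl_3h",  "S_littoralis", "lepidopteran", 3, "microarray", "cluster2"),
    rec("sl_9h",  "S_littoralis", "lepidopteran", 9, "microarray", "cluster2"),
    rec("pr_3h",  "P_rapae",     "lepidopteran", 3,  "microarray", "cluster2"),
    rec("fo_48h", "F_occidentalis", "thrips", 48, "microarray", "cluster2"),
    rec("by_5d",  "B_yothersi",  "mite", 120, "rnaseq", "cluster2"),
    rec("px_12h", "P_xylostella", "lepidopteran", 12, "microarray", "cluster2"),
    # cluster 3: strong late lepidopteran series
    rec("pr_6h",  "P_rapae", "lepidopteran", 6,  "rnaseq", "cluster3"),
    rec("pr_12h", "P_rapae", "lepidopteran", 12, "rnaseq", "cluster3"),
    rec("pr_24h", "P_rapae", "lepidopteran", 24, "rnaseq", "cluster3"),
    # cluster 4: spider-mite time course plus leafminer
    rec("tu_30min", "T_urticae", "mite", 0.5, "rnaseq", "cluster4"),
    rec("tu_1h",  "T_urticae", "mite", 1,  "rnaseq", "cluster4"),
    rec("tu_3h",  "T_urticae", "mite", 3,  "rnaseq", "cluster4"),
    rec("tu_24h", "T_urticae", "mite", 24, "rnaseq", "cluster4"),
    rec("tu_kon_1h", "T_urticae", "mite", 1, "microarray", "cluster4"),
    rec("tu_kon_24h", "T_urticae", "mite", 24, "microarray", "cluster4"),
    rec("lh_24h", "L_huidobrensis", "leafminer", 24, "rnaseq", "cluster4"),
    rec("lh_48h", "L_huidobrensis", "leafminer", 48, "microarray", "cluster4")
  ))
}

# Gene universe and planted module assignment for a spec (deterministic,
# no RNG: modules take consecutive blocks at the start of the universe).
.plant_modules <- function(spec) {
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  module_of <- stats::setNames(rep("null", spec$n_genes), genes)
  at <- 1L
  take <- function(n) {
    idx <- seq.int(at, length.out = n)
    at <<- at + n
    genes[idx]
  }
  core <- take(spec$core_module$n)
  module_of[core] <- "core"
  cluster_genes <- list()
  for (cl in names(spec$cluster_modules)) {
    g <- take(spec$cluster_modules[[cl]]$n)
    module_of[g] <- paste0("cluster-", cl)
    cluster_genes[[cl]] <- g
  }
  species_genes <- list()
  for (sp in names(spec$species_specific)) {
    g <- take(spec$species_specific[[sp]]$n)
    module_of[g] <- paste0("species-", sp)
    species_genes[[sp]] <- g
  }
  list(genes = genes, module_of = module_of, core = core,
       cluster_genes = cluster_genes, species_genes = species_genes)
}

# Planted mean log2FC matrix mu(g, e).
.planted_mu <- function(spec, plant) {
  man <- spec$experiments
  n_e <- nrow(man)
  mu <- matrix(0, spec$n_genes, n_e,
               dimnames = list(plant$genes, man$experiment_id))
  cl_of <- spec$cluster_of[man$experiment_id]
  active_core <- !cl_of %in% spec$core_module$silent_clusters
  mu[plant$core, active_core] <- spec$core_module$mu
  for (cl in names(spec$cluster_modules))
    mu[plant$cluster_genes[[cl]], cl_of == cl] <-
      spec$cluster_modules[[cl]]$mu
  for (sp in names(spec$species_specific))
    mu[plant$species_genes[[sp]], man$species == sp] <-
      spec$species_specific[[sp]]$mu
  mu
}

#' Simulate a collection of herbivory meta-experiments
#'
#' For each experiment e and gene g, `log2fc = mu(g, e) + N(0, noise_sd)`
#' where `mu` is the planted effect when g's module is active in e's
#' cluster or species, else 0. The adjusted p-value is assigned
#' (`de_padj` for planted cells, `null_padj` otherwise) rather than
#' computed: the pipeline consumes DEG tables, so no read-count model is
#' simulated. Each microarray experiment drops a uniform random fraction
#' of genes to emulate platform coverage.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the output is a pure function of
#'   (spec, seed).
#' @return List with `tables` (list of [deg_table()]), `manifest`
#'   (data frame) and `truth` (ground truth: `cluster_of`, `module_of`,
#'   `hub_nodes`).
#' @export
simulate_meta_experiments <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  plant <- .plant_modules(spec)
  mu <- .planted_mu(spec, plant)
  man <- spec$experiments
  with_seed(seed, {
    lfc <- mu + matrix(stats::rnorm(length(mu), 0, spec$noise_sd),
                       nrow(mu), ncol(mu))
    tables <- lapply(seq_len(nrow(man)), function(j) {
      keep <- rep(TRUE, spec$n_genes)
      if (man$platform[j] == "microarray" && spec$platform_missing_rate > 0) {
        n_drop <- floor(spec$platform_missing_rate * spec$n_genes)
        keep[sample.int(spec$n_genes, n_drop)] <- FALSE
      }
      padj <- ifelse(mu[, j] != 0, spec$de_padj, spec$null_padj)
      deg_table(man$experiment_id[j], plant$genes[keep],
                lfc[keep, j], padj[keep])
    })
    names(tables) <- man$experiment_id
    truth <- list(cluster_of = spec$cluster_of[man$experiment_id],
                  module_of = plant$module_of,
                  hub_nodes = character(0))
    list(tables = tables,
         manifest = man[setdiff(names(man), "cluster")],
         truth = truth)
  })
}

#' Simulate a single-species infestation time course
#'
#' One DEG table per time point for one species, with planted
#' "early-only" genes (active only at the first time point),
#' "persistent" genes (active at every time point) and "late-only"
#' genes (active only at the last), sized by `spec$time_course`. These
#' support the shared/specific time-point overlap analyses.
#'
#' @param spec A [synthetic_spec()].
#' @param time_points Numeric vector of hours (default the study's
#'   0.5, 1, 3, 24 design).
#' @param species Species label for the generated experiments.
#' @param seed Integer seed.
#' @return List with `tables` (named `<species>_<t>h`), `manifest`, and
#'   `truth` (`early`, `persistent`, `late` gene sets).
#' @export
simulate_time_course <- function(spec, time_points = c(0.5, 1, 3, 24),
                                 species = "T_urticae", seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), length(time_points) >= 1)
  tc <- spec$time_course
  n_planted <- tc$early + tc$persistent + tc$late
  if (n_planted > spec$n_genes)
    stop("simulate_time_course: planted sets exceed n_genes")
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  early <- genes[seq_len(tc$early)]
  persistent <- genes[seq.int(tc$early + 1L, length.out = tc$persistent)]
  late <- genes[seq.int(tc$early + tc$persistent + 1L,
                        length.out = tc$late)]
  ids <- sprintf("%s_%gh", tolower(species), time_points)
  mu <- matrix(0, spec$n_genes, length(time_points),
               dimnames = list(genes, ids))
  mu[early, 1L] <- tc$mu
  mu[persistent, ] <- tc$mu
  mu[late, length(time_points)] <- tc$mu
  with_seed(seed, {
    lfc <- mu + matrix(stats::rnorm(length(mu), 0, spec$noise_sd),
                       nrow(mu), ncol(mu))
    tables <- lapply(seq_along(ids), function(j) {
      padj <- ifelse(mu[, j] != 0, spec$de_padj, spec$null_padj)
      deg_table(ids[j], genes, lfc[, j], padj)
    })
    names(tables) <- ids
    manifest <- data.frame(experiment_id = ids, species = species,
                           taxon_group = "mite",
                           time_point_h = time_points,
                           platform = "rnaseq", stringsAsFactors = FALSE)
    list(tables = tables, manifest = manifest,
         truth = list(early = early, persistent = persistent, late = late))
  })
}

#' Simulate a PPI network with planted connector hubs
#'
#' Builds a preferential-attachment background graph (each new node
#' attaches to `attach_m` existing nodes), attaches every seed gene to
#' `attach_m` background vertices (seed genes are therefore never
#' mutually adjacent), then inserts each planned hub with direct edges
#' to its assigned seed genes, so the hub provides length-2 paths among
#' seeds that the background rarely matches. All edges carry
#' `combined_score = 999` and `experimental_score = 500` unless
#' overridden.
#'
#' @param n_background Number of background vertices (default 200).
#' @param seed_genes Character vector of seed gene names.
#' @param hub_plan Named list: hub name -> character vector of the seed
#'   genes it connects. Hub names must be distinct from seed genes.
#' @param attach_m Edges per newly attached node (default 2).
#' @param connect_hubs Also wire the planned hubs to one another,
#'   emulating an interacting regulatory core whose members route the
#'   traffic between their seed modules (default FALSE).
#' @param seed Integer seed.
#' @param combined_score,experimental_score Scores for all edges.
#' @return List with `network` ([ppi_network()]) and `truth`
#'   (`hub_nodes`, `seed_genes`).
#' @export
simulate_ppi <- function(n_background = 200, seed_genes = character(0),
                         hub_plan = list(), attach_m = 2,
                         connect_hubs = FALSE, seed = 1L,
                         combined_score = 999, experimental_score = 500) {
  if (attach_m >= n_background)
    stop("simulate_ppi: attach_m must be smaller than n_background")
  if (length(intersect(names(hub_plan), seed_genes)))
    stop("simulate_ppi: hub names must be distinct from seed genes")
  bad <- setdiff(unlist(hub_plan, use.names = FALSE), seed_genes)
  if (length(bad))
    stop("simulate_ppi: hub_plan references unknown seed gene(s): ",
         paste(bad, collapse = ", "))
  bg <- sprintf("bg%04d", seq_len(n_background))
  with_seed(seed, {
    g <- igraph::sample_pa(n_background, m = attach_m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- data.frame(node_a = bg[el[, 1L]], node_b = bg[el[, 2L]],
                        stringsAsFactors = FALSE)
    for (s in seed_genes) {
      hosts <- bg[sample.int(n_background, attach_m)]
      edges <- rbind(edges, data.frame(node_a = s, node_b = hosts,
                                       stringsAsFactors = FALSE))
    }
    for (h in names(hub_plan))
      edges <- rbind(edges, data.frame(node_a = h, node_b = hub_plan[[h]],
                                       stringsAsFactors = FALSE))
    if (connect_hubs && length(hub_plan) >= 2) {
      hp <- utils::combn(names(hub_plan), 2)
      edges <- rbind(edges, data.frame(node_a = hp[1, ], node_b = hp[2, ],
                                       stringsAsFactors = FALSE))
    }
    edges$combined_score <- combined_score
    edges$experimental_score <- experimental_score
    list(network = ppi_network(edges),
         truth = list(hub_nodes = names(hub_plan) %||% character(0),
                      seed_genes = seed_genes))
  })
}
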