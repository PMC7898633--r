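# End-to-end orchestration: configuration, the final set-algebra
# integration, and the full pipeline with reproducibility metadata.

#' Build a pipeline configuration
#'
#' Collects every stage parameter with its default. The seed is
#' mandatory: every stochastic stage derives a deterministic sub-seed
#' from it, so a run is a pure function of (inputs, config, seed).
#' Configurations can also be loaded from YAML or JSON via
#' [read_pipeline_config()].
#'
#' @param seed Integer root seed (required).
#' @param synthetic Use the built-in synthetic scenario (default TRUE).
#' @param manifest,deg_dir,ppi_edges Input paths for file-based runs:
#'   manifest TSV, a directory of `<experiment_id>.tsv` DEG tables, and
#'   a STRING-style edge list.
#' @param target_species Species whose response is dissected
#'   (default `"T_urticae"`).
#' @param padj_max,abs_lfc_min DEG-calling thresholds (0.05, 1).
#' @param fill_policy Matrix fill policy, `"zero"` or `"reported"`.
#' @param min_experiments Recurrence threshold (default 10).
#' @param r_min Pearson threshold for the correlation graph (0.95).
#' @param k Number of experiment clusters (default 4).
#' @param var_threshold Cumulative-variance cut for dimension selection
#'   (0.70).
#' @param top_n Contribution genes retained (100).
#' @param B,alpha Bootstrap replications (10000) and two-sided
#'   miscoverage (0.05).
#' @param min_combined,require_experimental PPI confidence filter
#'   (strict > 900; experimental evidence required).
#' @param top_hubs Betweenness table depth per network (15).
#' @param rounds,per_round Expansion rounds (6) and nodes added per
#'   round (5).
#' @param annotation Optional named list term -> gene vector for
#'   enrichment.
#' @param spec Optional [synthetic_spec()] override for synthetic runs.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(seed,
                            synthetic = TRUE,
                            manifest = NULL, deg_dir = NULL,
                            ppi_edges = NULL,
                            target_species = "T_urticae",
                            padj_max = 0.05, abs_lfc_min = 1,
                            fill_policy = "zero",
                            min_experiments = 10, r_min = 0.95,
                            k = 4, var_threshold = 0.70, top_n = 100,
                            B = 10000, alpha = 0.05,
                            min_combined = 900,
                            require_experimental = TRUE,
                            top_hubs = 15, rounds = 6, per_round = 5,
                            annotation = NULL, spec = NULL) {
  if (missing(seed) || is.null(seed))
    stop("pipeline_config: seed is mandatory")
  stopifnot(padj_max > 0, padj_max < 1, abs_lfc_min > 0,
            r_min > 0, r_min <= 1, min_experiments >= 1, k >= 1,
            var_threshold > 0, var_threshold < 1, top_n >= 1,
            B >= 1, alpha > 0, alpha < 1,
            min_combined >= 0, min_combined <= 1000,
            top_hubs >= 1, rounds >= 1, per_round >= 1)
  if (!synthetic && (is.null(manifest) || is.null(deg_dir)))
    stop("pipeline_config: file-based runs need manifest and deg_dir")
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 manifest = manifest, deg_dir = deg_dir,
                 ppi_edges = ppi_edges,
                 target_species = target_species,
                 padj_max = padj_max, abs_lfc_min = abs_lfc_min,
                 fill_policy = fill_policy,
                 min_experiments = min_experiments, r_min = r_min,
                 k = k, var_threshold = var_threshold, top_n = top_n,
                 B = B, alpha = alpha, min_combined = min_combined,
                 require_experimental = require_experimental,
                 top_hubs = top_hubs, rounds = rounds,
                 per_round = per_round, annotation = annotation,
                 spec = spec),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path; `.yaml`/`.yml` parsed with yaml, `.json`
#'   with jsonlite.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Integration of the four evidence gene sets
#'
#' Combines the evidence layers into the final seed set:
#' species-specific genes that appear in the basal network, genes shared
#' by the basal network and the cluster-contribution set, and
#' cluster-contribution genes that are not part of the correlated
#' coexpression module --
#' `(specific & basal) | (basal & cluster) | (cluster \ correlated)`.
#' The three constituent subsets are reported separately.
#'
#' @param sets List with character vectors `basal`, `correlated`,
#'   `cluster_contributing`, `specific`.
#' @return List with `seeds` and the three constituents
#'   `specific_in_basal`, `basal_and_cluster`,
#'   `cluster_not_correlated`.
#' @export
integration_seed_selection <- function(sets) {
  stopifnot(all(c("basal", "correlated", "cluster_contributing",
                  "specific") %in% names(sets)))
  s <- lapply(sets, function(x) unique(as.character(x)))
  specific_in_basal <- intersect(s$specific, s$basal)
  basal_and_cluster <- intersect(s$basal, s$cluster_contributing)
  cluster_not_correlated <- setdiff(s$cluster_contributing, s$correlated)
  list(seeds = sort(unique(c(specific_in_basal, basal_and_cluster,
                             cluster_not_correlated))),
       specific_in_basal = sort(specific_in_basal),
       basal_and_cluster = sort(basal_and_cluster),
       cluster_not_correlated = sort(cluster_not_correlated))
}

# Run a stage, rethrowing any error with the stage name and a
# machine-readable class.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("herbimeta_stage_error", "error",
                             "condition"),
                   list(message = sprintf("stage '%s' failed: %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

# Load inputs for a file-based run.
.load_inputs <- function(config) {
  manifest <- read_experiment_manifest(config$manifest)
  tables <- lapply(manifest$experiment_id, function(id) {
    path <- file.path(config$deg_dir, paste0(id, ".tsv"))
    if (!file.exists(path))
      stop("missing DEG table for experiment ", id, ": ", path)
    read_deg_table(path, id)
  })
  names(tables) <- manifest$experiment_id
  ppi <- NULL
  if (!is.null(config$ppi_edges))
    ppi <- read_ppi_edges(config$ppi_edges,
                          min_combined = config$min_combined,
                          require_experimental = config$require_experimental)
  list(tables = tables, manifest = manifest, ppi = ppi, truth = NULL)
}

# Built-in synthetic scenario: meta-experiments from the default spec
# plus a planted-hub PPI graph whose seed genes are early core-module
# genes (connected in triples of six by three hubs) and the
# species-specific genes.
.load_synthetic <- function(config) {
  spec <- config$spec %||% synthetic_spec()
  sim <- simulate_meta_experiments(spec, seed = stage_seed(config$seed,
                                                           "simulate"))
  plant <- .plant_modules(spec)
  n_hub_seeds <- min(18L, spec$core_module$n)
  hub_seeds <- plant$core[seq_len(n_hub_seeds)]
  sp_genes <- unlist(plant$species_genes, use.names = FALSE)
  hub_plan <- split(hub_seeds,
                    rep(paste0("HUB", 1:3),
                        each = ceiling(n_hub_seeds / 3))[seq_len(n_hub_seeds)])
  ppi_sim <- simulate_ppi(n_background = 200,
                          seed_genes = c(hub_seeds, sp_genes),
                          hub_plan = hub_plan, attach_m = 1,
                          connect_hubs = TRUE,
                          seed = stage_seed(config$seed, "ppi"))
  truth <- sim$truth
  truth$hub_nodes <- ppi_sim$truth$hub_nodes
  list(tables = sim$tables, manifest = sim$manifest,
       ppi = ppi_sim$network, truth = truth)
}

#' Run the full meta-analysis pipeline
#'
#' Executes, in order: DEG calling, matrix assembly, time-course overlap
#' partitions for the target species, recurrence filtering with the
#' correlation graph and its fully connected subnetworks, experiment
#' clustering, PCA with dimension selection and contribution ranking,
#' BCa cluster-specificity calls, species-specific gene sets, minimum
#' connected PPI networks per time point with top-betweenness hub
#' tables, recurrent-hub detection, the four-set integration, seed-set
#' expansion, and optional enrichment. The run is bitwise-reproducible
#' given (inputs, config): every stochastic stage uses a sub-seed
#' derived from the root seed by stable hashing of the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory passed to [write_results()].
#' @return A result bundle (named list); see the individual stage
#'   functions for the element types.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- .stage("inputs", if (config$synthetic)
    .load_synthetic(config) else .load_inputs(config))
  tables <- inputs$tables
  manifest <- inputs$manifest

  calls <- .stage("deg_calling", lapply(tables, call_degs,
                                        padj_max = config$padj_max,
                                        abs_lfc_min = config$abs_lfc_min))
  mat <- .stage("matrix_assembly",
                assemble_matrix(tables, manifest,
                                fill_policy = config$fill_policy,
                                padj_max = config$padj_max,
                                abs_lfc_min = config$abs_lfc_min))

  # time-course group: target-species experiments at >= 2 time points
  tc_rows <- manifest[manifest$species == config$target_species, ,
                      drop = FALSE]
  tc_rows <- tc_rows[tc_rows$platform == "rnaseq", , drop = FALSE]
  tc_rows <- tc_rows[order(tc_rows$time_point_h), , drop = FALSE]
  time_venn <- NULL
  if (nrow(tc_rows) >= 2 &&
      length(unique(tc_rows$time_point_h)) >= 2) {
    tc_ids <- tc_rows$experiment_id
    time_venn <- .stage("time_overlap",
                        time_overlap_partition(calls[tc_ids]))
  }

  recurrent <- .stage("recurrence",
                      recurrence(mat, config$min_experiments))
  corr <- NULL; subnets <- list(connected_genes = character(0),
                                clique_components = list())
  if (length(recurrent) >= 2) {
    corr <- .stage("correlation",
                   correlation_graph(mat, recurrent,
                                     r_min = config$r_min))
    subnets <- .stage("subnetworks", fully_connected_subnetworks(corr))
  }
  correlated <- unique(unlist(subnets$clique_components,
                              use.names = FALSE)) %||% character(0)

  clusters <- .stage("clustering", cluster_experiments(mat, k = config$k))
  pca <- .stage("pca", pca_contributions(mat))
  dims <- .stage("dimension_selection",
                 select_dimensions(pca, config$var_threshold))
  top_genes <- .stage("contributions",
                      top_contributing_genes(pca, dims$dims,
                                             n = min(config$top_n,
                                                     length(mat$genes))))
  spec_calls <- .stage("specificity",
                       cluster_specificity(mat, top_genes, clusters,
                                           B = config$B,
                                           alpha = config$alpha,
                                           seed = stage_seed(config$seed,
                                                             "bca")))
  specific <- .stage("species_specific",
                     species_specific_degs(mat, manifest,
                                           config$target_species))

  # target cluster: where most target-species experiments fall
  target_exps <- manifest$experiment_id[manifest$species ==
                                          config$target_species]
  target_cluster <- names(which.max(table(
    clusters$assignment[target_exps])))
  cluster_contributing <- spec_calls$gene_id[
    spec_calls$cluster == target_cluster & spec_calls$flagged &
      spec_calls$direction == "above"]

  # per-time-point minimum connected networks and hub tables
  min_nets <- list(); hub_tables <- list(); hubs <- character(0)
  basal <- character(0); basal_net <- NULL
  if (!is.null(inputs$ppi) && !is.null(time_venn)) {
    lfc_of <- function(id) {
      d <- tables[[id]]$data
      stats::setNames(d$log2fc, d$gene_id)
    }
    for (id in tc_rows$experiment_id) {
      seeds_t <- intersect(c(calls[[id]]$up, calls[[id]]$down),
                           inputs$ppi$nodes)
      if (length(seeds_t) == 0L) next
      mn <- .stage(paste0("min_network/", id),
                   minimum_connected_network(inputs$ppi, seeds_t))
      st <- node_centralities(mn$subnetwork, seeds = seeds_t,
                              expression = lfc_of(id))
      min_nets[[id]] <- mn
      hub_tables[[id]] <- top_betweenness(st, n = config$top_hubs)
    }
    if (length(hub_tables) >= 2)
      hubs <- .stage("recurrent_hubs", recurrent_hubs(hub_tables))
    if (length(hubs) >= 1) {
      basal_net <- .stage("basal_network",
                          minimum_connected_network(inputs$ppi, hubs))
      basal <- basal_net$retained_nodes
    }
  }

  sets <- list(basal = basal, correlated = correlated,
               cluster_contributing = cluster_contributing,
               specific = unique(c(specific$up, specific$down)))
  integration <- .stage("integration", integration_seed_selection(sets))
  integration_venn <- .stage("integration_venn", venn_partition(sets))

  expansion <- NULL
  if (!is.null(inputs$ppi)) {
    exp_seeds <- intersect(integration$seeds, inputs$ppi$nodes)
    if (length(exp_seeds))
      expansion <- .stage("expansion",
                          expand_network(inputs$ppi, exp_seeds,
                                         rounds = config$rounds,
                                         per_round = config$per_round))
  }

  enrichment <- NULL
  if (!is.null(config$annotation) && length(integration$seeds))
    enrichment <- .stage("enrichment",
                         enrich_terms(intersect(integration$seeds,
                                                mat$genes),
                                      config$annotation, mat$genes))

  bundle <- list(
    config = unclass(config)[!vapply(unclass(config), is.function,
                                     logical(1))],
    seed = config$seed,
    matrix = mat,
    manifest = manifest,
    time_venn = time_venn,
    recurrent = recurrent,
    correlation = corr,
    subnetworks = subnets,
    clusters = clusters,
    pca_dimensions = dims,
    top_genes = top_genes,
    specificity = spec_calls,
    species_specific = specific,
    hub_tables = hub_tables,
    min_networks = min_nets,
    recurrent_hub_nodes = hubs,
    target_cluster = target_cluster,
    integration_sets = sets,
    integration = integration,
    integration_venn = integration_venn,
    expansion = expansion,
    enrichment = enrichment,
    truth = inputs$truth,
    gene_sets = list(
      recurrent = recurrent,
      correlated = correlated,
      cluster_contributing = cluster_contributing,
      specific_up = specific$up,
      specific_down = specific$down,
      integration_seeds = integration$seeds,
      recurrent_hubs = hubs,
      basal = basal),
    tables = c(list(top_genes = top_genes, specificity = spec_calls),
               hub_tables),
    networks = c(if (!is.null(expansion))
      list(expansion = expansion$subnetwork),
      if (!is.null(basal_net)) list(basal = basal_net$subnetwork))
  )
  if (!is.null(out_dir))
    bundle$written <- .stage("write_results",
                             write_results(bundle, out_dir))
  bundle
}
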