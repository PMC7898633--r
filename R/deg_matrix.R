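# DEG calling, assembly of the gene x experiment log2FC matrix, and the
# set-algebra analyses (time-point Venn, species-specific genes).

#' Call differentially expressed genes from one experiment's table
#'
#' A gene is up-regulated when its adjusted p-value is strictly below
#' `padj_max` and its log2 fold change strictly above `abs_lfc_min`;
#' down-regulated when the p-value passes and the log2 fold change is
#' strictly below `-abs_lfc_min`. Both inequalities are strict, so
#' log2FC = 1 at the default threshold is not called. Genes with a
#' missing adjusted p-value are never called.
#'
#' @param table A [deg_table()].
#' @param padj_max Adjusted p-value threshold (default 0.05).
#' @param abs_lfc_min Absolute log2 fold-change threshold (default 1).
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(table, padj_max = 0.05, abs_lfc_min = 1) {
  stopifnot(inherits(table, "deg_table"), padj_max > 0, abs_lfc_min > 0)
  d <- table$data
  sig <- !is.na(d$padj) & d$padj < padj_max
  list(up = d$gene_id[sig & d$log2fc > abs_lfc_min],
       down = d$gene_id[sig & d$log2fc < -abs_lfc_min])
}

new_deg_matrix <- function(lfc, de_mask, measured_mask) {
  stopifnot(identical(dim(lfc), dim(de_mask)),
            identical(dim(lfc), dim(measured_mask)))
  if (any(de_mask & !measured_mask))
    stop("deg_matrix: de_mask set for an unmeasured cell")
  structure(list(genes = rownames(lfc), experiments = colnames(lfc),
                 lfc = lfc, de_mask = de_mask,
                 measured_mask = measured_mask),
            class = "deg_matrix")
}

#' @export
print.deg_matrix <- function(x, ...) {
  cat(sprintf("deg_matrix: %d genes x %d experiments (%d DE calls)\n",
              length(x$genes), length(x$experiments), sum(x$de_mask)))
  invisible(x)
}

#' Assemble the gene x experiment log2 fold-change matrix
#'
#' Rows are the union of all genes called differentially expressed in at
#' least one experiment; columns follow manifest order (restricted to
#' experiments with a table). Cells hold the reported log2FC where the
#' gene was measured on the platform; with `fill_policy = "zero"`
#' (default) measured-but-not-DE cells are set to 0, which matches how
#' published DEG-list heatmaps are conventionally drawn; `"reported"`
#' keeps the reported value. Unmeasured cells are 0 with
#' `measured_mask = FALSE`, so platform coverage is never mistaken for
#' absence of response.
#'
#' @param tables List of [deg_table()] objects.
#' @param manifest Experiment manifest data frame (see
#'   [read_experiment_manifest()]).
#' @param fill_policy `"zero"` or `"reported"`.
#' @param padj_max,abs_lfc_min DEG thresholds passed to [call_degs()].
#' @return A `deg_matrix`: list with `genes`, `experiments`, numeric
#'   matrix `lfc`, and logical matrices `de_mask`, `measured_mask`.
#' @export
assemble_matrix <- function(tables, manifest,
                            fill_policy = c("zero", "reported"),
                            padj_max = 0.05, abs_lfc_min = 1) {
  fill_policy <- match.arg(fill_policy)
  validate_manifest(manifest)
  ids <- vapply(tables, function(t) t$experiment_id, character(1))
  missing_exp <- setdiff(ids, manifest$experiment_id)
  if (length(missing_exp))
    stop("assemble_matrix: table(s) without manifest entry: ",
         paste(missing_exp, collapse = ", "))
  names(tables) <- ids
  exp_order <- manifest$experiment_id[manifest$experiment_id %in% ids]

  calls <- lapply(tables, call_degs, padj_max = padj_max,
                  abs_lfc_min = abs_lfc_min)
  genes <- sort(unique(unlist(lapply(calls, unlist), use.names = FALSE)))
  n_g <- length(genes); n_e <- length(exp_order)
  lfc <- matrix(0, n_g, n_e, dimnames = list(genes, exp_order))
  de <- matrix(FALSE, n_g, n_e, dimnames = list(genes, exp_order))
  measured <- matrix(FALSE, n_g, n_e, dimnames = list(genes, exp_order))
  for (e in exp_order) {
    d <- tables[[e]]$data
    idx <- match(d$gene_id, genes)
    present <- !is.na(idx)
    measured[idx[present], e] <- TRUE
    de_genes <- c(calls[[e]]$up, calls[[e]]$down)
    de[match(intersect(de_genes, genes), genes), e] <- TRUE
    if (fill_policy == "reported") {
      lfc[idx[present], e] <- d$log2fc[present]
    } else {
      sel <- present & d$gene_id %in% de_genes
      lfc[idx[sel], e] <- d$log2fc[sel]
    }
  }
  new_deg_matrix(lfc, de, measured)
}

#' Recurrently regulated genes
#'
#' Genes differentially expressed in at least `min_experiments`
#' experiments (row sum of the DE mask), the entry rule for the
#' correlation analysis.
#'
#' @param matrix A `deg_matrix`.
#' @param min_experiments Minimum number of experiments with a DE call
#'   (default 10; "at least", so a gene DE in exactly 10 is included).
#' @return Character vector of gene identifiers.
#' @export
recurrence <- function(matrix, min_experiments = 10) {
  stopifnot(inherits(matrix, "deg_matrix"),
            min_experiments >= 1,
            min_experiments <= length(matrix$experiments))
  matrix$genes[rowSums(matrix$de_mask) >= min_experiments]
}

#' Exact Venn partition of named gene sets
#'
#' Decomposes the union of the input sets into disjoint regions, one per
#' membership signature (e.g. `"A"`, `"A&B"`). Counting works for any
#' number of sets.
#'
#' @param named_sets Named list of character vectors.
#' @return Object of class `venn_partition`: list with `set_names`,
#'   `region_counts` (named integer vector; regions with count 0 are
#'   included for completeness) and `region_members` (named list).
#' @export
venn_partition <- function(named_sets) {
  stopifnot(is.list(named_sets), length(named_sets) >= 2,
            !is.null(names(named_sets)), all(nzchar(names(named_sets))))
  set_names <- names(named_sets)
  named_sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(named_sets, use.names = FALSE)))
  membership <- vapply(named_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  # all non-empty signatures, in binary order: A, B, A&B, C, A&C, ...
  n <- length(set_names)
  signatures <- vapply(seq_len(2^n - 1L), function(code) {
    paste(set_names[bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) > 0L],
          collapse = "&")
  }, character(1))
  region_members <- stats::setNames(
    vector("list", length(signatures)), signatures)
  for (s in signatures) region_members[[s]] <- character(0)
  if (length(universe)) {
    codes <- as.integer(membership %*% bitwShiftL(1L, seq_len(n) - 1L))
    for (code in unique(codes))
      region_members[[signatures[code]]] <- universe[codes == code]
  }
  structure(list(set_names = set_names,
                 region_counts = vapply(region_members, length, integer(1)),
                 region_members = region_members),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition of", paste(x$set_names, collapse = ", "), "\n")
  nz <- x$region_counts[x$region_counts > 0]
  for (s in names(nz)) cat(sprintf("  %-30s %d\n", s, nz[[s]]))
  invisible(x)
}

#' Shared and specific genes across infestation time points
#'
#' Applies [venn_partition()] separately to the up- and down-regulated
#' DEG sets of an ordered time course, giving the time-specific and
#' shared regions.
#'
#' @param deg_calls Named list (one entry per time point, in order) of
#'   `list(up =, down =)` DEG calls as returned by [call_degs()].
#' @return List with `up` and `down` [venn_partition()] objects.
#' @export
time_overlap_partition <- function(deg_calls) {
  stopifnot(length(deg_calls) >= 2, !is.null(names(deg_calls)))
  list(up = venn_partition(lapply(deg_calls, `[[`, "up")),
       down = venn_partition(lapply(deg_calls, `[[`, "down")))
}

#' Species-specific differentially expressed genes
#'
#' A gene is specific to the target species when it is called DE (in the
#' given direction) in at least one experiment of that species and is
#' not DE in either direction in any experiment of any other species.
#' A gene called up in one target experiment and down in another is
#' reported in both directions with a warning.
#'
#' @param matrix A `deg_matrix`.
#' @param manifest Experiment manifest covering the matrix columns.
#' @param target_species Species name as it appears in the manifest.
#' @return List with character vectors `up` and `down`.
#' @export
species_specific_degs <- function(matrix, manifest, target_species) {
  stopifnot(inherits(matrix, "deg_matrix"))
  validate_manifest(manifest)
  if (!target_species %in% manifest$species)
    stop("species_specific_degs: unknown species '", target_species, "'")
  species_of <- stats::setNames(manifest$species, manifest$experiment_id)
  is_target <- species_of[matrix$experiments] == target_species
  de <- matrix$de_mask
  up_mask <- de & matrix$lfc > 0
  down_mask <- de & matrix$lfc < 0
  de_elsewhere <- rowSums(de[, !is_target, drop = FALSE]) > 0
  up <- matrix$genes[rowSums(up_mask[, is_target, drop = FALSE]) > 0 &
                       !de_elsewhere]
  down <- matrix$genes[rowSums(down_mask[, is_target, drop = FALSE]) > 0 &
                         !de_elsewhere]
  both <- intersect(up, down)
  if (length(both))
    warning("species_specific_degs: gene(s) called up and down within ",
            target_species, ": ", paste(both, collapse = ", "))
  list(up = up, down = down)
}
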