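# Readers/writers for the three input formats and for result artifacts.
# All identifiers are opaque, case-sensitive strings: no probe mapping or
# orthology resolution is attempted anywhere in the package.

VALID_PLATFORMS <- c("microarray", "rnaseq")

#' Construct a differential-expression table
#'
#' A `deg_table` holds one experiment's per-gene differential-expression
#' statistics: gene identifier, log2 fold change versus control, and
#' BH-adjusted p-value. It is the unit of input of the whole pipeline;
#' the package never sees raw counts or intensities.
#'
#' @param experiment_id Single string identifying the experiment.
#' @param gene_id Character vector of gene identifiers (non-empty strings).
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Numeric vector of adjusted p-values in \[0, 1\]; `NA` allowed
#'   (genes with missing p-values are never called differentially expressed).
#' @return An object of class `deg_table`: a list with `experiment_id` and a
#'   data frame `data` with one row per gene.
#' @export
deg_table <- function(experiment_id, gene_id, log2fc, padj) {
  stopifnot(is.character(experiment_id), length(experiment_id) == 1L)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("deg_table: duplicate gene_id values; collapse before construction")
  if (any(!nzchar(gene_id)))
    stop("deg_table: empty gene_id")
  log2fc <- as.numeric(log2fc)
  padj <- as.numeric(padj)
  bad <- !is.na(padj) & (padj < 0 | padj > 1)
  if (any(bad))
    stop("deg_table: padj outside [0, 1] for gene(s) ",
         paste(utils::head(gene_id[bad], 5L), collapse = ", "))
  structure(
    list(experiment_id = experiment_id,
         data = data.frame(gene_id = gene_id, log2fc = log2fc, padj = padj,
                           stringsAsFactors = FALSE)),
    class = "deg_table")
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table '%s': %d genes\n", x$experiment_id, nrow(x$data)))
  invisible(x)
}

# Guess the field separator of a delimited text file from its header line.
.guess_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read a differential-expression table from a delimited file
#'
#' Reads a TSV/CSV with a header. Column names are mapped, so tables coming
#' from DESeq2, limma or hand-curated supplements can be consumed unchanged.
#' Duplicate gene rows (e.g. multiple probes) collapse to the row with the
#' smallest adjusted p-value, ties broken by larger absolute log2 fold
#' change, then by first occurrence.
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#' @param experiment_id Experiment identifier to attach to the table.
#' @param gene_col,lfc_col,padj_col Names of the gene / log2FC / adjusted
#'   p-value columns in the file header; when several candidates are
#'   given, the first one present is used.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path, experiment_id,
                           gene_col = c("gene", "gene_id"),
                           lfc_col = c("log2fc", "log2FoldChange"),
                           padj_col = "padj", sep = NULL) {
  if (is.null(sep)) sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  pick <- function(cands) {
    hit <- cands[cands %in% names(df)]
    if (!length(hit))
      stop(sprintf("read_deg_table: required column '%s' missing in %s",
                   cands[1L], path))
    hit[1L]
  }
  gene_col <- pick(gene_col)
  lfc_col <- pick(lfc_col)
  padj_col <- pick(padj_col)
  if (nrow(df) == 0L)
    return(deg_table(experiment_id, character(0), numeric(0), numeric(0)))
  gene <- as.character(df[[gene_col]])
  lfc <- .parse_numeric(df[[lfc_col]], lfc_col, path)
  padj <- .parse_numeric(df[[padj_col]], padj_col, path, allow_na = TRUE)
  # collapse duplicates: min padj, then max |log2fc|, then first occurrence
  ord <- order(gene, ifelse(is.na(padj), Inf, padj), -abs(lfc),
               seq_along(gene))
  keep <- !duplicated(gene[ord])
  idx <- ord[keep]
  idx <- idx[order(idx)]  # preserve file order of the surviving rows
  deg_table(experiment_id, gene[idx], lfc[idx], padj[idx])
}

.parse_numeric <- function(x, col, path, allow_na = FALSE) {
  if (is.numeric(x)) return(as.numeric(x))
  raw <- trimws(as.character(x))
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val) & nzchar(raw) & !toupper(raw) %in% c("NA", "NAN", "")
  if (any(bad))
    stop(sprintf(
      "read table: unparsable value '%s' in column '%s' of %s (data line %d)",
      raw[which(bad)[1L]], col, path, which(bad)[1L]))
  if (!allow_na && anyNA(val))
    stop(sprintf("read table: missing value in column '%s' of %s", col, path))
  val
}

#' Read an experiment manifest
#'
#' The manifest describes each transcriptomic experiment in the collection:
#' identifier, herbivore species, broader taxon group (mite, aphid,
#' lepidopteran, ...), infestation time point in hours, and platform
#' (`microarray` or `rnaseq`).
#'
#' @param path Delimited file (tab or comma) with header columns
#'   `experiment_id`, `species`, `taxon_group`, `time_point_h`, `platform`.
#' @return A data frame with one row per experiment, in file order.
#' @export
read_experiment_manifest <- function(path) {
  sep <- .guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  required <- c("experiment_id", "species", "taxon_group", "time_point_h",
                "platform")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("read_experiment_manifest: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- df[required]
  if (nrow(df) == 0L) return(validate_manifest(df))
  df$experiment_id <- as.character(df$experiment_id)
  df$species <- as.character(df$species)
  df$taxon_group <- as.character(df$taxon_group)
  df$time_point_h <- .parse_numeric(df$time_point_h, "time_point_h", path)
  df$platform <- as.character(df$platform)
  validate_manifest(df)
}

#' Validate an experiment manifest data frame
#'
#' @param manifest Data frame with the five manifest columns.
#' @return The manifest, invisibly unchanged, or an error.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  dup <- unique(manifest$experiment_id[duplicated(manifest$experiment_id)])
  if (length(dup))
    stop("manifest: duplicate experiment_id: ", paste(dup, collapse = ", "))
  bad_platform <- setdiff(unique(manifest$platform), VALID_PLATFORMS)
  if (nrow(manifest) && length(bad_platform))
    stop("manifest: unknown platform value(s): ",
         paste(bad_platform, collapse = ", "),
         " (expected ", paste(VALID_PLATFORMS, collapse = "/"), ")")
  if (nrow(manifest) && any(manifest$time_point_h < 0))
    stop("manifest: negative time_point_h")
  manifest
}

#' Construct a protein-protein interaction network
#'
#' An undirected, simple graph in STRING style: every edge carries a
#' combined confidence score and an experimental-evidence sub-score, both
#' on the 0-1000 scale. Edges are canonicalized (unordered pairs),
#' deduplicated keeping the maximum-score copy, and self-loops rejected.
#'
#' @param edges Data frame with columns `node_a`, `node_b`,
#'   `combined_score`, `experimental_score`.
#' @param nodes Optional character vector of extra (possibly isolated)
#'   node names to include.
#' @return An object of class `ppi_network`: list with `nodes` (sorted
#'   character vector) and `edges` (canonical data frame).
#' @export
ppi_network <- function(edges, nodes = character(0)) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        combined_score = integer(0),
                        experimental_score = integer(0),
                        stringsAsFactors = FALSE)
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  cs <- as.integer(round(edges$combined_score))
  es <- as.integer(round(edges$experimental_score))
  if (length(cs) && (any(cs < 0 | cs > 1000) | any(es < 0 | es > 1000)))
    stop("ppi_network: scores must lie in [0, 1000]")
  self <- a == b
  if (any(self)) {
    a <- a[!self]; b <- b[!self]; cs <- cs[!self]; es <- es[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  # keep the max-score copy among duplicates
  ord <- order(key, -cs, -es)
  keep <- !duplicated(key[ord])
  idx <- ord[keep]
  idx <- idx[order(lo[idx], hi[idx])]
  out <- data.frame(node_a = lo[idx], node_b = hi[idx],
                    combined_score = cs[idx], experimental_score = es[idx],
                    stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(out$node_a, out$node_b, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = out), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-style interaction edge list
#'
#' Applies the confidence filter used throughout the pipeline: keep an
#' interaction only when its combined score exceeds `min_combined`
#' (strictly, i.e. "higher than 900" keeps 901 and drops 900) and, when
#' `require_experimental` is set, only when there is any experimental
#' evidence (experimental sub-score > 0). The surviving edges are
#' symmetrized and deduplicated keeping the maximum-score copy.
#'
#' @param path Whitespace- or tab-separated file with header columns
#'   `node_a`, `node_b` (aliases `protein1`/`protein2` accepted),
#'   `combined_score`, `experimental_score` (alias `experiments`).
#' @param min_combined Strict lower bound on the combined score
#'   (default 900).
#' @param require_experimental Require experimental_score > 0
#'   (default TRUE).
#' @return A [ppi_network()] of the surviving edges.
#' @export
read_ppi_edges <- function(path, min_combined = 900,
                           require_experimental = TRUE) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "", check.names = FALSE)
  alias <- c(protein1 = "node_a", protein2 = "node_b",
             experiments = "experimental_score")
  for (nm in names(alias))
    if (nm %in% names(df) && !alias[[nm]] %in% names(df))
      names(df)[names(df) == nm] <- alias[[nm]]
  required <- c("node_a", "node_b", "combined_score", "experimental_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("read_ppi_edges: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  cs <- .parse_numeric(df$combined_score, "combined_score", path)
  es <- .parse_numeric(df$experimental_score, "experimental_score", path)
  if (length(cs) && (any(cs < 0 | cs > 1000) || any(es < 0 | es > 1000))) {
    bad <- which(cs < 0 | cs > 1000 | es < 0 | es > 1000)[1L]
    stop(sprintf("read_ppi_edges: score outside [0, 1000] at data line %d of %s",
                 bad, path))
  }
  keep <- cs > min_combined
  if (require_experimental) keep <- keep & es > 0
  ppi_network(data.frame(node_a = df$node_a[keep], node_b = df$node_b[keep],
                         combined_score = cs[keep],
                         experimental_score = es[keep],
                         stringsAsFactors = FALSE))
}

# ---- result artifact writers/readers -------------------------------------

#' Write a gene set, one identifier per line
#' @param genes Character vector (may be empty).
#' @param path Output file path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a gene set written by [write_gene_set()]
#' @param path File path.
#' @return Character vector of gene identifiers.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Write a DEG matrix as a trio of TSV files
#'
#' Writes `<prefix>_lfc.tsv`, `<prefix>_de.tsv`, `<prefix>_measured.tsv`
#' (genes in rows, experiments in columns, header row, row names in the
#' first column).
#' @param m A `deg_matrix` (see [assemble_matrix()]).
#' @param prefix Path prefix for the three files.
#' @return Character vector of the three paths, invisibly.
#' @export
write_deg_matrix <- function(m, prefix) {
  stopifnot(inherits(m, "deg_matrix"))
  paths <- paste0(prefix, c("_lfc.tsv", "_de.tsv", "_measured.tsv"))
  .write_mat <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  .write_mat(m$lfc, paths[1L])
  .write_mat(m$de_mask * 1L, paths[2L])
  .write_mat(m$measured_mask * 1L, paths[3L])
  invisible(paths)
}

#' Read a DEG matrix written by [write_deg_matrix()]
#' @param prefix The prefix used when writing.
#' @return A `deg_matrix`.
#' @export
read_deg_matrix <- function(prefix) {
  .read_mat <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    mat <- as.matrix(df[-1L])
    rownames(mat) <- df$gene_id
    mat
  }
  lfc <- .read_mat(paste0(prefix, "_lfc.tsv"))
  de <- .read_mat(paste0(prefix, "_de.tsv")) > 0
  measured <- .read_mat(paste0(prefix, "_measured.tsv")) > 0
  new_deg_matrix(lfc, de, measured)
}

#' Write a PPI network as edge-list and node TSV files
#' @param net A [ppi_network()].
#' @param prefix Path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @export
write_ppi_network <- function(net, prefix) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(net$nodes, paste0(prefix, "_nodes.tsv"))
  invisible(prefix)
}

#' Read a PPI network written by [write_ppi_network()]
#' @param prefix The prefix used when writing.
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(prefix) {
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  nodes <- readLines(paste0(prefix, "_nodes.tsv"))
  ppi_network(edges, nodes = nodes[nzchar(nodes)])
}

#' Write a pipeline result bundle to a directory
#'
#' Writes every artifact in `bundle` to `out_dir` using plain-text formats
#' (gene lists, TSV matrices and tables, edge lists) plus a
#' `run_metadata.json` file recording the configuration, seed and package
#' version. Re-reading each file reproduces the object.
#'
#' @param bundle A named list as produced by [run_full_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Data frame manifest of written files (artifact, path), invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("write_results: cannot create output directory ", out_dir)
  files <- character(0)
  .add <- function(name, path) files[[name]] <<- path
  w <- function(name, rel) { p <- file.path(out_dir, rel); .add(name, p); p }

  if (!is.null(bundle$matrix))
    write_deg_matrix(bundle$matrix, sub("_lfc\\.tsv$", "",
                     w("matrix", "deg_matrix_lfc.tsv")))
  for (nm in names(bundle$gene_sets %||% list()))
    write_gene_set(bundle$gene_sets[[nm]],
                   w(paste0("gene_set_", nm), paste0("genes_", nm, ".txt")))
  for (nm in names(bundle$tables %||% list()))
    utils::write.table(bundle$tables[[nm]],
                       w(paste0("table_", nm), paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$networks %||% list()))
    write_ppi_network(bundle$networks[[nm]],
                      sub("_edges\\.tsv$", "",
                          w(paste0("network_", nm),
                            paste0("network_", nm, "_edges.tsv"))))
  meta <- list(package = "herbimeta",
               version = as.character(utils::packageVersion("herbimeta")),
               seed = bundle$seed, config = bundle$config)
  jsonlite::write_json(meta, w("metadata", "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- data.frame(artifact = names(files),
                         path = unname(unlist(files)),
                         stringsAsFactors = FALSE)
  # the on-disk manifest stores paths relative to out_dir so two runs of
  # the same configuration are byte-identical
  rel <- data.frame(artifact = manifest$artifact,
                    path = basename(manifest$path),
                    stringsAsFactors = FALSE)
  utils::write.table(rel, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
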