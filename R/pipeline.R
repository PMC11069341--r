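# File-level workflow wrappers.
#
# Each run_* function wires the module functions into one step of the
# guild-quantification workflow, reading and writing the package's
# standard interchange files (newick, jplace, TSV, YAML sidecars). They
# back the command-line script in inst/scripts/guildq.R and keep the whole
# workflow scriptable from R. Every run is deterministic given its config
# and seed, and the resolved config is written next to the outputs.

#' Assemble a run configuration
#'
#' @param ... Named configuration entries; unknown names are rejected.
#'   Recognized: `tree`, `traits`, `jplace`, `abundance`, `taxonomy`,
#'   `clusters`, `marker1`, `marker2`, `target`, `organism_map`, `out_dir`,
#'   `n_rand`, `seed`, `min_confidence`, `min_leaves`, `rank`,
#'   `aggregation`, `impact`.
#' @return A classed list with defaults filled in.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  known <- c("tree", "traits", "jplace", "abundance", "taxonomy", "clusters",
             "marker1", "marker2", "target", "organism_map", "out_dir",
             "n_rand", "seed", "min_confidence", "min_leaves", "rank",
             "aggregation", "impact")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(out_dir = ".", n_rand = 20000, seed = NULL,
                   min_confidence = 0.5, min_leaves = 4, rank = 2,
                   aggregation = "sum")
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

require_paths <- function(cfg, keys) {
  for (key in keys) {
    if (is.null(cfg[[key]])) stop("config lacks required path: ", key)
    if (!file.exists(cfg[[key]])) {
      stop("input file for '", key, "' not found: ", cfg[[key]])
    }
  }
}

write_resolved_config <- function(cfg, out_dir, step) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- cfg[!vapply(cfg, is.null, logical(1))]
  cfg_plain$step <- step
  yaml::write_yaml(cfg_plain, file.path(out_dir, paste0(step, "_config.yml")))
}

## read a cluster table (node, label, u); node may be an ape node id or an
## internal node label present in the tree.
read_cluster_table <- function(path, tree) {
  cl <- read_tsv(path)
  stopifnot(all(c("node", "label", "u") %in% names(cl)))
  node <- suppressWarnings(as.integer(cl$node))
  if (anyNA(node)) {
    if (is.null(tree$node.label)) stop("non-numeric cluster nodes need node labels in the tree")
    idx <- match(as.character(cl$node), tree$node.label)
    if (anyNA(idx)) {
      stop("cluster node label(s) not in tree: ",
           paste(cl$node[is.na(idx)], collapse = ", "))
    }
    node <- length(tree$tip.label) + idx
  }
  data.frame(node = node, label = as.character(cl$label), u = cl$u)
}

#' Run the trait-enrichment step
#'
#' Reads a reference tree and a leaf trait table, runs the node
#' randomization test, selects the most-general significant nodes, and
#' writes `enrichment.tsv` plus `selected_clusters.tsv` (node, label, u)
#' ready for [run_quantify()].
#'
#' @param cfg A [run_config()] with `tree`, `traits`, `out_dir`, `n_rand`,
#'   `min_leaves`, `seed`.
#' @return Invisibly, a list with `results`, `selected`, and output paths.
#' @export
run_enrich <- function(cfg) {
  require_paths(cfg, c("tree", "traits"))
  tree <- ape::read.tree(cfg$tree)
  traits <- read_tsv(cfg$traits)
  res <- node_trait_enrichment(tree, traits, n_rand = cfg$n_rand,
                               min_leaves = cfg$min_leaves, seed = cfg$seed)
  res <- select_general_nodes(res, tree)
  selected_nodes <- sort(unique(res$node[res$most_general]))
  at <- define_implementations(tree, selected_nodes)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(enrichment = file.path(cfg$out_dir, "enrichment.tsv"),
             selected = file.path(cfg$out_dir, "selected_clusters.tsv"))
  write_tsv(res, paths["enrichment"])
  write_tsv(at$cluster_map, paths["selected"])
  write_resolved_config(cfg, cfg$out_dir, "enrich")
  message(sum(res$most_general), " most-general enriched (node, trait) pairs; ",
          nrow(at$cluster_map), " implementation cluster(s)")
  invisible(list(results = res, selected = at$cluster_map, paths = paths))
}

#' Run the guild quantification step
#'
#' Reads placements (jplace), the cluster/univocity table, leaf taxonomy
#' and the abundance table; assigns and quality-filters queries, builds
#' sequence groups, fits the expected-richness power law and writes the
#' impact table (`impact.tsv`) with a YAML model sidecar. Discard counts
#' and the mean confidence of kept placements are logged.
#'
#' @param cfg A [run_config()] with `jplace`, `clusters`, `abundance`,
#'   optionally `taxonomy`, plus `min_confidence` and `rank`.
#' @return Invisibly, a list with `impact`, `model`, `filter`, paths.
#' @export
run_quantify <- function(cfg) {
  require_paths(cfg, c("jplace", "clusters", "abundance"))
  jp <- read_jplace(cfg$jplace)
  clusters <- read_cluster_table(cfg$clusters, jp$tree)
  leaf_tax <- NULL
  if (!is.null(cfg$taxonomy)) {
    require_paths(cfg, "taxonomy")
    tt <- read_tsv(cfg$taxonomy)
    leaf_tax <- stats::setNames(tt$taxonomy, tt$leaf_id)
  }
  at <- annotated_tree(jp$tree, clusters)
  assignments <- assign_queries(jp, at, leaf_taxonomies = leaf_tax)
  flt <- filter_low_quality(assignments, cfg$min_confidence)
  message(sprintf("discarded %d/%d placements (%.2f%%); mean confidence of kept: %.3f",
                  flt$summary$n_discarded, flt$summary$n_total,
                  flt$summary$pct_discarded,
                  flt$summary$mean_confidence_kept))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(impact = file.path(cfg$out_dir, "impact.tsv"),
             model = file.path(cfg$out_dir, "richness_model.yml"))
  if (nrow(flt$kept) == 0) {
    warning("all queries fell below the confidence threshold; empty impact table")
    empty <- data.frame(taxon = character(0), implementation = character(0),
                        context = character(0), abundance_tpm = numeric(0),
                        d_obs = integer(0), d_exp = numeric(0),
                        u = numeric(0), k = numeric(0), status = character(0))
    write_tsv(empty, paths["impact"])
    write_resolved_config(cfg, cfg$out_dir, "quantify")
    return(invisible(list(impact = empty, model = NULL, filter = flt,
                          paths = paths)))
  }
  abundance <- read_tsv(cfg$abundance)
  groups <- build_groups(flt$kept, abundance, rank = cfg$rank)
  model <- fit_richness_model(groups)
  univocity <- stats::setNames(clusters$u, clusters$label)
  impact <- build_impact_table(groups, model, univocity)
  write_tsv(impact, paths["impact"])
  yaml::write_yaml(list(c = model$c, gamma = model$gamma,
                        r_squared = model$r_squared,
                        n_points = model$n_points,
                        n_excluded = model$n_excluded),
                   paths["model"])
  write_resolved_config(cfg, cfg$out_dir, "quantify")
  invisible(list(impact = impact, model = model, filter = flt,
                 paths = paths))
}

#' Run the fold-change step
#'
#' Computes the ratio of aggregated impact between two selections of an
#' impact table, e.g. `context = "meso"` over `context = "epi"`.
#'
#' @param cfg A [run_config()] with `impact` (path to an impact TSV) and
#'   `aggregation` (`"sum"` or `"pooled"`).
#' @param numerator,denominator Named lists of column filters.
#' @return The fold change, invisibly (also written to
#'   `fold_change.tsv`).
#' @export
run_foldchange <- function(cfg, numerator, denominator) {
  require_paths(cfg, "impact")
  impact <- read_tsv(cfg$impact)
  model <- NULL
  if (identical(cfg$aggregation, "pooled")) {
    model_path <- file.path(dirname(cfg$impact), "richness_model.yml")
    if (file.exists(model_path)) {
      m <- yaml::read_yaml(model_path)
      model <- structure(list(c = m$c, gamma = m$gamma,
                              r_squared = m$r_squared,
                              n_points = m$n_points,
                              n_excluded = m$n_excluded %||% 0,
                              log_base = exp(1)),
                         class = "richness_model")
    }
  }
  fc <- fold_change(impact, numerator, denominator,
                    mode = cfg$aggregation, model = model)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(
    numerator = paste(names(numerator), unlist(numerator), sep = "=",
                      collapse = ","),
    denominator = paste(names(denominator), unlist(denominator), sep = "=",
                        collapse = ","),
    mode = cfg$aggregation, fold_change = fc),
    file.path(cfg$out_dir, "fold_change.tsv"))
  message(sprintf("fold change = %.4g", fc))
  invisible(fc)
}

#' Run the divergence null-model step
#'
#' Reads the target gene tree, the two phylomarker trees and the organism
#' map; computes node-wise mean normalized patristic distances, fits the
#' marker-vs-marker null envelope and flags target nodes beyond it.
#' Writes `divergence_points.tsv` and `null_envelope.yml`.
#'
#' @param cfg A [run_config()] with `target`, `marker1`, `marker2`,
#'   `organism_map`.
#' @return Invisibly, list with `points`, `envelope`, paths.
#' @export
run_divergence <- function(cfg) {
  require_paths(cfg, c("target", "marker1", "marker2", "organism_map"))
  target <- ape::read.tree(cfg$target)
  m1 <- ape::read.tree(cfg$marker1)
  m2 <- ape::read.tree(cfg$marker2)
  omap <- read_tsv(cfg$organism_map)
  points <- node_group_distances(target, m1, m2, omap)
  env <- fit_null(points)
  points <- flag_divergent(points, env)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(points = file.path(cfg$out_dir, "divergence_points.tsv"),
             envelope = file.path(cfg$out_dir, "null_envelope.yml"))
  write_tsv(points, paths["points"])
  yaml::write_yaml(list(slope = env$slope, intercept = env$intercept,
                        sigma = env$sigma, n_points = env$n_points),
                   paths["envelope"])
  write_resolved_config(cfg, cfg$out_dir, "divergence")
  message(sum(points$outlier), "/", nrow(points),
          " nodes beyond the taxonomy null")
  invisible(list(points = points, envelope = env, paths = paths))
}
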