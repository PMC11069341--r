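# Synthetic-data generation with planted ground truth.
#
# Every input the package consumes — reference trees, leaf trait tables,
# jplace placements, abundance tables, marker-tree triples — can be
# generated here with known truth, so the whole pipeline is testable
# without external data. Simulation operates at the placement/abundance
# level (no sequences are simulated). Trees are pure-birth (Yule)
# topologies with i.i.d. exponential branch lengths; per-group abundances
# are lognormal (heavy-tailed, like real metagenomic TPM spreads), and
# per-group richness follows the same power law in abundance that the
# impact model fits, so planted impact coefficients are self-consistent.

#' Simulate a reference tree
#'
#' Pure-birth (Yule) topology with i.i.d. exponential branch lengths.
#'
#' @param n_leaves Number of leaves (at least 3).
#' @param seed Optional integer seed (same seed, same newick string).
#' @param branch_mean Mean of the exponential branch lengths.
#' @return A rooted `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_leaves, seed = NULL, branch_mean = 0.1) {
  if (n_leaves < 3) stop("n_leaves must be at least 3")
  with_seed(seed, {
    tree <- ape::rphylo(n_leaves, birth = 1, death = 0)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / branch_mean)
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
    tree
  })
}

#' Plant trait shifts on chosen clades
#'
#' Baseline trait values are `Normal(baseline, noise_sd)`; leaves under
#' clade `i` are shifted by `shifts[i]`. A fraction of leaves is set
#' missing at random. The shifted clade roots are the ground-truth
#' enriched nodes.
#'
#' @param tree A `phylo`.
#' @param clade_nodes Integer node ids of the shifted clades (disjoint).
#' @param shifts Numeric shifts, one per clade.
#' @param noise_sd Leaf-level noise SD (default 1).
#' @param baseline Baseline trait mean (default 0).
#' @param missing_frac Fraction of leaves with missing values (default 0;
#'   1 is an error: no data-bearing leaves would remain).
#' @param trait Trait name used in the output table.
#' @param seed Optional seed.
#' @return List: `traits` (long data frame `leaf_id`, `trait`, `value`)
#'   and `truth` (data frame `node`, `shift`; empty if all shifts are 0).
#' @export
plant_traits <- function(tree, clade_nodes = integer(0), shifts = numeric(0),
                         noise_sd = 1, baseline = 0, missing_frac = 0,
                         trait = "trait1", seed = NULL) {
  stopifnot(length(clade_nodes) == length(shifts))
  if (missing_frac >= 1) stop("missing_frac = 1 leaves no data-bearing leaves")
  ct <- clade_tips(tree)
  if (length(clade_nodes) > 1) {
    tips <- unlist(lapply(clade_nodes, function(nd) ct[[nd]]))
    if (anyDuplicated(tips)) stop("planted clades overlap")
  }
  n_tip <- length(tree$tip.label)
  with_seed(seed, {
    v <- stats::rnorm(n_tip, baseline, noise_sd)
    for (i in seq_along(clade_nodes)) {
      v[ct[[clade_nodes[i]]]] <- v[ct[[clade_nodes[i]]]] + shifts[i]
    }
    if (missing_frac > 0) {
      drop <- sample.int(n_tip, floor(missing_frac * n_tip))
      v[drop] <- NA
    }
    traits <- data.frame(leaf_id = tree$tip.label, trait = trait, value = v)
    traits <- traits[!is.na(traits$value), , drop = FALSE]
    rownames(traits) <- NULL
    truth <- data.frame(node = clade_nodes, shift = shifts)
    truth <- truth[truth$shift != 0, , drop = FALSE]
    list(traits = traits, truth = truth)
  })
}

#' Pick disjoint internal clades of a given size range
#'
#' Greedy helper for building simulation scenarios: returns up to `k`
#' internal node ids whose clades are pairwise disjoint and hold between
#' `min_size` and `max_size` leaves (largest first).
#'
#' @param tree A `phylo`.
#' @param k Maximum number of clades.
#' @param min_size,max_size Clade size bounds in leaves.
#' @return Integer vector of node ids (length `<= k`).
#' @export
pick_disjoint_clades <- function(tree, k, min_size = 4, max_size = 16) {
  ct <- clade_tips(tree)
  n_tip <- length(tree$tip.label)
  internal <- n_tip + seq_len(tree$Nnode)
  sizes <- lengths(ct[internal])
  cand <- internal[sizes >= min_size & sizes <= max_size]
  cand <- cand[order(-sizes[match(cand, internal)])]
  chosen <- integer(0)
  taken <- integer(0)
  for (nd in cand) {
    if (length(chosen) >= k) break
    if (!any(ct[[nd]] %in% taken)) {
      chosen <- c(chosen, nd)
      taken <- c(taken, ct[[nd]])
    }
  }
  chosen
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

## number every edge of `tree` (0-based, edge-matrix order) and return the
## edge_node map used by the jplace machinery.
number_edges <- function(tree) {
  stats::setNames(tree$edge[, 2L], as.character(seq_len(nrow(tree$edge)) - 1L))
}

#' Simulate placements and abundances with planted impact coefficients
#'
#' For every (cluster, context) pair a group abundance `A` is drawn from a
#' lognormal law, its richness set to `d = max(1, round(c * A^gamma))`
#' (the same abundance-richness power law the impact model fits), and `d`
#' unique queries created, each carrying `A / d` TPM and placing its
#' like_weight_ratio mass on edges inside the home cluster (Dirichlet
#' concentrated on a focal edge; `lwr_concentration = Inf` puts all mass on
#' one edge). With `exact_richness = TRUE` abundances are snapped onto the
#' power law exactly, so the planted impact table is recovered to
#' round-off by the full pipeline.
#'
#' Reference leaves under cluster `i` get taxonomy `Bacteria;<label_i>;<leaf>`,
#' so species-level grouping reproduces one group per (cluster, context).
#'
#' @param tree Reference `phylo`.
#' @param clusters Data frame `node`, `label`, `u` (disjoint clades), or
#'   NULL for an empty placement set.
#' @param contexts Character vector of context (environment) labels.
#' @param tpm_meanlog Lognormal meanlog of group abundance per context
#'   (recycled).
#' @param tpm_sdlog Lognormal sdlog of group abundance (default 0.5).
#' @param richness List `c`, `gamma` of the planted power law.
#' @param lwr_concentration Dirichlet concentration of the focal edge
#'   (default `Inf`: single-edge placements).
#' @param n_spread_edges Edges per placement when concentration is finite.
#' @param exact_richness Snap abundances onto the power law exactly.
#' @param seed Optional seed.
#' @return List of class `guild_scenario`: `jplace`, `abundance`
#'   (`query_id`, `context`, `tpm`), `truth` (planted group table with
#'   `u` and `k_true`), `annotated_tree`, `leaf_taxonomies`, `richness`,
#'   `seed`.
#' @export
simulate_placements <- function(tree, clusters, contexts = "ctx1",
                                tpm_meanlog = 4, tpm_sdlog = 0.5,
                                richness = list(c = 1, gamma = 0.5),
                                lwr_concentration = Inf,
                                n_spread_edges = 3,
                                exact_richness = FALSE, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  edge_node <- number_edges(tree)
  tree_text <- deparse_jplace_tree(tree, edge_node)
  ct <- clade_tips(tree)
  n_all <- length(tree$tip.label) + tree$Nnode

  leaf_tax <- stats::setNames(
    paste0("Bacteria;Unassigned;", tree$tip.label), tree$tip.label)
  empty_pl <- data.frame(name = character(0), edge_num = integer(0),
                         likelihood = numeric(0),
                         like_weight_ratio = numeric(0),
                         multiplicity = numeric(0))
  make_jp <- function(pl) {
    structure(list(tree = tree, edge_node = edge_node, tree_text = tree_text,
                   placements = pl,
                   fields = c("edge_num", "likelihood", "like_weight_ratio"),
                   version = 3, metadata = list(invocation = "simulated")),
              class = "jplace")
  }
  if (is.null(clusters) || nrow(clusters) == 0) {
    return(structure(
      list(jplace = make_jp(empty_pl),
           abundance = data.frame(query_id = character(0),
                                  context = character(0), tpm = numeric(0)),
           truth = data.frame(), annotated_tree = annotated_tree(tree),
           leaf_taxonomies = leaf_tax, richness = richness, seed = seed),
      class = "guild_scenario"))
  }

  at <- annotated_tree(tree, clusters)
  for (i in seq_len(nrow(clusters))) {
    tips_i <- ct[[clusters$node[i]]]
    leaf_tax[tips_i] <- paste0("Bacteria;", clusters$label[i], ";",
                               tree$tip.label[tips_i])
  }
  # edges inside each cluster: edges whose child node lies in the clade
  node_in_clade <- function(root) {
    which(vapply(seq_len(n_all),
                 function(v) all(ct[[v]] %in% ct[[root]]), logical(1)))
  }
  edges_of_cluster <- lapply(clusters$node, function(root) {
    inside <- node_in_clade(root)
    as.integer(names(edge_node))[unname(edge_node) %in% inside]
  })
  if (any(lengths(edges_of_cluster) == 0)) stop("cluster with no edges")
  tpm_meanlog <- rep_len(tpm_meanlog, length(contexts))

  with_seed(seed, {
    pl_rows <- list()
    ab_rows <- list()
    truth_rows <- list()
    for (j in seq_along(contexts)) {
      for (i in seq_len(nrow(clusters))) {
        A <- exp(stats::rnorm(1, tpm_meanlog[j], tpm_sdlog))
        d <- max(1L, as.integer(round(richness$c * A^richness$gamma)))
        if (exact_richness) A <- (d / richness$c)^(1 / richness$gamma)
        qids <- sprintf("q_%s_%s_%03d", clusters$label[i], contexts[j],
                        seq_len(d))
        ab_rows[[length(ab_rows) + 1L]] <- data.frame(
          query_id = qids, context = contexts[j], tpm = A / d)
        home <- edges_of_cluster[[i]]
        for (q in qids) {
          focal <- home[sample.int(length(home), 1L)]
          if (is.infinite(lwr_concentration) || length(home) == 1L) {
            pl_rows[[length(pl_rows) + 1L]] <- data.frame(
              name = q, edge_num = focal, likelihood = -1,
              like_weight_ratio = 1, multiplicity = 1)
          } else {
            others <- setdiff(home, focal)
            others <- others[sample.int(length(others),
                                        min(n_spread_edges - 1L,
                                            length(others)))]
            w <- rdirichlet1(c(lwr_concentration, rep(1, length(others))))
            pl_rows[[length(pl_rows) + 1L]] <- data.frame(
              name = q, edge_num = c(focal, others), likelihood = -1,
              like_weight_ratio = w, multiplicity = 1)
          }
        }
        d_exp <- richness$c * A^richness$gamma
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          taxon = paste0("Bacteria;", clusters$label[i]),
          implementation = clusters$label[i], context = contexts[j],
          abundance_tpm = A, d_obs = d, u = clusters$u[i],
          k_true = A * (d / d_exp) * clusters$u[i])
      }
    }
    placements <- do.call(rbind, pl_rows)
    placements <- placements[order(placements$name,
                                   -placements$like_weight_ratio,
                                   placements$edge_num), , drop = FALSE]
    rownames(placements) <- NULL
    truth <- do.call(rbind, truth_rows)
    truth <- truth[order(truth$taxon, truth$implementation, truth$context), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    structure(
      list(jplace = make_jp(placements),
           abundance = do.call(rbind, ab_rows),
           truth = truth, annotated_tree = at, leaf_taxonomies = leaf_tax,
           richness = richness, seed = seed),
      class = "guild_scenario")
  })
}

#' Write a simulated scenario to disk
#'
#' Emits the scenario as the package's standard interchange files:
#' reference newick, jplace, abundance TSV, leaf taxonomy TSV, cluster
#' TSV, ground-truth group TSV and a YAML sidecar describing the
#' generation law.
#'
#' @param scenario A `guild_scenario` from [simulate_placements()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "guild_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tree = file.path(dir, "reference.nwk"),
    jplace = file.path(dir, "placements.jplace"),
    abundance = file.path(dir, "abundance.tsv"),
    taxonomy = file.path(dir, "leaf_taxonomy.tsv"),
    clusters = file.path(dir, "clusters.tsv"),
    truth = file.path(dir, "truth_groups.tsv"),
    scenario = file.path(dir, "scenario.yml")
  )
  ape::write.tree(scenario$jplace$tree, paths["tree"])
  write_jplace(scenario$jplace, paths["jplace"])
  write_tsv(scenario$abundance, paths["abundance"])
  write_tsv(data.frame(leaf_id = names(scenario$leaf_taxonomies),
                       taxonomy = unname(scenario$leaf_taxonomies)),
            paths["taxonomy"])
  # key clusters by internal node label when available, so the table stays
  # valid for any reader regardless of its node numbering
  cl <- scenario$annotated_tree$cluster_map
  tree <- scenario$annotated_tree$tree
  n_tip <- length(tree$tip.label)
  if (!is.null(tree$node.label) && all(cl$node > n_tip)) {
    cl$node <- tree$node.label[cl$node - n_tip]
  }
  write_tsv(cl, paths["clusters"])
  write_tsv(scenario$truth, paths["truth"])
  yaml::write_yaml(list(generator = "guildquant::simulate_placements",
                        richness = scenario$richness,
                        seed = scenario$seed),
                   paths["scenario"])
  invisible(paths)
}

#' Simulate a phylomarker pair and a target tree with planted convergence
#'
#' The two marker trees are the base tree with independent lognormal
#' per-branch rate jitter. The target tree is a third jittered copy on
#' which `n_convergence_events` leaf prune-regraft moves place pairs of
#' distant taxa side by side, emulating functional convergence; the moved
#' pairs are the ground-truth outliers of the divergence null model.
#'
#' @param base_tree A `phylo` with at least 10 leaves.
#' @param rate_jitter_sd SD of the lognormal branch-rate jitter.
#' @param n_convergence_events Number of planted convergence events.
#' @param seed Optional seed.
#' @return List: `marker1`, `marker2`, `target` (phylo),
#'   `organism_map` (identity leaf -> organism map covering all trees),
#'   `truth` (data frame `leaf_a`, `leaf_b`, `node` = pair MRCA in the
#'   target tree).
#' @export
simulate_marker_pair <- function(base_tree, rate_jitter_sd = 0.1,
                                 n_convergence_events = 0, seed = NULL) {
  stopifnot(inherits(base_tree, "phylo"))
  n_tip <- length(base_tree$tip.label)
  if (n_tip < 10) stop("base tree must have at least 10 leaves")
  if (2 * n_convergence_events > n_tip / 2) {
    stop("too many convergence events for this tree size")
  }
  jitter <- function(tree) {
    tree$edge.length <- tree$edge.length *
      exp(stats::rnorm(nrow(tree$edge), 0, rate_jitter_sd))
    tree
  }
  with_seed(seed, {
    marker1 <- jitter(base_tree)
    marker2 <- jitter(base_tree)
    target <- jitter(base_tree)
    truth <- data.frame(leaf_a = character(0), leaf_b = character(0))
    if (n_convergence_events > 0) {
      D <- patristic_matrix(base_tree, normalize = TRUE)
      thresh <- stats::quantile(D[upper.tri(D)], 0.75)
      used <- character(0)
      for (e in seq_len(n_convergence_events)) {
        cand <- which(D > thresh, arr.ind = TRUE)
        cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
        labs <- cbind(rownames(D)[cand[, 1]], rownames(D)[cand[, 2]])
        ok <- !(labs[, 1] %in% used) & !(labs[, 2] %in% used)
        cand <- labs[ok, , drop = FALSE]
        if (nrow(cand) == 0) stop("not enough distant leaf pairs left")
        pick <- cand[sample.int(nrow(cand), 1L), ]
        used <- c(used, pick)
        a <- pick[1]; b <- pick[2]
        small <- 0.02 * mean(target$edge.length)
        target <- ape::drop.tip(target, b)
        a_idx <- which(target$tip.label == a)
        a_pendant <- target$edge.length[target$edge[, 2] == a_idx]
        target <- phytools::bind.tip(
          target, b, edge.length = small,
          where = which(target$tip.label == a),
          position = min(small, a_pendant / 2))
        truth <- rbind(truth, data.frame(leaf_a = a, leaf_b = b))
      }
    }
    truth$node <- if (nrow(truth) > 0) {
      vapply(seq_len(nrow(truth)), function(i) {
        ape::getMRCA(target, c(truth$leaf_a[i], truth$leaf_b[i]))
      }, integer(1))
    } else integer(0)
    organism_map <- do.call(rbind, lapply(
      c("target", "marker1", "marker2"),
      function(id) data.frame(leaf_id = base_tree$tip.label, tree_id = id,
                              organism = base_tree$tip.label)))
    list(marker1 = marker1, marker2 = marker2, target = target,
         organism_map = organism_map, truth = truth)
  })
}
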