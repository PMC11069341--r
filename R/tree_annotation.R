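# Reference-tree annotation: functional clusters (univocity) and
# trait-enriched "implementations".
#
# Two routes are supported, matching how different guild markers are
# curated in practice:
#   * direct biochemical evidence on reference sequences, propagated
#     conservatively to maximal unanimous clades (assign_univocity), and
#   * environmental preferences of cultured species on the leaves, tested
#     for enrichment at internal nodes by randomization
#     (node_trait_enrichment), with the most-general significant nodes
#     defining the implementations (select_general_nodes,
#     define_implementations).

#' Construct an annotated reference tree
#'
#' Bundles a rooted reference gene tree with its cluster map (which nodes
#' root functional sequence spaces, and their univocity) and optional leaf
#' metadata such as taxonomy paths.
#'
#' @param tree A rooted `phylo` object with unique tip labels.
#' @param cluster_map Data frame with columns `node` (ape node id: tips are
#'   `1..Ntip`, internals `Ntip+1..`), `label` (cluster name) and `u`
#'   (univocity in `[0, 1]`). Cluster regions must be disjoint: no cluster
#'   root may descend from another.
#' @param leaf_metadata Optional data frame keyed by `leaf_id` with e.g. a
#'   `taxonomy` column (semicolon-separated ranked path).
#' @return An object of class `annotated_tree`.
#' @export
annotated_tree <- function(tree, cluster_map = NULL, leaf_metadata = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(cluster_map)) {
    cluster_map <- data.frame(node = integer(0), label = character(0),
                              u = numeric(0))
  }
  stopifnot(all(c("node", "label", "u") %in% names(cluster_map)))
  n_all <- length(tree$tip.label) + tree$Nnode
  if (any(cluster_map$node < 1 | cluster_map$node > n_all)) {
    stop("cluster_map references node ids outside the tree")
  }
  if (anyDuplicated(cluster_map$node)) stop("duplicated cluster root node")
  if (any(cluster_map$u < 0 | cluster_map$u > 1)) {
    stop("univocity must lie in [0, 1]")
  }
  ct <- clade_tips(tree)
  tips_per_cluster <- lapply(cluster_map$node, function(nd) ct[[nd]])
  all_tips <- unlist(tips_per_cluster)
  if (anyDuplicated(all_tips)) {
    stop("cluster regions overlap: some leaf falls under two cluster roots")
  }
  if (!is.null(leaf_metadata)) {
    stopifnot("leaf_id" %in% names(leaf_metadata))
    unknown <- setdiff(leaf_metadata$leaf_id, tree$tip.label)
    if (length(unknown) > 0) {
      stop("leaf_metadata references unknown leaves: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  structure(
    list(tree = tree, cluster_map = cluster_map,
         leaf_metadata = leaf_metadata),
    class = "annotated_tree"
  )
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("Annotated reference tree: %d leaves, %d cluster(s)\n",
              length(x$tree$tip.label), nrow(x$cluster_map)))
  if (nrow(x$cluster_map) > 0) {
    cl <- leaf_clusters(x)
    tab <- table(cl)
    for (lab in names(tab)) cat(sprintf("  %s: %d leaves\n", lab, tab[[lab]]))
  }
  invisible(x)
}

#' Cluster label of every leaf
#'
#' @param at An `annotated_tree`.
#' @param incertae_label Label for leaves outside every cluster.
#' @return Named character vector, one entry per tip label.
#' @export
leaf_clusters <- function(at, incertae_label = "incertae") {
  stopifnot(inherits(at, "annotated_tree"))
  tree <- at$tree
  out <- stats::setNames(rep(incertae_label, length(tree$tip.label)),
                         tree$tip.label)
  ct <- clade_tips(tree)
  for (i in seq_len(nrow(at$cluster_map))) {
    out[ct[[at$cluster_map$node[i]]]] <- at$cluster_map$label[i]
  }
  out
}

## cluster label + u of every node (tips and internals); a node belongs to
## the cluster of its nearest ancestor-or-self cluster root.
node_cluster_of <- function(at, incertae_label = "incertae") {
  tree <- at$tree
  n_all <- length(tree$tip.label) + tree$Nnode
  label <- rep(incertae_label, n_all)
  u <- rep(NA_real_, n_all)
  ct <- clade_tips(tree)
  for (i in seq_len(nrow(at$cluster_map))) {
    nd <- at$cluster_map$node[i]
    # all nodes inside the clade rooted at nd
    inside <- which(vapply(seq_len(n_all), function(v) {
      all(ct[[v]] %in% ct[[nd]])
    }, logical(1)))
    label[inside] <- at$cluster_map$label[i]
    u[inside] <- at$cluster_map$u[i]
  }
  data.frame(node = seq_len(n_all), label = label, u = u)
}

#' Propagate sequence-level functional evidence to tree clusters
#'
#' Each maximal monophyletic clade whose evidenced leaves unanimously agree
#' becomes a cluster root with `u = 1` (functional) or `u = 0`
#' (non-functional). Mixed or unevidenced regions stay `incertae`; the
#' propagation is conservative in that no cluster ever contains
#' contradictory evidence. Leaves labeled `"ambiguous"` carry no usable
#' evidence and behave as unevidenced.
#'
#' @param tree A rooted `phylo`.
#' @param evidence Named character vector `leaf -> state`, states in
#'   `c("functional", "non-functional", "ambiguous")`.
#' @return An `annotated_tree` whose cluster map holds the maximal
#'   unanimous clades (labels `c1`, `c2`, ... in node order).
#' @export
assign_univocity <- function(tree, evidence) {
  stopifnot(inherits(tree, "phylo"))
  if (length(evidence) < 1) stop("evidence must cover at least one leaf")
  unknown <- setdiff(names(evidence), tree$tip.label)
  if (length(unknown) > 0) {
    stop("evidence references unknown leaves: ",
         paste(unknown, collapse = ", "))
  }
  bad <- setdiff(unique(evidence),
                 c("functional", "non-functional", "ambiguous"))
  if (length(bad) > 0) stop("unknown evidence state(s): ",
                            paste(bad, collapse = ", "))

  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  ct <- clade_tips(tree)
  state <- stats::setNames(rep(NA_character_, n_tip), tree$tip.label)
  state[names(evidence)] <- ifelse(evidence == "ambiguous", NA, evidence)

  n_func <- vapply(ct, function(ix) sum(state[ix] == "functional",
                                        na.rm = TRUE), numeric(1))
  n_nonf <- vapply(ct, function(ix) sum(state[ix] == "non-functional",
                                        na.rm = TRUE), numeric(1))
  pure <- (n_func > 0) != (n_nonf > 0) # exactly one evidence state present
  par <- node_parents(tree)
  maximal <- pure & (is.na(par) | !pure[ifelse(is.na(par), 1L, par)])
  roots <- which(maximal)
  if (length(roots) == 0) return(annotated_tree(tree))
  cluster_map <- data.frame(
    node = roots,
    label = paste0("c", seq_along(roots)),
    u = as.numeric(n_func[roots] > 0)
  )
  annotated_tree(tree, cluster_map)
}

#' Leaf-trait enrichment of internal nodes by randomization
#'
#' For every internal node and trait, compares the mean trait value of the
#' node's data-bearing leaves against the null distribution obtained by
#' shuffling the trait values among all data-bearing leaves of the tree.
#' A node is significant when its permutation z-score satisfies
#' `|z| >= z_threshold` (default 3, matching a one-tailed permutation
#' P below 0.003 at the normal operating point); both tails are tested so
#' that clades with unusually low as well as unusually high trait values
#' are detected.
#'
#' @param tree A rooted `phylo` (or `annotated_tree`).
#' @param traits Long-format data frame with columns `leaf_id`, `trait`,
#'   `value`; missing values simply absent. Binary traits are treated as
#'   0/1 numerics.
#' @param n_rand Number of randomizations (default `20000`; at least 1000).
#' @param min_leaves Minimum data-bearing leaves under a node for it to be
#'   eligible for significance (default 4).
#' @param z_threshold Significance threshold on `|z|` (default 3).
#' @param seed Optional integer seed; results are deterministic given it.
#' @return Data frame with one row per (internal node, trait):
#'   `node`, `trait`, `n_leaves_with_data`, `observed_mean`, `null_mean`,
#'   `null_sd`, `z`, `p_one_tailed` (the smaller tail, `(b+1)/(B+1)`
#'   corrected), `significant`, `most_general` (filled by
#'   [select_general_nodes()]).
#' @export
node_trait_enrichment <- function(tree, traits, n_rand = 20000,
                                  min_leaves = 4, z_threshold = 3,
                                  seed = NULL) {
  if (inherits(tree, "annotated_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  stopifnot(all(c("leaf_id", "trait", "value") %in% names(traits)))
  if (n_rand < 1000) stop("n_rand must be at least 1000")
  traits <- traits[!is.na(traits$value), , drop = FALSE]
  unknown <- setdiff(unique(traits$leaf_id), tree$tip.label)
  if (length(unknown) > 0) {
    stop("trait table references unknown leaves: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (nrow(traits) == 0) stop("trait table has no non-missing values")

  n_tip <- length(tree$tip.label)
  internal <- n_tip + seq_len(tree$Nnode)
  ct <- clade_tips(tree)

  with_seed(seed, {
    res <- lapply(sort(unique(traits$trait)), function(tr) {
      tt <- traits[traits$trait == tr, , drop = FALSE]
      tt <- tt[!duplicated(tt$leaf_id), , drop = FALSE]
      tt <- tt[order(tt$leaf_id), , drop = FALSE] # input-order invariance
      leaf_idx <- match(tt$leaf_id, tree$tip.label)
      v <- tt$value
      L <- length(v)
      if (L < 2) stop("trait '", tr, "' has fewer than 2 data-bearing leaves")

      # membership of data-bearing leaves under each internal node
      M <- matrix(0, nrow = length(internal), ncol = L)
      for (j in seq_along(internal)) {
        M[j, leaf_idx %in% ct[[internal[j]]]] <- 1
      }
      counts <- rowSums(M)
      obs <- as.vector(M %*% v) / pmax(counts, 1)

      # permutation null, chunked to bound memory
      B <- n_rand
      sum1 <- numeric(length(internal))
      sum2 <- numeric(length(internal))
      b_hi <- numeric(length(internal))
      b_lo <- numeric(length(internal))
      tol <- 1e-9 * max(abs(v), 1)
      done <- 0L
      while (done < B) {
        nb <- min(2000L, B - done)
        P <- vapply(seq_len(nb), function(i) v[sample.int(L)], numeric(L))
        nm <- (M %*% P) / pmax(counts, 1)
        sum1 <- sum1 + rowSums(nm)
        sum2 <- sum2 + rowSums(nm^2)
        b_hi <- b_hi + rowSums(nm >= obs - tol)
        b_lo <- b_lo + rowSums(nm <= obs + tol)
        done <- done + nb
      }
      null_mean <- sum1 / B
      null_var <- pmax(sum2 / B - null_mean^2, 0)
      null_sd <- sqrt(null_var)
      z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, 0)
      p <- pmin((b_hi + 1) / (B + 1), (b_lo + 1) / (B + 1))
      ok <- counts >= min_leaves & null_sd > 0
      data.frame(
        node = internal, trait = tr, n_leaves_with_data = counts,
        observed_mean = ifelse(counts > 0, obs, NA_real_),
        null_mean = null_mean, null_sd = null_sd, z = z,
        p_one_tailed = p,
        significant = ok & abs(z) >= z_threshold,
        most_general = NA
      )
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Select the most general trait-enriched nodes
#'
#' Per trait, keeps the significant nodes whose parent is not significant
#' for that same trait (the root qualifies when significant), and marks
#' them `most_general` in the results.
#'
#' @param results Output of [node_trait_enrichment()] for one tree.
#' @param tree The same tree the results were computed on.
#' @return The results data frame with `most_general` filled in.
#' @export
select_general_nodes <- function(results, tree) {
  if (inherits(tree, "annotated_tree")) tree <- tree$tree
  par <- node_parents(tree)
  results$most_general <- FALSE
  for (tr in unique(results$trait)) {
    rows <- which(results$trait == tr)
    sig_nodes <- results$node[rows][results$significant[rows]]
    for (i in rows) {
      if (!results$significant[i]) next
      p <- par[results$node[i]]
      results$most_general[i] <- is.na(p) || !(p %in% sig_nodes)
    }
  }
  results
}

#' Define implementations from selected nodes
#'
#' Turns the most-general enriched nodes into the implementation clusters
#' of the reference tree. Identical selections from different traits merge
#' into one cluster; when two selected nodes are nested, the one covering
#' more leaves wins (ties broken by first-seen order). Any nesting that
#' survives resolution is an error. Leaves outside every selected clade
#' remain `incertae`.
#'
#' @param tree A rooted `phylo` (or `annotated_tree`, whose topology is
#'   reused).
#' @param selected_nodes Integer node ids (duplicates allowed; typically
#'   the `most_general` nodes of [select_general_nodes()] across traits).
#' @param labels Optional character labels, one per unique node (defaults
#'   to `impl1`, `impl2`, ... in decreasing clade size).
#' @param u Univocity assigned to the implementations (default 1).
#' @return An `annotated_tree` with the implementation cluster map.
#' @export
define_implementations <- function(tree, selected_nodes, labels = NULL,
                                   u = 1) {
  if (inherits(tree, "annotated_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  nodes <- unique(as.integer(selected_nodes))
  if (length(nodes) == 0) return(annotated_tree(tree))
  ct <- clade_tips(tree)
  sizes <- vapply(nodes, function(nd) length(ct[[nd]]), numeric(1))
  ord <- order(-sizes)
  nodes <- nodes[ord]
  sizes <- sizes[ord]
  keep <- rep(TRUE, length(nodes))
  for (i in seq_along(nodes)) {
    if (!keep[i]) next
    for (j in seq_along(nodes)) {
      if (i == j || !keep[j]) next
      nested <- all(ct[[nodes[j]]] %in% ct[[nodes[i]]])
      if (nested) {
        if (sizes[j] < sizes[i]) {
          keep[j] <- FALSE # larger clade takes precedence
        } else {
          stop("nested selections of equal size cannot be resolved")
        }
      }
    }
  }
  nodes <- nodes[keep]
  # disjointness after resolution
  tips <- unlist(lapply(nodes, function(nd) ct[[nd]]))
  if (anyDuplicated(tips)) {
    stop("selected nodes remain nested/overlapping after resolution")
  }
  if (is.null(labels)) labels <- paste0("impl", seq_along(nodes))
  if (length(labels) != length(nodes)) {
    stop("need one label per resolved node (", length(nodes), ")")
  }
  u <- rep_len(u, length(nodes))
  annotated_tree(tree, data.frame(node = nodes, label = labels, u = u))
}
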