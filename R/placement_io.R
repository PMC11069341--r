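# Phylogenetic placement ingestion (jplace) and query classification.
#
# Consumes the placement output of EPA-ng-style tools: a reference tree
# whose edges carry {N} numbers, and per-query placements with
# like_weight_ratio (LWR) support. Queries are assigned the cluster of the
# tree region receiving most of their LWR mass (best-hit), taxonomically
# labeled by the consensus path at the best edge, quality-filtered, and
# aggregated into sequence groups for the guild model.

JPLACE_KNOWN_FIELDS <- c("edge_num", "likelihood", "like_weight_ratio",
                         "distal_length", "pendant_length")
EDGE_TAG <- "_JPLACEEDGE_"

## Parse a jplace tree string: "{N}" edge tokens are moved into node labels,
## the tree is read with ape, and the tokens recovered from tip/node labels.
## Returns list(tree, edge_node): edge_node[as.character(N)] = id of the
## node below edge N.
parse_jplace_tree <- function(text) {
  s <- gsub("(:[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\{([0-9]+)\\}",
            paste0(EDGE_TAG, "\\2\\1"), text)
  s <- gsub("\\{([0-9]+)\\}", paste0(EDGE_TAG, "\\1"), s)
  tree <- ape::read.tree(text = s)
  if (is.null(tree)) stop("could not parse jplace tree string")
  strip <- function(labels) {
    has <- grepl(EDGE_TAG, labels, fixed = TRUE)
    parts <- strsplit(labels, EDGE_TAG, fixed = TRUE)
    clean <- vapply(parts, function(p) p[1], character(1))
    num <- rep(NA_integer_, length(labels))
    num[has] <- as.integer(vapply(parts[has], function(p) p[2], character(1)))
    list(clean = clean, num = num)
  }
  tips <- strip(tree$tip.label)
  tree$tip.label <- tips$clean
  node_num <- rep(NA_integer_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    nl <- strip(tree$node.label)
    tree$node.label <- nl$clean
    node_num <- nl$num
  }
  n_tip <- length(tree$tip.label)
  ids <- c(seq_len(n_tip), n_tip + seq_len(tree$Nnode))
  nums <- c(tips$num, node_num)
  keep <- !is.na(nums)
  edge_node <- stats::setNames(ids[keep], as.character(nums[keep]))
  list(tree = tree, edge_node = edge_node)
}

## Render a phylo back to a jplace tree string, numbering each edge by the
## node below it according to `edge_node` (node id -> edge number).
deparse_jplace_tree <- function(tree, edge_node) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  lens <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  num_of <- stats::setNames(as.integer(names(edge_node)),
                            as.character(unname(edge_node)))
  rec <- function(nd) {
    tag <- if (!is.na(num_of[as.character(nd)])) {
      sprintf("{%d}", num_of[as.character(nd)])
    } else ""
    brl <- lens[as.character(nd)]
    suffix <- if (!is.na(brl)) sprintf(":%s%s", format(brl, digits = 12), tag)
              else tag
    if (nd <= n_tip) {
      paste0(tree$tip.label[nd], suffix)
    } else {
      kids <- children[[as.character(nd)]]
      lab <- if (!is.null(tree$node.label)) tree$node.label[nd - n_tip] else ""
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
             ")", lab, suffix)
    }
  }
  paste0(rec(root_node(tree)), ";")
}

#' Read a jplace placement file
#'
#' Parses a version-3 jplace file: the edge-numbered reference tree, the
#' `fields` declaration, and the per-query placements. Placements are
#' returned in long form, one row per (query, edge).
#'
#' @param path Path to a jplace file.
#' @return Object of class `jplace`: `tree` (phylo), `edge_node` (edge
#'   number -> id of the node below that edge), `tree_text`, `placements`
#'   (data frame `name`, `edge_num`, `likelihood`, `like_weight_ratio`,
#'   `multiplicity`), `fields`, `version`, `metadata`.
#' @export
read_jplace <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("tree", "placements", "fields")) {
    if (is.null(j[[key]])) stop("jplace file lacks required key: ", key)
  }
  version <- j$version %||% NA_integer_
  if (!is.na(version) && !version %in% c(2, 3)) {
    warning("jplace version ", version, " not tested; proceeding")
  }
  fields <- unlist(j$fields)
  unknown <- setdiff(fields, JPLACE_KNOWN_FIELDS)
  if (length(unknown) > 0) {
    warning("ignoring unknown jplace field(s): ",
            paste(unknown, collapse = ", "))
  }
  if (!all(c("edge_num", "like_weight_ratio") %in% fields)) {
    stop("jplace fields must include edge_num and like_weight_ratio")
  }
  parsed <- parse_jplace_tree(j$tree)

  rows <- list()
  for (pl in j$placements) {
    name <- if (!is.null(pl$n)) as.character(pl$n[[1]])
            else if (!is.null(pl$nm)) as.character(pl$nm[[1]][[1]])
            else stop("placement without 'n' or 'nm' name entry")
    mult <- if (!is.null(pl$nm)) as.numeric(pl$nm[[1]][[2]]) else 1
    for (p in pl$p) {
      vals <- stats::setNames(as.list(p), fields)
      rows[[length(rows) + 1L]] <- data.frame(
        name = name,
        edge_num = as.integer(vals$edge_num),
        likelihood = as.numeric(vals$likelihood %||% NA_real_),
        like_weight_ratio = as.numeric(vals$like_weight_ratio),
        multiplicity = mult
      )
    }
  }
  placements <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(name = character(0), edge_num = integer(0),
               likelihood = numeric(0), like_weight_ratio = numeric(0),
               multiplicity = numeric(0))
  if (nrow(placements) > 0) {
    bad_edges <- setdiff(placements$edge_num,
                         as.integer(names(parsed$edge_node)))
    if (length(bad_edges) > 0) {
      stop("placements reference edge number(s) absent from the tree: ",
           paste(utils::head(bad_edges, 5), collapse = ", "))
    }
    lwr_sums <- tapply(placements$like_weight_ratio, placements$name, sum)
    if (any(lwr_sums > 1 + 1e-6)) {
      stop("like_weight_ratio sums exceed 1 for query: ",
           names(lwr_sums)[which.max(lwr_sums)])
    }
    placements <- placements[order(placements$name,
                                   -placements$like_weight_ratio,
                                   placements$edge_num), , drop = FALSE]
    rownames(placements) <- NULL
  }
  structure(
    list(tree = parsed$tree, edge_node = parsed$edge_node,
         tree_text = j$tree, placements = placements,
         fields = fields, version = version %||% 3,
         metadata = j$metadata %||% list()),
    class = "jplace"
  )
}

#' Write a jplace placement file
#'
#' Emits version-3 jplace with placements order-normalized (sorted by query
#' name, then decreasing LWR) so that write/read round trips are stable.
#'
#' @param jp A `jplace` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(jp, path) {
  stopifnot(inherits(jp, "jplace"))
  pl <- jp$placements
  fields <- c("edge_num", "likelihood", "like_weight_ratio")
  entries <- lapply(split(pl, pl$name), function(rows) {
    rows <- rows[order(-rows$like_weight_ratio, rows$edge_num), , drop = FALSE]
    list(
      p = lapply(seq_len(nrow(rows)), function(i) {
        list(rows$edge_num[i],
             if (is.na(rows$likelihood[i])) 0 else rows$likelihood[i],
             rows$like_weight_ratio[i])
      }),
      n = list(rows$name[1])
    )
  })
  entries <- entries[order(names(entries))]
  names(entries) <- NULL
  obj <- list(
    version = 3,
    tree = jp$tree_text %||% deparse_jplace_tree(jp$tree, jp$edge_node),
    placements = entries,
    fields = as.list(fields),
    metadata = list(invocation = "guildquant::write_jplace")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Consensus taxonomy of every tree node
#'
#' Assigns each internal node the longest common prefix of its leaves'
#' ranked, semicolon-separated taxonomy paths; tips keep their own path.
#'
#' @param tree A rooted `phylo`.
#' @param leaf_taxonomies Named character vector `leaf -> path`
#'   ("Bacteria;Proteobacteria;...").
#' @return Character vector indexed by node id (tips then internals);
#'   disjoint subtrees yield `""` at their ancestor.
#' @export
consensus_taxonomy <- function(tree, leaf_taxonomies) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, names(leaf_taxonomies))
  if (length(missing) > 0) {
    stop("no taxonomy for leaf/leaves: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  bad <- names(leaf_taxonomies)[is.na(leaf_taxonomies) |
                                !nzchar(leaf_taxonomies)]
  bad <- intersect(bad, tree$tip.label)
  if (length(bad) > 0) stop("malformed taxonomy path for leaf: ", bad[1])
  paths <- strsplit(unname(leaf_taxonomies[tree$tip.label]), ";", fixed = TRUE)
  ct <- clade_tips(tree)
  n_tip <- length(tree$tip.label)
  vapply(seq_len(n_tip + tree$Nnode), function(nd) {
    pp <- paths[ct[[nd]]]
    prefix <- pp[[1]]
    for (p in pp[-1]) {
      m <- min(length(prefix), length(p))
      same <- prefix[seq_len(m)] == p[seq_len(m)]
      cut <- if (all(same)) m else which(!same)[1] - 1L
      prefix <- prefix[seq_len(cut)]
      if (length(prefix) == 0) break
    }
    paste(prefix, collapse = ";")
  }, character(1))
}

#' Assign placed queries to clusters and taxonomy (best hit)
#'
#' Sums each query's like_weight_ratio mass per cluster of the annotated
#' tree (an edge belongs to the cluster of the node below it) and assigns
#' the cluster with the largest total (best-hit rule). The assignment
#' confidence is that winning mass; the taxonomy is the consensus path at
#' the best-supported edge within the winning cluster. Queries whose
#' winning region is outside every cluster stay `incertae`; queries in
#' `u = 0` clusters are kept but flagged non-functional (their impact will
#' be zero).
#'
#' @param placements A `jplace` object.
#' @param at An `annotated_tree` on the same leaf set (cluster roots are
#'   matched across trees by identical tip sets).
#' @param leaf_taxonomies Optional named vector `leaf -> taxonomy path`;
#'   defaults to the `taxonomy` column of the annotated tree's
#'   `leaf_metadata`.
#' @param incertae_label Label for out-of-cluster regions.
#' @return Data frame of class `query_assignments`: `query`, `cluster`,
#'   `u`, `status`, `taxonomy`, `confidence`, `best_edge`.
#' @export
assign_queries <- function(placements, at, leaf_taxonomies = NULL,
                           incertae_label = "incertae") {
  stopifnot(inherits(placements, "jplace"), inherits(at, "annotated_tree"))
  jt <- placements$tree
  if (nrow(jt$edge) != nrow(at$tree$edge) ||
      !setequal(jt$tip.label, at$tree$tip.label)) {
    stop("edge mismatch: placement tree and annotated tree are incompatible")
  }
  # carry the cluster map onto the placement tree's own numbering
  mapped <- match_nodes_by_tips(at$cluster_map$node, at$tree, jt)
  if (anyNA(mapped)) {
    stop("edge mismatch: cluster root clade(s) absent from placement tree")
  }
  at_j <- annotated_tree(jt, data.frame(node = mapped,
                                        label = at$cluster_map$label,
                                        u = at$cluster_map$u))
  node_cl <- node_cluster_of(at_j, incertae_label)
  u_of_label <- c(stats::setNames(at$cluster_map$u, at$cluster_map$label))

  if (is.null(leaf_taxonomies) && !is.null(at$leaf_metadata) &&
      "taxonomy" %in% names(at$leaf_metadata)) {
    leaf_taxonomies <- stats::setNames(at$leaf_metadata$taxonomy,
                                       at$leaf_metadata$leaf_id)
  }
  taxo <- if (!is.null(leaf_taxonomies)) {
    consensus_taxonomy(jt, leaf_taxonomies)
  } else NULL

  pl <- placements$placements
  if (nrow(pl) == 0) {
    out <- data.frame(query = character(0), cluster = character(0),
                      u = numeric(0), status = character(0),
                      taxonomy = character(0), confidence = numeric(0),
                      best_edge = integer(0))
    class(out) <- unique(c("query_assignments", class(out)))
    return(out)
  }
  pl$node <- unname(placements$edge_node[as.character(pl$edge_num)])
  pl$cluster <- node_cl$label[pl$node]

  rows <- lapply(split(pl, pl$name), function(q) {
    mass <- tapply(q$like_weight_ratio, q$cluster, sum)
    top <- max(mass)
    winners <- names(mass)[mass >= top - 1e-12]
    if (length(winners) > 1) {
      # tie: prefer the cluster holding the single best-supported edge,
      # then lexicographic
      best_row <- q[which.max(q$like_weight_ratio), ]
      winner <- if (best_row$cluster %in% winners) best_row$cluster
                else sort(winners)[1]
      message("LWR tie for query '", q$name[1], "' resolved to '",
              winner, "'")
    } else {
      winner <- winners
    }
    inwin <- q[q$cluster == winner, , drop = FALSE]
    best <- inwin[which.max(inwin$like_weight_ratio), ]
    u <- if (winner == incertae_label) NA_real_ else
      unname(u_of_label[[winner]])
    status <- if (winner == incertae_label) "incertae"
              else if (u == 0) "non_functional" else "functional"
    data.frame(
      query = q$name[1], cluster = winner, u = u, status = status,
      taxonomy = if (is.null(taxo)) NA_character_ else taxo[best$node],
      confidence = unname(mass[winner]), best_edge = best$edge_num
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("query_assignments", class(out)))
  out
}

#' Filter poorly supported query assignments
#'
#' Discards queries whose best-cluster confidence (summed like_weight_ratio
#' of the winning cluster) falls below a threshold, and reports the discard
#' count, percentage, and the mean confidence of the kept queries — the
#' "weighted likelihood robustness" of the kept set.
#'
#' @param assignments A `query_assignments` data frame.
#' @param min_confidence Threshold in `[0, 1]` (default 0.5).
#' @return List of class `placement_filter`: `kept`, `discarded`,
#'   `summary` (`n_total`, `n_discarded`, `pct_discarded`,
#'   `mean_confidence_kept`).
#' @export
filter_low_quality <- function(assignments, min_confidence = 0.5) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  low <- assignments$confidence < min_confidence
  kept <- assignments[!low, , drop = FALSE]
  discarded <- assignments[low, , drop = FALSE]
  n <- nrow(assignments)
  structure(
    list(kept = kept, discarded = discarded,
         summary = list(
           n_total = n,
           n_discarded = nrow(discarded),
           pct_discarded = if (n > 0) 100 * nrow(discarded) / n else 0,
           mean_confidence_kept = if (nrow(kept) > 0) mean(kept$confidence)
                                  else NA_real_)),
    class = "placement_filter"
  )
}

#' @export
print.placement_filter <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Placement filter: %d/%d discarded (%.2f%%)\n",
              s$n_discarded, s$n_total, s$pct_discarded))
  cat(sprintf("  mean confidence of kept queries: %.3f\n",
              s$mean_confidence_kept))
  invisible(x)
}

## Truncate a semicolon path to `rank` levels (NULL keeps the full path);
## an empty/unresolved path falls back to "Unclassified".
truncate_rank <- function(path, rank = NULL) {
  if (is.na(path) || !nzchar(path)) return("Unclassified")
  parts <- strsplit(path, ";", fixed = TRUE)[[1]]
  if (!is.null(rank)) parts <- parts[seq_len(min(rank, length(parts)))]
  paste(parts, collapse = ";")
}

#' Aggregate assigned queries into sequence groups
#'
#' Joins kept query assignments with a per-context abundance table and
#' builds one group per (taxon, implementation, context) with summed TPM
#' and observed richness (`d_obs` = number of distinct member queries in
#' that context).
#'
#' @param assignments Kept `query_assignments` (e.g.
#'   `filter_low_quality(...)$kept`).
#' @param abundance Data frame with columns `query_id`, `context`, `tpm`.
#'   Duplicated (query, context) rows are an error; abundance rows for
#'   queries never placed raise a warning and are dropped.
#' @param rank Taxonomy depth used as the grouping taxon (NULL = full
#'   consensus path).
#' @param missing_abundance `"error"` (default) if a kept query has no
#'   abundance row at all, or `"zero"` to keep it with zero TPM in a
#'   context named `"unknown"`.
#' @return A `group_table` data frame (`taxon`, `implementation`,
#'   `context`, `abundance_tpm`, `d_obs`).
#' @export
build_groups <- function(assignments, abundance, rank = NULL,
                         missing_abundance = c("error", "zero")) {
  missing_abundance <- match.arg(missing_abundance)
  stopifnot(all(c("query_id", "context", "tpm") %in% names(abundance)))
  if (anyDuplicated(abundance[c("query_id", "context")])) {
    stop("duplicated (query_id, context) rows in abundance table")
  }
  unplaced <- setdiff(abundance$query_id, assignments$query)
  if (length(unplaced) > 0) {
    warning(length(unplaced),
            " abundance entries for queries never placed; dropped")
    abundance <- abundance[!abundance$query_id %in% unplaced, , drop = FALSE]
  }
  noab <- setdiff(assignments$query, abundance$query_id)
  if (length(noab) > 0) {
    if (missing_abundance == "error") {
      stop(length(noab), " placed query/queries missing from the abundance ",
           "table (first: ", noab[1], ")")
    }
    abundance <- rbind(abundance,
                       data.frame(query_id = noab, context = "unknown",
                                  tpm = 0))
  }
  m <- merge(abundance, assignments, by.x = "query_id", by.y = "query")
  m$taxon <- vapply(m$taxonomy, truncate_rank, character(1), rank = rank)
  key <- interaction(m$taxon, m$cluster, m$context, drop = TRUE)
  rows <- lapply(split(m, key), function(g) {
    data.frame(taxon = g$taxon[1], implementation = g$cluster[1],
               context = g$context[1], abundance_tpm = sum(g$tpm),
               d_obs = length(unique(g$query_id)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon, out$implementation, out$context), , drop = FALSE]
  rownames(out) <- NULL
  as_group_table(out)
}
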