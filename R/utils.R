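# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Tip indices descending from every node of a rooted phylo object.
## Returns a list of length Ntip + Nnode; element i holds the tip indices
## under node i (a tip is its own, singleton clade).
clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) out[[i]] <- i
  edge <- stats::reorder(tree, "postorder")$edge
  for (r in seq_len(nrow(edge))) {
    out[[edge[r, 1L]]] <- c(out[[edge[r, 1L]]], out[[edge[r, 2L]]])
  }
  out
}

## Parent node of every node (NA for the root).
node_parents <- function(tree) {
  par <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

root_node <- function(tree) length(tree$tip.label) + 1L

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's .Random.seed is restored afterwards so seeded package functions
## do not disturb the user's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

## Stable key for a set of tip labels (used to match nodes across trees
## that share a leaf set but were read independently).
tipset_key <- function(labels) paste(sort(labels), collapse = "\r")

## Map node ids of `from` onto node ids of `to` by identical tip-label sets.
## Returns an integer vector parallel to `nodes` with NA where no node of
## `to` subtends the same leaves.
match_nodes_by_tips <- function(nodes, from, to) {
  ct_from <- clade_tips(from)
  ct_to <- clade_tips(to)
  keys_to <- vapply(
    ct_to,
    function(ix) tipset_key(to$tip.label[ix]),
    character(1)
  )
  keys_from <- vapply(
    nodes,
    function(nd) tipset_key(from$tip.label[ct_from[[nd]]]),
    character(1)
  )
  match(keys_from, keys_to)
}

## Write a data.frame as plain TSV (the package's interchange format).
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}
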