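# Shared fixtures, all generated in code.

# fully balanced rooted tree with 2^depth leaves and unit branch lengths
balanced_tree <- function(depth) {
  newick <- "x"
  for (i in seq_len(depth)) {
    newick <- gsub("x", "(x:1,x:1)", newick, fixed = TRUE)
  }
  tree <- ape::read.tree(text = paste0(newick, ";"))
  tree$tip.label <- paste0("t", seq_along(tree$tip.label))
  tree
}

# tree with one maximal clade of n_clade leaves against n_bg background
# leaves (the clade hangs directly off the root); returns the tree and the
# clade's node id — the canonical planted-clade scenario for power checks
planted_clade_tree <- function(n_clade, n_bg, seed) {
  set.seed(seed)
  left <- ape::rphylo(n_clade, birth = 1, death = 0)
  right <- ape::rphylo(n_bg, birth = 1, death = 0)
  left$tip.label <- paste0("c", seq_len(n_clade))
  right$tip.label <- paste0("b", seq_len(n_bg))
  nwk <- paste0("(", sub(";$", "", ape::write.tree(left)), ":0.5,",
                sub(";$", "", ape::write.tree(right)), ":0.5);")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length[is.na(tree$edge.length) | tree$edge.length <= 0] <- 0.1
  list(tree = tree, clade = ape::getMRCA(tree, paste0("c", seq_len(n_clade))))
}

# minimal hand-written jplace file; returns its path
minimal_jplace <- function(dir = tempdir()) {
  path <- file.path(dir, "minimal.jplace")
  writeLines(paste0(
    '{"version": 3,',
    ' "tree": "((A:0.1{0},B:0.2{1}):0.3{2},(C:0.1{3},D:0.1{4}):0.2{5}):0{6};",',
    ' "placements": [{"p": [[0, -100.5, 1.0]], "n": ["query1"]}],',
    ' "fields": ["edge_num", "likelihood", "like_weight_ratio"],',
    ' "metadata": {"invocation": "test"}}'
  ), path)
  path
}

# exact permutation-null tail probabilities for the mean of the leaves
# under one node: enumerates every subset of size m of the trait values
# (all equally likely under a tree-wide shuffle)
exact_node_tails <- function(values, m, observed, tol = 1e-9) {
  subsets <- utils::combn(length(values), m)
  means <- colMeans(matrix(values[subsets], nrow = m))
  list(p_hi = mean(means >= observed - tol),
       p_lo = mean(means <= observed + tol))
}

# independent closed-form OLS oracle (slope/intercept from moments)
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       sigma = sqrt(sum(res^2) / (length(x) - 2)),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}
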