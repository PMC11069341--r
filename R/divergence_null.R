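# Phylomarker divergence null model.
#
# Tests whether the divergence pattern of a functional gene tree is
# explained by taxonomy. Two phylomarker trees (e.g. 16S rRNA and rplB)
# built for the same organisms define the neutral expectation: their
# node-wise mean normalized patristic distances fall on a straight line.
# The same quantity computed on the target gene tree is compared against
# that line; nodes falling outside a +/- 3 sigma residual band diverge
# more (or converge more) than taxonomy predicts.

#' Pairwise patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of leaves,
#' optionally normalized by the tree diameter (maximum pairwise distance)
#' so that values lie in `[0, 1]`.
#'
#' @param tree A `phylo` with non-negative branch lengths.
#' @param normalize Divide by the maximum pairwise distance (default TRUE).
#' @return A symmetric numeric matrix with zero diagonal, dimnames the tip
#'   labels.
#' @export
patristic_matrix <- function(tree, normalize = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  D <- ape::cophenetic.phylo(tree)
  if (normalize) {
    dmax <- max(D)
    if (dmax > 0) D <- D / dmax
  }
  D
}

## organism-pair distance matrix for one tree given leaf -> organism map;
## when an organism has several leaves the pairwise leaf distances are
## combined with `combine` ("mean" or "min").
organism_distances <- function(tree, org_of_leaf, organisms,
                               combine = c("mean", "min")) {
  combine <- match.arg(combine)
  D <- patristic_matrix(tree, normalize = TRUE)
  leaves_of <- split(names(org_of_leaf), org_of_leaf)
  K <- length(organisms)
  if (all(lengths(leaves_of[organisms]) == 1L)) {
    lv <- vapply(leaves_of[organisms], `[`, character(1), 1L)
    out <- D[lv, lv, drop = FALSE]
    dimnames(out) <- list(organisms, organisms)
    return(out)
  }
  out <- matrix(NA_real_, K, K, dimnames = list(organisms, organisms))
  diag(out) <- 0
  if (K < 2) return(out)
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      li <- leaves_of[[organisms[i]]]
      lj <- leaves_of[[organisms[j]]]
      block <- D[li, lj, drop = FALSE]
      val <- if (combine == "mean") mean(block) else min(block)
      out[i, j] <- out[j, i] <- val
    }
  }
  out
}

#' Node-wise mean distances in target and phylomarker trees
#'
#' For every internal node of the target gene tree subtending at least two
#' mapped organisms present in both phylomarker trees, computes the mean
#' over organism pairs of the normalized patristic distance in each
#' phylomarker tree and in the target tree.
#'
#' Organisms represented by several target-tree leaves (a gene may occur in
#' multiple, distant copies) contribute, by default, the minimum leaf-pair
#' distance in the target tree (the most convergent copy); set
#' `target_combine = "mean"` for the average. Phylomarker trees combine
#' multiple leaves by the mean.
#'
#' @param target_tree The functional gene tree (`phylo`).
#' @param marker1,marker2 The two phylomarker trees (`phylo`).
#' @param organism_map Data frame with columns `leaf_id`, `tree_id`
#'   (`"target"`, `"marker1"`, `"marker2"`) and `organism`.
#' @param target_combine `"min"` (default) or `"mean"` for multi-copy
#'   organisms in the target tree.
#' @return Data frame of class `divergence_points` with columns `node`,
#'   `n_organisms`, `dist_marker1`, `dist_marker2`, `dist_target`,
#'   `outlier` (NA until [flag_divergent()]).
#' @export
node_group_distances <- function(target_tree, marker1, marker2, organism_map,
                                 target_combine = c("min", "mean")) {
  target_combine <- match.arg(target_combine)
  stopifnot(all(c("leaf_id", "tree_id", "organism") %in% names(organism_map)))
  trees <- list(target = target_tree, marker1 = marker1, marker2 = marker2)
  maps <- lapply(names(trees), function(id) {
    m <- organism_map[organism_map$tree_id == id, , drop = FALSE]
    m <- m[m$leaf_id %in% trees[[id]]$tip.label, , drop = FALSE]
    stats::setNames(m$organism, m$leaf_id)
  })
  names(maps) <- names(trees)
  common <- Reduce(intersect, lapply(maps, function(m) unique(unname(m))))
  if (length(common) < 2) {
    stop("fewer than 2 organisms common to the target and both markers")
  }
  common <- sort(common)
  Dm1 <- organism_distances(marker1, maps$marker1, common, "mean")
  Dm2 <- organism_distances(marker2, maps$marker2, common, "mean")
  Dt <- organism_distances(target_tree, maps$target, common, target_combine)

  n_tip <- length(target_tree$tip.label)
  ct <- clade_tips(target_tree)
  org_of_tip <- maps$target[target_tree$tip.label]
  rows <- lapply(n_tip + seq_len(target_tree$Nnode), function(nd) {
    orgs <- unique(org_of_tip[ct[[nd]]])
    orgs <- sort(orgs[!is.na(orgs) & orgs %in% common])
    if (length(orgs) < 2) return(NULL)
    pairs <- utils::combn(orgs, 2)
    idx <- cbind(match(pairs[1, ], common), match(pairs[2, ], common))
    data.frame(node = nd, n_organisms = length(orgs),
               dist_marker1 = mean(Dm1[idx]),
               dist_marker2 = mean(Dm2[idx]),
               dist_target = mean(Dt[idx]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no internal node subtends 2+ organisms shared with both markers")
  }
  out$outlier <- NA
  rownames(out) <- NULL
  class(out) <- unique(c("divergence_points", class(out)))
  out
}

#' Fit the two-phylomarker null envelope
#'
#' Ordinary least-squares regression of the marker-2 node distances on the
#' marker-1 node distances; the residual standard deviation (denominator
#' `n - 2`) defines the `+/- 3 sigma` band of taxonomically expected
#' divergence.
#'
#' @param points A `divergence_points` data frame (or any data frame with
#'   `dist_marker1` and `dist_marker2`).
#' @return Object of class `null_envelope`: `slope`, `intercept`, `sigma`,
#'   `n_points`.
#' @export
fit_null <- function(points) {
  x <- points$dist_marker1
  y <- points$dist_marker2
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points to fit the null model")
  if (length(unique(x)) < 2) stop("degenerate regressor: marker-1 distances identical")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / (length(x) - 2))
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         sigma = sigma, n_points = length(x)),
    class = "null_envelope"
  )
}

#' @export
print.null_envelope <- function(x, ...) {
  cat(sprintf(
    "Divergence null envelope: y = %.4f x + %.4f, sigma = %.4g (n = %d)\n",
    x$slope, x$intercept, x$sigma, x$n_points))
  invisible(x)
}

#' Flag nodes diverging beyond the taxonomy null
#'
#' A node is an outlier when its target-tree distance departs from the
#' envelope prediction at its marker-1 distance by more than
#' `sigma_mult * sigma` (two-sided: convergence below the line and excess
#' divergence above it are both flagged). With `sigma = 0` any non-zero
#' residual is an outlier.
#'
#' @param points A `divergence_points` data frame.
#' @param envelope A `null_envelope` from [fit_null()].
#' @param sigma_mult Width of the band in residual SDs (default 3).
#' @return `points` with `residual` and logical `outlier` columns filled.
#' @export
flag_divergent <- function(points, envelope, sigma_mult = 3) {
  stopifnot(inherits(envelope, "null_envelope"))
  pred <- envelope$slope * points$dist_marker1 + envelope$intercept
  points$residual <- points$dist_target - pred
  # 1e-10 floor: normalized distances are O(1), so this only absorbs
  # floating-point noise when sigma is (near) zero
  points$outlier <- abs(points$residual) > sigma_mult * envelope$sigma + 1e-10
  points
}
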