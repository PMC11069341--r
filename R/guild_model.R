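# Guild impact model: expected-richness power law and impact coefficients.
#
# A group s of equivalent sequences (one taxon, one implementation, one
# environmental context) is scored by
#
#   k_s = A_s * (d_obs,s / d_exp,s) * u_s
#
# where A_s is the summed abundance (TPM), d_obs,s the number of unique
# sequences observed in the group, u_s the univocity of its implementation
# (binary here: functional 1, non-functional 0), and d_exp,s the richness
# expected from abundance alone under the gene-wide power law
#
#   d_exp = c * A^gamma
#
# fitted by ordinary least squares on the log-log scale.

#' Validate and normalize a sequence-group table
#'
#' A group table holds one row per (taxon, implementation, context) group
#' with its summed abundance and observed richness. This is the unit on
#' which impact coefficients are computed.
#'
#' @param groups A data frame with columns `taxon`, `implementation`,
#'   `context`, `abundance_tpm` (non-negative), and `d_obs` (count of
#'   distinct member sequences).
#' @return The validated data frame (invisibly classed `group_table`).
#' @export
as_group_table <- function(groups) {
  required <- c("taxon", "implementation", "context", "abundance_tpm", "d_obs")
  missing <- setdiff(required, names(groups))
  if (length(missing) > 0) {
    stop("group table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(groups$abundance_tpm)) || any(groups$abundance_tpm < 0)) {
    stop("abundance_tpm must be finite and non-negative")
  }
  if (any(groups$d_obs != round(groups$d_obs)) || any(groups$d_obs < 0)) {
    stop("d_obs must be non-negative integer counts")
  }
  if (any(groups$abundance_tpm > 0 & groups$d_obs < 1)) {
    stop("groups with positive abundance must have d_obs >= 1")
  }
  class(groups) <- unique(c("group_table", class(groups)))
  groups
}

#' Fit the expected-richness power law
#'
#' Fits `d = c * A^gamma` by ordinary least squares of `log(d_obs)` on
#' `log(abundance_tpm)` across groups, pooled over taxa, implementations
#' and contexts of one gene. Groups with zero abundance carry no
#' information about the law and are excluded (their count is reported).
#'
#' @param groups A group table (see [as_group_table()]), or any data frame
#'   with `abundance_tpm` and `d_obs` columns.
#' @param log_base Base of the logarithm used internally. The returned
#'   `c` and `gamma` are on the linear scale and do not depend on it; it is
#'   recorded for reproducibility.
#' @return An object of class `richness_model` with elements `c`, `gamma`,
#'   `r_squared`, `n_points`, `n_excluded`, `log_base`.
#' @export
fit_richness_model <- function(groups, log_base = exp(1)) {
  if (!all(c("abundance_tpm", "d_obs") %in% names(groups))) {
    stop("groups must have abundance_tpm and d_obs columns")
  }
  usable <- groups$abundance_tpm > 0 & groups$d_obs >= 1
  n_excluded <- sum(!usable)
  A <- groups$abundance_tpm[usable]
  d <- groups$d_obs[usable]
  if (length(A) < 3) {
    stop("insufficient points: need >= 3 groups with positive abundance, got ",
         length(A))
  }
  if (length(unique(A)) == 1L) {
    stop("degenerate regressor: all abundances identical, cannot fit exponent")
  }
  x <- log(A, base = log_base)
  y <- log(d, base = log_base)
  fit <- stats::lm(y ~ x)
  gamma <- unname(stats::coef(fit)[2L])
  c_const <- log_base^unname(stats::coef(fit)[1L])
  # computed directly so that exact power-law inputs give r2 = 1 quietly
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(
    list(c = c_const, gamma = gamma, r_squared = r2,
         n_points = length(A), n_excluded = n_excluded,
         log_base = log_base),
    class = "richness_model"
  )
}

#' @export
print.richness_model <- function(x, ...) {
  cat("Expected-richness power law: d_exp = c * A^gamma\n")
  cat(sprintf("  c = %.6g, gamma = %.6g\n", x$c, x$gamma))
  cat(sprintf("  R^2 = %.4f on %d groups (%d zero-abundance excluded)\n",
              x$r_squared, x$n_points, x$n_excluded))
  invisible(x)
}

#' Expected sequence richness at a given abundance
#'
#' Evaluates the fitted power law `d_exp = c * A^gamma`.
#'
#' @param model A `richness_model` from [fit_richness_model()].
#' @param abundance_tpm Positive abundance value(s) in TPM.
#' @return Expected richness, strictly positive, same length as input.
#' @export
expected_richness <- function(model, abundance_tpm) {
  stopifnot(inherits(model, "richness_model"))
  if (any(!is.finite(abundance_tpm)) || any(abundance_tpm <= 0)) {
    stop("abundance_tpm must be finite and > 0")
  }
  model$c * abundance_tpm^model$gamma
}

#' Impact coefficient of a group of equivalent sequences
#'
#' Computes `k = A * (d_obs / d_exp) * u`: abundance, rescaled by the
#' richness surprise (observed over expected unique-sequence counts), and
#' annulled for non-functional implementations (`u = 0`). Groups richer
#' than expected from their abundance are rewarded (`k > A`), poorer ones
#' penalized.
#'
#' @param abundance_tpm Summed abundance of the group (TPM, `>= 0`).
#' @param d_obs Observed number of unique sequences.
#' @param d_exp Expected richness at this abundance (`> 0`).
#' @param u Univocity in `[0, 1]` (binary in practice).
#' @return The impact coefficient, `>= 0`. Vectorized over its arguments.
#' @export
impact_coefficient <- function(abundance_tpm, d_obs, d_exp, u) {
  if (any(!is.finite(d_exp)) || any(d_exp <= 0)) {
    stop("d_exp must be finite and > 0")
  }
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (any(abundance_tpm < 0)) stop("abundance_tpm must be >= 0")
  abundance_tpm * (d_obs / d_exp) * u
}

#' Build the per-group impact table
#'
#' Applies the impact coefficient to every group. Groups whose
#' implementation is the undefined label get no `k` value (recorded as
#' `NA` and flagged `"incertae"`, distinct from `k = 0` of a
#' non-functional `u = 0` implementation, which is retained and flagged).
#'
#' @param groups A group table (see [as_group_table()]).
#' @param model A fitted `richness_model`.
#' @param univocity Named numeric vector mapping implementation labels to
#'   `u` in `[0, 1]`. Every implementation present in `groups`, other than
#'   `incertae_label`, must be covered.
#' @param incertae_label Label of the undefined sequence space
#'   (default `"incertae"`).
#' @return A data frame (class `impact_table`): the group columns plus
#'   `d_exp`, `u`, `k`, and a `status` flag
#'   (`"functional"`, `"non_functional"`, `"incertae"`).
#' @export
build_impact_table <- function(groups, model, univocity,
                               incertae_label = "incertae") {
  groups <- as_group_table(as.data.frame(groups))
  stopifnot(inherits(model, "richness_model"))
  impl <- as.character(groups$implementation)
  defined <- setdiff(unique(impl), incertae_label)
  missing_u <- setdiff(defined, names(univocity))
  if (length(missing_u) > 0) {
    stop("no univocity entry for implementation(s): ",
         paste(missing_u, collapse = ", "))
  }
  if (any(univocity < 0 | univocity > 1)) stop("univocity must lie in [0, 1]")

  out <- as.data.frame(groups)
  n <- nrow(out)
  out$d_exp <- NA_real_
  out$u <- NA_real_
  out$k <- NA_real_
  out$status <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (impl[i] == incertae_label) {
      out$status[i] <- "incertae"
      next
    }
    u_i <- unname(univocity[[impl[i]]])
    out$u[i] <- u_i
    A <- out$abundance_tpm[i]
    if (A > 0) {
      out$d_exp[i] <- expected_richness(model, A)
      out$k[i] <- impact_coefficient(A, out$d_obs[i], out$d_exp[i], u_i)
    } else {
      out$k[i] <- 0 # no reads observed, no contribution
    }
    out$status[i] <- if (u_i == 0) "non_functional" else "functional"
  }
  class(out) <- unique(c("impact_table", class(out)))
  out
}

#' Aggregate impact coefficients
#'
#' Sums `k` over groups sharing the kept dimensions. Undefined
#' (`incertae`) groups carry no `k` and are excluded; the grand total over
#' defined groups is conserved under any grouping.
#'
#' @param table An `impact_table` from [build_impact_table()].
#' @param by Character subset of `c("taxon", "implementation", "context")`
#'   to keep; empty (default) collapses everything to the grand total.
#' @return A data frame with the `by` columns and the summed `k`.
#' @export
aggregate_k <- function(table, by = character()) {
  allowed <- c("taxon", "implementation", "context")
  if (length(by) > 0 && !all(by %in% allowed)) {
    stop("unknown grouping key(s): ",
         paste(setdiff(by, allowed), collapse = ", "))
  }
  if (nrow(table) == 0) stop("impact table is empty")
  defined <- table[!is.na(table$k), , drop = FALSE]
  if (length(by) == 0) {
    return(data.frame(k = sum(defined$k)))
  }
  if (nrow(defined) == 0) {
    out <- defined[, by, drop = FALSE]
    out$k <- numeric(0)
    rownames(out) <- NULL
    return(out)
  }
  agg <- stats::aggregate(defined["k"], by = defined[by], FUN = sum)
  agg <- agg[do.call(order, agg[by]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

select_rows <- function(table, selector) {
  keep <- rep(TRUE, nrow(table))
  for (col in names(selector)) {
    if (!col %in% names(table)) stop("unknown selector column: ", col)
    keep <- keep & table[[col]] %in% selector[[col]]
  }
  table[keep, , drop = FALSE]
}

#' Fold change of aggregated impact between two selections
#'
#' Ratio of summed `k` between two subsets of the impact table, e.g. the
#' mesopelagic versus epipelagic totals of one implementation. In
#' `mode = "pooled"` the functional groups of each selection are first
#' pooled into a single sequence set (abundances and observed richness
#' summed) and the impact coefficient is re-evaluated on the pooled set.
#'
#' @param table An `impact_table`.
#' @param numerator,denominator Named lists selecting rows, e.g.
#'   `list(context = "meso")`.
#' @param mode `"sum"` (default): ratio of summed `k`. `"pooled"`:
#'   re-apply the impact coefficient to pooled groups (requires `model`).
#' @param model A `richness_model`, needed for `mode = "pooled"`.
#' @return The fold change (a single number).
#' @export
fold_change <- function(table, numerator, denominator,
                        mode = c("sum", "pooled"), model = NULL) {
  mode <- match.arg(mode)
  num <- select_rows(table, numerator)
  den <- select_rows(table, denominator)
  if (nrow(num) == 0) stop("numerator selection is empty")
  if (nrow(den) == 0) stop("denominator selection is empty")
  total <- function(x) {
    if (mode == "sum") return(sum(x$k, na.rm = TRUE))
    if (is.null(model)) stop("mode = 'pooled' requires a richness model")
    fx <- x[!is.na(x$u) & x$u > 0, , drop = FALSE]
    if (nrow(fx) == 0) return(0)
    A <- sum(fx$abundance_tpm)
    d <- sum(fx$d_obs)
    if (A <= 0) return(0)
    impact_coefficient(A, d, expected_richness(model, A), 1)
  }
  den_total <- total(den)
  if (den_total <= 0) stop("denominator aggregate k is zero; fold change undefined")
  total(num) / den_total
}
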