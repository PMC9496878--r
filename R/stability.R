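#' Nodal temporal correlation coefficient of a dynamic network
#'
#' For each node `i` of a binary dynamic network with `W` layers, measures
#' how much its connection neighbourhood overlaps between consecutive
#' layers:
#' \deqn{C_i = \frac{1}{W-1} \sum_{t=1}^{W-1}
#'   \frac{\sum_j a_{ij}(t)\, a_{ij}(t+1)}
#'        {\sqrt{\left[\sum_j a_{ij}(t)\right]\left[\sum_j a_{ij}(t+1)\right]}}}
#' where \eqn{a_{ij}(t)} is the adjacency indicator in layer `t`. Each term
#' is the co-neighbour count normalised by the geometric mean of the two
#' degrees, so \eqn{C_i \in [0, 1]}: 1 means the neighbourhood is identical
#' (and non-empty) across all consecutive layers, 0 means consecutive
#' neighbourhoods never share a connection.
#'
#' When a node is isolated in layer `t` or `t+1` the term is 0/0; under the
#' default `isolated = "zero"` that term contributes 0 and still counts in
#' the `W - 1` divisor, under `"skip"` it is dropped from both numerator
#' and divisor (a node with no valid term gets 0). `denominator =
#' "product"` replaces the geometric mean by the plain product
#' \eqn{k_i(t)\,k_i(t+1)} for sensitivity checks; it is not bounded away
#' from deflating \eqn{C_i} and is not the default.
#'
#' @param net A `dynamic_network` (see [build_dynamic_networks()]) with at
#'   least two layers, or a plain list of binary adjacency matrices.
#' @param isolated Treatment of isolated-node terms: `"zero"` (default) or
#'   `"skip"`.
#' @param denominator `"geometric"` (default) or `"product"`.
#' @return Numeric vector of length `N` with values in \[0, 1\].
#' @export
temporal_correlation <- function(net,
                                 isolated = c("zero", "skip"),
                                 denominator = c("geometric", "product")) {
  isolated <- arg_match(isolated)
  denominator <- arg_match(denominator)
  layers <- if (inherits(net, "dynamic_network")) net$layers else net
  if (!is.list(layers) || length(layers) < 2) {
    abort("temporal correlation undefined for a single window: need W >= 2 layers.")
  }
  n <- nrow(layers[[1]])
  w <- length(layers)
  acc <- numeric(n)
  valid <- numeric(n)
  deg_prev <- rowSums(layers[[1]])
  for (t in 2:w) {
    deg_cur <- rowSums(layers[[t]])
    common <- rowSums(layers[[t - 1]] * layers[[t]])
    den <- switch(denominator,
      geometric = sqrt(deg_prev * deg_cur),
      product = deg_prev * deg_cur
    )
    ok <- den > 0
    acc[ok] <- acc[ok] + common[ok] / den[ok]
    valid <- valid + ok
    deg_prev <- deg_cur
  }
  divisor <- switch(isolated, zero = rep(w - 1, n), skip = valid)
  out <- ifelse(divisor > 0, acc / divisor, 0)
  as.numeric(out)
}

#' Average nodal stability over the density grid
#'
#' @param per_density Numeric matrix, densities in rows, nodes in columns.
#' @return Numeric vector: per-node unweighted mean over densities.
#' @export
average_over_densities <- function(per_density) {
  if (!is.matrix(per_density) || nrow(per_density) < 1) {
    abort("`per_density` must be a matrix with at least one density row.")
  }
  colMeans(per_density)
}

#' Aggregate nodal stability to network and whole-brain level
#'
#' @param nodal Numeric vector of density-averaged nodal temporal
#'   correlation coefficients, in node-index order.
#' @param table A validated node table with as many rows as `nodal`.
#' @return List with `whole_brain` (mean over every node, regardless of
#'   network assignment) and `per_network` (named numeric vector: mean over
#'   each populated declared network, `"unassigned"` excluded).
#' @export
aggregate_stability <- function(nodal, table) {
  table <- validate_node_table(table, networks = node_table_networks(table))
  if (length(nodal) != nrow(table)) {
    abort(paste0(
      "length of `nodal` (", length(nodal),
      ") does not match node table size (", nrow(table), ")."
    ))
  }
  nets <- setdiff(node_table_networks(table), "unassigned")
  nets <- nets[nets %in% table$network_label]
  per_network <- vapply(nets, function(nw) {
    mean(nodal[nodes_of_network(table, nw) + 1L])
  }, numeric(1))
  list(whole_brain = mean(nodal), per_network = per_network)
}

#' Full stability pipeline for one subject
#'
#' Composes the whole per-subject computation: sliding-window Pearson
#' correlation, proportional thresholding at every density of the grid,
#' nodal temporal correlation per density, unweighted averaging across
#' densities, and aggregation to network and whole-brain level.
#'
#' Internally the density loop shares one ranking of each window's
#' correlations instead of materialising every binary network, which gives
#' results identical to the explicit
#' [build_dynamic_networks()] + [temporal_correlation()] composition
#' (this equivalence is exercised in the package tests).
#'
#' @inheritParams windowed_correlation
#' @inheritParams threshold_by_density
#' @inheritParams temporal_correlation
#' @param table Node table defining the network aggregation.
#' @param spec Optional [make_windows()] spec; by default one is built from
#'   the series with the conventional 100 s window and 6 s step.
#' @param densities Density grid, default [density_grid()].
#' @return A `stability_profile` object; see [tidy.stability_profile()].
#' @export
#' @examples
#' tab <- synthetic_node_table(12)
#' ts <- generate_subject(cohort_config(n_nodes = 12, n_timepoints = 80),
#'                        dwell_global = 20, seed = 1)
#' prof <- compute_stability(ts, tab, densities = density_grid(0.1, 0.5, 0.1))
#' glance(prof)
compute_stability <- function(ts, table, spec = NULL,
                              densities = density_grid(),
                              rank = c("signed", "absolute"),
                              rounding = c("floor", "round"),
                              isolated = c("zero", "skip"),
                              denominator = c("geometric", "product")) {
  rank <- arg_match(rank)
  rounding <- arg_match(rounding)
  isolated <- arg_match(isolated)
  denominator <- arg_match(denominator)
  stopifnot(inherits(ts, "subject_time_series"))
  table <- validate_node_table(table, networks = node_table_networks(table))
  n <- nrow(ts$data)
  if (nrow(table) != n) {
    abort("node table size does not match the number of series rows.")
  }
  if (is.null(spec)) spec <- make_windows(ncol(ts$data), ts$tr_seconds)
  if (spec$n_windows < 2) {
    abort("temporal correlation undefined for a single window: need W >= 2.")
  }
  if (length(densities) < 1 || any(densities <= 0) || any(densities > 1)) {
    abort("`densities` must lie in (0, 1].")
  }
  if (length(densities) > 1 && any(diff(densities) <= 0)) {
    abort("`densities` must be strictly increasing.")
  }

  corrs <- windowed_correlation(ts, spec)
  pairs <- ut_pairs(n)
  n_pairs <- length(pairs$linear)
  w <- spec$n_windows
  d_count <- length(densities)
  ks <- vapply(densities, edge_count, integer(1),
               n_nodes = n, rounding = rounding)

  # rank of every node pair within every window (1 = strongest)
  ranks <- matrix(0L, n_pairs, w)
  for (t in seq_len(w)) {
    v <- corrs[[t]][pairs$linear]
    key <- if (rank == "signed") v else abs(v)
    ord <- order(-key, seq_len(n_pairs))
    ranks[ord, t] <- seq_len(n_pairs)
  }

  # node x pair incidence matrix: degree and co-neighbour counts by matmul
  inc <- matrix(0, n, n_pairs)
  inc[cbind(pairs$i, seq_len(n_pairs))] <- 1
  inc[cbind(pairs$j, seq_len(n_pairs))] <- 1

  present <- function(t) {
    # pair x density logical: is the pair among the top K at each density
    outer(ranks[, t], ks, "<=")
  }
  prev <- present(1)
  deg_prev <- inc %*% prev
  acc <- matrix(0, n, d_count)
  valid <- matrix(0, n, d_count)
  for (t in 2:w) {
    cur <- present(t)
    deg_cur <- inc %*% cur
    common <- inc %*% (prev & cur)
    den <- switch(denominator,
      geometric = sqrt(deg_prev * deg_cur),
      product = deg_prev * deg_cur
    )
    ok <- den > 0
    acc[ok] <- acc[ok] + common[ok] / den[ok]
    valid <- valid + ok
    prev <- cur
    deg_prev <- deg_cur
  }
  divisor <- switch(isolated,
    zero = matrix(w - 1, n, d_count),
    skip = valid
  )
  per_density <- t(ifelse(divisor > 0, acc / divisor, 0))  # density x node
  dimnames(per_density) <- list(
    density = format(densities),
    node = table$node_label
  )
  nodal <- average_over_densities(per_density)
  agg <- aggregate_stability(nodal, table)
  structure(
    list(
      subject_id = ts$subject_id,
      densities = densities,
      per_density = per_density,
      nodal = nodal,
      whole_brain = agg$whole_brain,
      per_network = agg$per_network,
      node_table = table,
      n_windows = w
    ),
    class = "stability_profile"
  )
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(
    "<stability_profile> ", x$subject_id, ": ", length(x$nodal), " nodes, ",
    length(x$densities), " densities, ", x$n_windows, " windows\n",
    "  whole-brain temporal correlation: ",
    formatC(x$whole_brain, digits = 4, format = "f"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a stability profile
#'
#' @param x A `stability_profile`.
#' @param ... Unused.
#' @return A tibble with one row per reported level: columns `subject_id`,
#'   `level` (`"whole_brain"`, `"network"` or `"node"`), `unit` (the label)
#'   and `temporal_correlation`.
#' @method tidy stability_profile
#' @export
tidy.stability_profile <- function(x, ...) {
  bind_rows(
    tibble(
      subject_id = x$subject_id, level = "whole_brain", unit = "whole_brain",
      temporal_correlation = x$whole_brain
    ),
    tibble(
      subject_id = x$subject_id, level = "network",
      unit = names(x$per_network),
      temporal_correlation = unname(x$per_network)
    ),
    tibble(
      subject_id = x$subject_id, level = "node",
      unit = x$node_table$node_label,
      temporal_correlation = unname(x$nodal)
    )
  )
}

#' @rdname tidy.stability_profile
#' @method glance stability_profile
#' @export
glance.stability_profile <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    n_nodes = length(x$nodal),
    n_densities = length(x$densities),
    n_windows = x$n_windows,
    whole_brain = x$whole_brain
  )
}

#' Combine many stability profiles into one tidy table
#'
#' @param profiles List of `stability_profile` objects.
#' @param level Which levels to keep (default all three).
#' @return A tibble, rows stacked across subjects.
#' @export
tidy_profiles <- function(profiles,
                          level = c("whole_brain", "network", "node")) {
  level <- match.arg(level, several.ok = TRUE)
  out <- bind_rows(lapply(profiles, tidy))
  out[out$level %in% level, ]
}
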