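#' Density grid for proportional thresholding
#'
#' The conventional grid of connection densities, 0.01 to 0.50 in steps of
#' 0.01 (50 values). Stability metrics are averaged over this grid so that
#' no single threshold drives the result.
#'
#' @param min,max,step Grid limits and increment.
#' @return Numeric vector of densities.
#' @export
density_grid <- function(min = 0.01, max = 0.50, step = 0.01) {
  if (min <= 0 || max > 1 || step <= 0 || min > max) {
    abort("invalid density grid: need 0 < min <= max <= 1 and step > 0.")
  }
  round(seq(min, max, by = step), 10)
}

# Upper-triangle node pairs (i < j, 0-based... returned 1-based) in
# lexicographic (i, j) order, the order used to break rank ties.
ut_pairs <- function(n_nodes) {
  ij <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  list(
    i = ij[, 1],
    j = ij[, 2],
    linear = (ij[, 2] - 1L) * n_nodes + ij[, 1]
  )
}

# Number of edges retained at a given density.
edge_count <- function(density, n_nodes,
                       rounding = c("floor", "round")) {
  rounding <- arg_match(rounding)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  k <- switch(rounding,
    floor = floor(density * n_pairs),
    round = round(density * n_pairs)
  )
  max(1L, as.integer(k))
}

#' Sliding-window Pearson correlation matrices
#'
#' Computes, for each window of a [make_windows()] specification, the
#' matrix of pairwise Pearson correlations between all node signals
#' restricted to that window.
#'
#' @param ts A [subject_time_series()].
#' @param spec A [window_spec][make_windows] built for `ncol(ts$data)`
#'   time points.
#' @return List of `spec$n_windows` symmetric correlation matrices with
#'   unit diagonal.
#' @export
windowed_correlation <- function(ts, spec) {
  stopifnot(inherits(ts, "subject_time_series"), inherits(spec, "window_spec"))
  if (spec$n_timepoints != ncol(ts$data)) {
    abort("window spec was built for a different number of time points.")
  }
  lapply(seq_len(spec$n_windows), function(w) {
    s <- spec$window_starts[w]
    xw <- ts$data[, (s + 1):(s + spec$length_samples), drop = FALSE]
    v <- apply(xw, 1, sd)
    if (any(v == 0)) {
      abort(paste0(
        "zero-variance signal for node(s) ",
        paste(which(v == 0) - 1L, collapse = ", "),
        " within window ", w,
        "; Pearson correlation is undefined there."
      ))
    }
    cc <- cor(t(xw))
    diag(cc) <- 1
    cc
  })
}

#' Binarise a correlation matrix at a proportional density
#'
#' Keeps the `K = max(1, floor(density * N(N-1)/2))` strongest connections
#' of a symmetric correlation matrix and sets them to 1, all others to 0
#' (proportional thresholding). By default connections are ranked by their
#' signed correlation value, so strong negative correlations are never
#' retained; `rank = "absolute"` ranks by magnitude instead. Ties at the
#' cut are resolved in favour of the lexicographically smallest `(i, j)`
#' node pair, which makes the result deterministic.
#'
#' @param corr Symmetric numeric correlation matrix.
#' @param density Target density in (0, 1].
#' @param rank Rank connections by `"signed"` (default) or `"absolute"`
#'   correlation.
#' @param rounding How the edge count is derived from the density:
#'   `"floor"` (default) or `"round"`.
#' @return Binary symmetric adjacency matrix with zero diagonal and exactly
#'   `K` edges.
#' @export
threshold_by_density <- function(corr, density,
                                 rank = c("signed", "absolute"),
                                 rounding = c("floor", "round")) {
  rank <- arg_match(rank)
  rounding <- arg_match(rounding)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    abort("`corr` must be a square matrix.")
  }
  if (length(density) != 1 || density <= 0 || density > 1) {
    abort("`density` must be a single value in (0, 1].")
  }
  n <- nrow(corr)
  pairs <- ut_pairs(n)
  v <- corr[pairs$linear]
  if (any(!is.finite(v))) {
    abort("`corr` contains non-finite off-diagonal entries.")
  }
  k <- edge_count(density, n, rounding)
  if (k > length(v)) {
    abort(paste0("density ", density, " asks for ", k, " edges but only ",
                 length(v), " node pairs exist."))
  }
  key <- if (rank == "signed") v else abs(v)
  keep <- head(order(-key, seq_along(key)), k)
  adj <- matrix(0L, n, n)
  adj[pairs$linear[keep]] <- 1L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

new_dynamic_network <- function(layers, density, edge_count) {
  structure(
    list(layers = layers, density = density, edge_count = edge_count),
    class = "dynamic_network"
  )
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(
    "<dynamic_network> density ", x$density, ": ", length(x$layers),
    " layers of ", nrow(x$layers[[1]]), " nodes, ", x$edge_count,
    " edges each\n",
    sep = ""
  )
  invisible(x)
}

#' Build binary dynamic networks over a density grid
#'
#' Runs the full construction for one subject: sliding-window Pearson
#' correlation followed by proportional thresholding of every window at
#' every requested density. Because thresholding keeps the top-`K` ranked
#' connections, the network at a lower density is always a subgraph of the
#' network at a higher density within the same window.
#'
#' @inheritParams windowed_correlation
#' @inheritParams threshold_by_density
#' @param densities Strictly increasing vector of densities in (0, 1];
#'   defaults to [density_grid()].
#' @return List of `dynamic_network` objects, one per density, each holding
#'   `spec$n_windows` binary adjacency layers.
#' @export
build_dynamic_networks <- function(ts, spec, densities = density_grid(),
                                   rank = c("signed", "absolute"),
                                   rounding = c("floor", "round")) {
  rank <- arg_match(rank)
  rounding <- arg_match(rounding)
  if (length(densities) < 1 || any(densities <= 0) || any(densities > 1)) {
    abort("`densities` must lie in (0, 1].")
  }
  if (any(diff(densities) <= 0)) {
    abort("`densities` must be strictly increasing.")
  }
  corrs <- windowed_correlation(ts, spec)
  n <- nrow(ts$data)
  lapply(densities, function(d) {
    layers <- lapply(corrs, threshold_by_density, density = d,
                     rank = rank, rounding = rounding)
    new_dynamic_network(layers, d, edge_count(d, n, rounding))
  })
}
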