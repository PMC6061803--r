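#' Directed shortest-path lengths
#'
#' Breadth-first geodesic distances on a binary directed graph.
#' `adjacency[i, j] = 1` encodes an edge `j -> i`; the returned matrix has
#' `D[s, t]` equal to the directed distance from `s` to `t`, `Inf` when `t`
#' is unreachable and 0 on the diagonal.
#'
#' @param adjacency square binary matrix with zero diagonal.
#' @return Numeric distance matrix.
#' @export
shortest_path_lengths <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  cpp_bfs_distances(adjacency)
}

check_adjacency <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == ncol(adjacency))
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  storage.mode(adjacency) <- "integer"
  adjacency
}

#' Global efficiency of a directed binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' `1/Inf = 0` (Latora-Marchiori).  1 for a complete digraph, 0 for an empty
#' one.
#'
#' @inheritParams shortest_path_lengths
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  stopifnot(nrow(adjacency) >= 2)
  cpp_global_efficiency(adjacency)
}

#' Local efficiency of every node of a directed binary graph
#'
#' For node `i`, the neighbourhood is the union of its in- and
#' out-neighbours; the local efficiency is the global efficiency of the
#' directed subgraph induced on that neighbourhood with `i` removed, and 0
#' when the node has fewer than two neighbours.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector of length `n_nodes`, values in `[0, 1]`.
#' @export
local_efficiency <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  cpp_local_efficiency(adjacency)
}

#' Local efficiency per node and frequency
#'
#' Applies [local_efficiency()] to each frequency bin of a binarized
#' adjacency series.
#'
#' @param adjacency_series an `adjacency_series` from
#'   [binarize_top_fraction()].
#' @param node_locations optional node coordinates carried through to the
#'   result.
#' @return An object of class `efficiency_map`: `values` (`n_nodes` x
#'   `n_freq`, in `[0, 1]`), `frequencies`, `node_locations`.
#' @export
local_efficiency_series <- function(adjacency_series, node_locations = NULL) {
  stopifnot(inherits(adjacency_series, "adjacency_series"))
  adj <- adjacency_series$adjacency
  storage.mode(adj) <- "integer"
  values <- cpp_local_efficiency_series(adj, dim(adj))
  structure(list(values = values,
                 frequencies = adjacency_series$frequencies,
                 node_locations = node_locations),
            class = "efficiency_map")
}

#' @export
print.efficiency_map <- function(x, ...) {
  cat(sprintf("<efficiency_map> %d nodes x %d frequency bins (%g-%g Hz), mean %.3f\n",
              nrow(x$values), ncol(x$values), min(x$frequencies),
              max(x$frequencies), mean(x$values)))
  invisible(x)
}

#' Long-format table of an efficiency map
#'
#' @param efficiency_map an `efficiency_map`.
#' @return Data frame with columns `node`, `frequency_hz`, `efficiency`.
#' @export
efficiency_long <- function(efficiency_map) {
  stopifnot(inherits(efficiency_map, "efficiency_map"))
  v <- efficiency_map$values
  data.frame(node = rep(seq_len(nrow(v)), times = ncol(v)),
             frequency_hz = rep(efficiency_map$frequencies, each = nrow(v)),
             efficiency = as.vector(v))
}
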